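	ALA	ARG	ASN	ASP	CYS	GLN	GLU	GLY	HIS	ILE	LEU	LYS	MET	PHE	PRO	SER	THR	TRP	TYR	VAL
ALA	NA	15	12	13	4	13	13	3	10	14	14	6	2	14	10	7	12	NA	15	6
ARG	15	NA	21	25	6	27	20	7	27	17	28	28	26	28	19	19	19	27	NA	22
ASN	12	21	25	24	15	28	26	10	21	26	26	24	20	29	21	17	20	24	27	23
ASP	13	25	24	9	18	29	26	NA	10	26	NA	26	24	20	22	17	21	22	23	NA
CYS	4	6	15	18	12	17	18	6	16	19	NA	18	15	18	16	10	8	18	19	16
GLN	13	27	28	29	17	20	28	NA	NA	NA	21	NA	26	26	24	18	4	26	24	17
GLU	13	20	26	26	18	28	NA	10	20	20	20	5	27	21	25	19	23	19	26	22
GLY	3	7	10	NA	6	NA	10	NA	10	9	NA	9	8	8	8	4	6	6	10	5
HIS	10	27	21	10	16	NA	20	10	26	27	10	6	19	28	20	14	17	28	20	20
ILE	14	17	26	26	19	NA	20	9	27	25	NA	30	26	28	19	18	24	27	NA	11
LEU	14	28	26	NA	NA	21	20	NA	10	NA	NA	NA	24	29	19	18	22	24	NA	9
LYS	6	28	24	26	18	NA	5	9	6	30	NA	28	23	26	21	15	25	28	NA	18
MET	2	26	20	24	15	26	27	8	19	26	24	23	20	28	21	4	23	27	27	23
PHE	14	28	29	20	18	26	21	8	28	28	29	26	28	25	21	20	22	26	29	NA
PRO	10	19	21	22	16	24	25	8	20	19	19	21	21	21	19	16	21	22	23	NA
SER	7	19	17	17	10	18	19	4	14	18	18	15	4	20	16	NA	NA	20	NA	15
THR	12	19	20	21	8	4	23	6	17	24	22	25	23	22	21	NA	8	23	20	18
TRP	NA	27	24	22	18	26	19	6	28	27	24	28	27	26	22	20	23	27	14	NA
TYR	15	NA	27	23	19	24	26	10	20	NA	NA	NA	27	29	23	NA	20	14	24	21
VAL	6	22	23	NA	16	17	22	5	20	11	9	18	23	NA	NA	15	18	NA	21	NA
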