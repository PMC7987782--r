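# psndelta

Wildtype-versus-mutant comparison of protein structure networks.

A disease-causing point mutation can leave a protein's backbone almost
unchanged yet rewire its internal residue-contact network — or bend the
backbone substantially while the local contacts survive. `psndelta`
quantifies both axes for a pair of crystal structures of the same protein:
it builds weighted all-atom protein structure networks (PSNs), partitions
their edges and hubs into retained / lost / gained sets, reports per-site
degree, strength and solvent-accessibility changes, and measures global
divergence with backbone Cα RMSD alongside a spectral network
dissimilarity score (NDS). It is written for structural bioinformaticians
studying how mutations perturb residue interaction networks, including at
functional sites distant from the mutated position.

## The model in brief

Residues are nodes. Two non-adjacent residues (sequence separation ≥ 2)
with a heavy-atom pair within 4.5 Å form an edge of weight

    I_ij = n_ij / N_{t(i) t(j)}

where `n_ij` counts the atom contacts and `N` is the highest contact count
observed for that amino-acid-type pair in a reference set (the
*normalization table*). A node of degree ≥ 11 is a hub. For two networks
on their topologically equivalent residues,

    NDS = sqrt( EDS² + EWCS² + (1 − CRS)² )

combines an edge-weight difference (EDS, normalized Frobenius norm),
a Spearman correlation of matched Laplacian eigenvector ranks (CRS), and
an eigenvalue-weighted cosine score between matched eigenvectors (EWCS).
Identical networks score 0; the ceiling is √3. The methods vignette
(`vignettes/psn-comparison-methods.Rmd`) derives every convention and
tie-break.

## Worked example

The package ships a synthetic-structure generator that reproduces the two
perturbation regimes without any downloads, so the whole pipeline is
runnable offline:

```r
library(psndelta)

pair <- make_pair("sidechain_repack", seed = 1)   # backbone fixed
compare_pair(pair$wt, pair$mut, config = psn_config(with_exposure = FALSE))
#> <comparison_report> SYNT:A vs SYNT:A
#>   common residues n = 80 (coverage 1.00 / 1.00)
#>   C-alpha RMSD 0.000 A | NDS 0.2186 (EDS 0.0627, CRS 0.9826, EWCS 0.2086)
#>   edges: retained 97, lost 2, gained 14
#>   hubs:  retained 0, lost 0, gained 0

hinge <- make_pair("hinge_bend", seed = 1)        # backbone bent
compare_pair(hinge$wt, hinge$mut, config = psn_config(with_exposure = FALSE))
#> <comparison_report> SYNT:A vs SYNT:A
#>   common residues n = 80 (coverage 1.00 / 1.00)
#>   C-alpha RMSD 5.792 A | NDS 0.1359 (EDS 0.0332, CRS 0.9410, EWCS 0.1178)
#>   edges: retained 96, lost 3, gained 0
#>   hubs:  retained 0, lost 0, gained 0
```

Read the two reports together: side-chain repacking leaves the backbone in
place (RMSD 0) while 16 edges change and the NDS rises to 0.22; the hinge
bend moves the backbone by 5.8 Å yet only 3 edges change and the NDS stays
lower (0.14). Backbone divergence and network divergence are decoupled —
which is exactly why both are reported.

Real structures go through the same entry point:

```r
rep <- compare_pair("wildtype.pdb", "mutant.pdb",
                    wt_chain = "A", mut_chain = "A",
                    sites = data.frame(seq_number = 304,
                                       role = "mutation_site"))
write_report(rep, "report.json")
```

`fetch_pdb("1EGE")` downloads an entry when network access is available.

## The analysis workflow

Numbered scripts under `analysis/` run the full study on synthetic
material and write their tables under `results/`:

| script | what it does |
|---|---|
| `analysis/01_simulate.R` | fixture chains, normalization table, 4 scenarios × 5 seeds as PDB files + manifest |
| `analysis/02_compare.R`  | full pipeline on every pair; per-pair JSON reports + `comparison_summary.tsv` |
| `analysis/03_summarise.R` | per-scenario means/SDs, regime-decoupling check, RMSD-vs-NDS scatter |

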