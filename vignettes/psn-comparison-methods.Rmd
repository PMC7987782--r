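---
title: "Comparing wildtype and mutant protein structure networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing wildtype and mutant protein structure networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psndelta)
```

## The model

A protein structure network (PSN) represents a protein chain as a weighted
undirected graph: residues are nodes, and two residues are linked when they
are in spatial contact. `psndelta` uses the all-atom geometric definition:
a pair of heavy atoms from two *non-adjacent* residues (sequence separation
of at least 2 by default) at Euclidean distance of at most 4.5 &Aring;
counts as an atom contact, and any residue pair with at least one atom
contact forms an edge. The edge weight is

$$I_{ij} = \frac{n_{ij}}{N_{t(i)\,t(j)}}$$

where $n_{ij}$ is the number of atom contacts between residues $i$ and $j$
and $N_{t(i)t(j)}$ is a *normalization value*: the highest atom-contact
count ever observed between residues of those two amino-acid types across
a reference structure set. Node *degree* is the number of incident edges,
*strength* the sum of incident weights, and a node with degree $\ge$ 11 is
a *hub*.

Given a wildtype and a mutant chain, the pipeline

1. maps *topologically equivalent residues* by global sequence alignment
   (point mutants of the same protein align end-to-end),
2. builds both PSNs and restricts them to the common node set,
3. partitions edges and hubs into **retained**, **lost** (unique to the
   wildtype) and **gained** (unique to the mutant),
4. reports per-site changes in degree, strength and solvent accessibility,
5. quantifies global backbone divergence (superposed C&alpha; RMSD) and
   global network divergence with the spectral **network dissimilarity
   score**.

## The network dissimilarity score

For two weighted networks $A$, $B$ on an identical node set, three
components are combined:

* **EDS** (edge difference score)
  $= \lVert A-B\rVert_F \,/\, \sqrt{S_A S_B}$, where $S$ sums each
  undirected edge weight once. It is zero iff the weighted edge sets
  coincide.
* **CRS** (correspondence score): both graph Laplacians are
  eigendecomposed, eigenvectors ranked by ascending eigenvalue and paired
  one-to-one across the two spectra; CRS is the Spearman correlation of
  the paired ranks, $1 - 6\sum d_k^2 / (n(n^2-1))$.
* **EWCS** (eigenvalue-weighted cosine score): the weighted
  root-mean-square of $(1-\lvert\cos\theta_k\rvert)$ over paired
  eigenvectors, with weights $\lvert 1-\lambda_k^A\rvert \,
  \lvert 1-\lambda_k^B\rvert$.

$$\mathrm{NDS} = \sqrt{\mathrm{EDS}^2 + \mathrm{EWCS}^2 +
  (1-\mathrm{CRS})^2}$$

Identical networks give $(\mathrm{EDS}, \mathrm{CRS}, \mathrm{EWCS}) =
(0, 1, 0)$ and NDS $= 0$; with every component at its extreme the score
reaches $\sqrt{3}$.

### Numerical choices

Several choices are deliberately pinned by unit tests because the score is
sensitive to them:

* **Laplacian variant.** The EWCS weight $\lvert 1-\lambda\rvert$ is
  centred at 1, the hallmark of the symmetric normalized Laplacian
  $L = I - D^{-1/2} A D^{-1/2}$ (spectrum in $[0,2]$), so that variant is
  the default; the combinatorial Laplacian $D - A$ is available as an
  option. Rows and columns of isolated nodes are zeroed so each isolated
  node contributes the exact eigenpair $(0, e_i)$ and self-comparison of
  graphs with isolated nodes is still exactly 0.
* **EDS summation convention.** The numerator is the full-matrix Frobenius
  norm; the denominator sums each undirected edge once (the
  `full_matrix` alternative is selectable). The single-edge halving
  fixture ($1.0$ vs $0.5$ on one shared edge $\Rightarrow$ EDS $= 1$) pins
  the convention.
* **Eigenvector pairing.** Eigenvector sign is arbitrary, so absolute
  cosines are used throughout. Vectors are paired greedily by maximal
  $\lvert\cos\rvert$, each vector used once; on non-degenerate fixtures
  with $n \le 6$ the greedy pairing is tested against exhaustive optimal
  assignment. Cosines within $10^{-12}$ of 1 are snapped to exactly 1 so
  that self-comparison is exact rather than accurate to eigensolver
  round-off.
* **Degenerate eigenvalues.** Within a cluster of (near-)equal eigenvalues
  (gaps $< 10^{-6}$) the individual eigenvectors are an arbitrary
  orthonormal basis, so their rank order carries no information. The
  matching is therefore canonicalized after the greedy pass: paired ranks
  are redistributed in sorted order inside each degenerate cluster, which
  minimizes the Spearman penalty over the equivalent eigendecompositions.
  Cosines keep the cosine-driven pairing (within a cluster the
  eigenvalues, and hence the EWCS weights, are tied). Without this step,
  graphs with repeated eigenvalues — e.g. several isolated nodes — show
  spuriously negative CRS for modest perturbations. Results on degenerate
  spectra are flagged in the output.
* **Bounds.** CRS $\in [-1, 1]$ and EWCS $\in [0, 1]$ by construction.
  EDS is *not* clamped: a pathological weight difference can push it above
  1, and the result records `eds_exceeds_one` instead of hiding it. The
  $\sqrt{3}$ ceiling therefore holds whenever EDS $\le 1$ and CRS $\ge 0$;
  strongly anti-correlated rank matchings could in principle exceed it,
  which the randomized bound suite monitors.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `cutoff` | 4.5 | &Aring; | atom-contact distance (closed boundary) |
| `min_seq_separation` | 2 | residues | excludes $i,i\pm1$ "contacts" |
| `hub_threshold` | 11 | edges | minimum hub degree |
| `norm_table` | derived from the input pair | counts | edge-weight denominator |
| `max_resolution` | 3.0 | &Aring; | crystal quality gate |
| `max_r_diff` | 0.05 | fraction | maximum $R_\mathrm{free}-R_\mathrm{work}$ |
| `probe_radius` | 1.4 | &Aring; | solvent probe (water) |
| `rsa_threshold` | 0.10 | fraction | buried/exposed boundary |
| `align_mode` | `"sequence"` | — | `"sequence+refine"` drops pairs deviating > 5 &Aring; |

The normalization table deserves emphasis: absolute NDS magnitudes depend
on it, while edge counts, degrees, hubs and the edge/hub partitions do
not. By default `compare_pair()` derives the table from the two input
chains themselves — the analysed "dataset" of a pairwise run — which
guarantees every occurring residue-type pair is covered and every weight
is at most 1. A fixed table (the bundled synthetic one via
`default_normalization()`, or any 20&times;20 TSV) can be supplied when
comparability across many pairs matters more.

Solvent accessibility is computed with an internal Shrake–Rupley sampler
(960 deterministic Fibonacci sphere points per atom, heavy atoms only)
against the Tien et al. theoretical maxima; relative accessibility below
0.10 classifies a residue as buried. Published analyses of this kind
rarely state their SASA tool or threshold, so these are declared,
configurable defaults rather than reproduction targets.

## The synthetic generator

Real wildtype/mutant crystal pairs show two extreme regimes: side-chain
repacking (backbone essentially unchanged, contact network rearranged) and
collective backbone motion (large C&alpha; RMSD, local networks
preserved). The generator reproduces both without any database access.

`make_chain()` builds an idealized &alpha;-helical backbone (rise 1.5
&Aring;/residue, 100&deg; twist, radius 2.3 &Aring;) carrying
pseudo-side-chains: one carbon pseudo-atom per heavy side-chain atom of
the residue type, stacked at 1.5 &Aring; spacing with seeded jitter of at
most 0.3 &Aring;. Side chains grow along the outward radial *tilted
alternately up and down the helix axis with period 4*. The tilt is
load-bearing: on this idealized helix a purely radial side chain can never
come within 4.5 &Aring; of a non-adjacent residue (the per-residue rise
alone exceeds the cut-off at separation $\ge 3$, and the 100&deg; twist
does the same at separation 2), which would leave every network edgeless.
The tilt lets side chains one helical turn apart interdigitate, giving
sparse but non-trivial networks (the shipped fixture set reaches node
degree 4).

* `perturb_sidechains(fraction = 0.5, magnitude = 3.0)` displaces the
  side-chain atoms of a random residue subset, leaving backbone atoms
  bitwise untouched: C&alpha; RMSD is exactly 0 while edges are made and
  broken.
* `hinge_bend(pivot = 3n/4, angle = 60)` rotates the chain tail rigidly
  about the tangential axis through the pivot C&alpha; (perpendicular to
  the helix axis). The positive sense swings the tail *outward*, away
  from the helix body; the opposite sense (or the radial axis choice)
  collides the tail with the body and *gains* edges, which is the
  opposite of the preserved-network regime this scenario emulates.
  Intra-segment distances are preserved exactly.
* `mutate_residue()` swaps one residue's pseudo-side chain for the target
  type's atom count — a point mutation with zero backbone RMSD.

The default scenario size is 80 residues: a realistic small single-domain
length whose spectra are stable enough for the regime comparison (spectral
scores on very small sparse graphs are dominated by eigenvector noise).
Determinism is absolute per seed (Mersenne–Twister, state restored after
each call).

What the generator does *not* emulate: real rotamer geometry, sterics,
secondary-structure diversity, crystal-packing artefacts, missing
residues, or hub-rich cores (synthetic degrees stay far below the hub
threshold of real structures). Passing tests on synthetic pairs therefore
validate the *machinery* — contact detection, weighting, partitions,
spectral scores, and the qualitative RMSD/NDS decoupling — not the
absolute magnitudes published for any particular protein, which
additionally depend on the unpublished normalization table of the
original analysis.

## Worked example

```{r example}
pair <- make_pair("sidechain_repack", seed = 1)
report <- compare_pair(pair$wt, pair$mut,
                       config = psn_config(with_exposure = FALSE))
report
```

The repack pair shows the first regime: zero backbone divergence with a
rearranged network. The converse:

```{r hinge}
hinge <- make_pair("hinge_bend", seed = 1)
compare_pair(hinge$wt, hinge$mut,
             config = psn_config(with_exposure = FALSE))
```

## Degenerate and edge-case inputs

* Chains with zero standard residues are rejected; non-standard residues
  are dropped (selenomethionine is mapped to methionine).
* Alternate locations keep the highest-occupancy copy, first in file on
  ties; hydrogens are parsed but excluded from contacts and SASA.
* Residues flanking a gap in the resolved chain count as sequence-adjacent
  (adjacency is defined on the resolved-residue order, not author
  numbering).
* An edgeless graph has no defined EDS (zero denominator); the error is
  signalled with a distinct condition class.
* `superpose()` requires at least 3 non-coincident points and disallows
  reflections.
* Mapped residues lacking a C&alpha; are dropped from RMSD with a
  warning; fewer than 3 usable pairs is an error.

## Known limitations

* Structure-based alignment (TM-align style) is not implemented; for
  point mutants of the same protein, global sequence alignment is exact,
  and `"sequence+refine"` approximates an aligned-core RMSD by iteratively
  discarding pairs deviating by more than 5 &Aring;. RMSD values for pairs
  with large conformational change are tolerance-bearing for this reason.
* Reproducing published absolute NDS values requires the original
  normalization table, which is not public; with a pair-derived or
  synthetic table the NDS is well-defined and internally consistent but
  can differ in magnitude.
* The greedy eigenvector pairing can differ from the globally optimal
  assignment when the cosine structure between two spectra is diffuse
  (genuinely dissimilar networks); on perturbation-scale differences with
  non-degenerate spectra the two agree, which is the tested regime.
* Single chains only; no biological assemblies, no structure repair.

## Problem sizes

The test-suite and analysis defaults are sized for a desk-scale run:
fixture chains of 30–60 residues, scenario chains of 80 residues, five
seeds per scenario, and 1000 randomized graph pairs (5–14 nodes) in the
bound suite. All are package choices made once; every number reported by
the analysis scripts is recomputed from scratch at run time.
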