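Package: psndelta
Title: Wildtype-Versus-Mutant Protein Structure Network Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds weighted all-atom protein structure networks (PSNs) from
    crystal structures, aligns wildtype and mutant chains to their
    topologically equivalent residues, partitions edges and hubs into
    retained, lost and gained sets, reports per-site degree, strength and
    solvent-accessibility changes, and quantifies global network divergence
    with a spectral Network Dissimilarity Score (NDS) alongside backbone
    C-alpha RMSD. Includes a synthetic-structure generator emulating
    side-chain repacking and hinge-bend perturbation regimes so the whole
    pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
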