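test_that("chain generation is deterministic per seed", {
  a <- make_chain(30, seed = 1)
  b <- make_chain(30, seed = 1)
  expect_identical(a$atoms, b$atoms)
  c2 <- make_chain(30, seed = 2)
  expect_false(identical(a$atoms, c2$atoms))
  expect_error(make_chain(5, "AXBZQ"), "non-standard")
  expect_error(make_chain(5, "AAAA"), "length")
})

test_that("consecutive C-alpha distances follow the helix closed form", {
  ch <- make_chain(40, seed = 3)
  ca <- atom_coords(ch)
  d <- sqrt(rowSums(diff(ca)^2))
  expected <- sqrt((2 * 2.3 * sin(100 / 2 * pi / 180))^2 + 1.5^2)
  expect_equal(d, rep(expected, 39), tolerance = 1e-8)
})

test_that("the default fixture set yields non-trivial networks", {
  chains <- fixture_chains()
  norm <- derive_normalization(chains)
  max_deg <- 0
  for (ch in chains) {
    psn <- build_psn(ch, norm)
    expect_gte(psndelta:::psn_edge_count(psn), 1)
    max_deg <- max(max_deg, node_metrics(psn)$degree)
  }
  expect_gte(max_deg, 4)
})

test_that("the bundled normalization table regenerates from the fixtures", {
  bundled <- default_normalization()
  fresh <- derive_normalization(fixture_chains())
  expect_equal(unclass(bundled), unclass(fresh)[rownames(bundled),
                                                colnames(bundled)],
               ignore_attr = TRUE)
})

test_that("side-chain perturbation leaves the backbone bitwise unchanged", {
  ch <- make_chain(40, seed = 4,
                   sequence = paste(rep(c("K", "L", "F", "S"), 10),
                                    collapse = ""))
  # fraction 0 is the identity
  expect_identical(perturb_sidechains(ch, 0, 3, seed = 1)$atoms, ch$atoms)
  pert <- perturb_sidechains(ch, 0.5, 3.0, seed = 1)
  bb <- ch$atoms$atom %in% c("N", "CA", "C", "O")
  expect_identical(pert$atoms[bb, ], ch$atoms[bb, ])
  # displacements bounded by the magnitude
  delta <- sqrt(rowSums((as.matrix(pert$atoms[, c("x", "y", "z")]) -
                           as.matrix(ch$atoms[, c("x", "y", "z")]))^2))
  expect_lte(max(delta), 3.0 + 1e-12)
  # determinism
  expect_identical(perturb_sidechains(ch, 0.5, 3.0, seed = 1)$atoms,
                   pert$atoms)
  expect_false(identical(perturb_sidechains(ch, 0.5, 3.0, seed = 2)$atoms,
                         pert$atoms))
})

test_that("side-chain repacking decouples RMSD from network change", {
  pr <- make_pair("sidechain_repack", seed = 1)
  mapping <- align_chains(pr$wt, pr$mut)
  expect_equal(ca_rmsd(pr$wt, pr$mut, mapping), 0, tolerance = 1e-10)
  norm <- derive_normalization(list(pr$wt, pr$mut))
  common <- restrict_common(build_psn(pr$wt, norm), build_psn(pr$mut, norm),
                            mapping)
  expect_gt(nds_score(common$wt, common$mut)$nds, 0)
})

test_that("hinge bending preserves intra-segment geometry exactly", {
  ch <- make_chain(40, seed = 5,
                   sequence = paste(rep(c("A", "K", "L", "S"), 10),
                                    collapse = ""))
  expect_identical(hinge_bend(ch, 30, 0)$atoms, ch$atoms)
  bent <- hinge_bend(ch, 30, 60)
  for (seg in list(ch$atoms$res_index <= 30, ch$atoms$res_index > 30)) {
    xyz0 <- as.matrix(ch$atoms[seg, c("x", "y", "z")])
    xyz1 <- as.matrix(bent$atoms[seg, c("x", "y", "z")])
    expect_equal(as.vector(dist(xyz0)), as.vector(dist(xyz1)),
                 tolerance = 1e-8)
  }
  expect_error(hinge_bend(ch, 0, 10), "pivot")
  expect_error(hinge_bend(ch, 39, 10), "pivot")
  # edges strictly within either segment are identical before/after
  norm <- derive_normalization(list(ch, bent))
  e0 <- psn_edges(build_psn(ch, norm))
  e1 <- psn_edges(build_psn(bent, norm))
  internal <- function(e) {
    n <- as.integer(e$node_a) ; m <- as.integer(e$node_b)
    e[(n <= 31 & m <= 31) | (n > 31 & m > 31), c("node_a", "node_b")]
  }
  expect_equal(internal(e0), internal(e1), ignore_attr = TRUE)
})

test_that("scenario pairs carry correct qualitative signatures", {
  idp <- make_pair("identity", seed = 2)
  expect_identical(idp$wt$atoms, idp$mut$atoms)
  expect_true(idp$expected$rmsd_zero)

  pm <- make_pair("point_mutation", seed = 2)
  mapping <- align_chains(pm$wt, pm$mut)
  expect_equal(attr(mapping, "n"), n_residues(pm$wt))
  expect_equal(ca_rmsd(pm$wt, pm$mut, mapping), 0, tolerance = 1e-10)
  pos <- pm$scenario$parameters$position
  expect_equal(pm$mut$residues$name3[pos + 1], aa_one_to_three("W"))
  # mutated node's degree recount at the substituted position
  norm <- derive_normalization(list(pm$wt, pm$mut))
  common <- restrict_common(build_psn(pm$wt, norm), build_psn(pm$mut, norm),
                            mapping)
  d <- site_deltas(common$wt, common$mut)
  recount <- sum(common$mut$adjacency[pos + 1, ] > 0) -
    sum(common$wt$adjacency[pos + 1, ] > 0)
  expect_equal(d$ddegree[pos + 1], recount)

  expect_error(make_pair("no_such_scenario"), "arg")
})

test_that("hinge bending moves the backbone but preserves local networks", {
  for (seed in 1:3) {
    hb <- make_pair("hinge_bend", seed = seed)
    rp <- make_pair("sidechain_repack", seed = seed)
    mapping <- align_chains(hb$wt, hb$mut)
    expect_gt(ca_rmsd(hb$wt, hb$mut, mapping), 1)
    norm <- derive_normalization(list(hb$wt, hb$mut))
    common <- restrict_common(build_psn(hb$wt, norm),
                              build_psn(hb$mut, norm), mapping)
    nds_hinge <- nds_score(common$wt, common$mut)$nds
    norm_rp <- derive_normalization(list(rp$wt, rp$mut))
    common_rp <- restrict_common(build_psn(rp$wt, norm_rp),
                                 build_psn(rp$mut, norm_rp),
                                 align_chains(rp$wt, rp$mut))
    nds_repack <- nds_score(common_rp$wt, common_rp$mut)$nds
    expect_lt(nds_hinge, nds_repack)
  }
})
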