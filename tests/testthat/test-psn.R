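test_that("contact detection honors the cutoff and adjacency exclusion", {
  # residues 0 and 2: single heavy atoms 4.4 A apart -> one contact record
  ch <- point_chain(rbind(c(0, 0, 0), c(20, 0, 0), c(4.4, 0, 0)))
  ct <- find_atom_contacts(ch)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$res_a, 0L)
  expect_equal(ct$res_b, 2L)
  expect_equal(ct$atom_pair_count, 1L)
  # adjacent residues 3 A apart: excluded
  ch2 <- point_chain(rbind(c(0, 0, 0), c(3, 0, 0)))
  expect_equal(nrow(find_atom_contacts(ch2)), 0)
  # boundary is closed: exactly 4.5 A counts
  ch3 <- point_chain(rbind(c(0, 0, 0), c(20, 0, 0), c(4.5, 0, 0)))
  expect_equal(nrow(find_atom_contacts(ch3)), 1)
})

test_that("contact detection equals the brute-force all-pairs oracle", {
  for (seed in c(1, 2)) {
    ch <- make_chain(30, seed = seed,
                     sequence = paste(sample(aa_table()$name1, 30,
                                             replace = TRUE), collapse = ""))
    fast <- find_atom_contacts(ch)
    slow <- brute_force_contacts(ch)
    expect_equal(fast$res_a, slow$res_a)
    expect_equal(fast$res_b, slow$res_b)
    expect_equal(fast$atom_pair_count, slow$atom_pair_count)
  }
})

test_that("normalization derivation takes the pooled maximum", {
  # one chain whose only contact is LEU-LEU with a known atom-pair count
  ch <- chain_from_atoms(list(
    list(name3 = "LEU", atoms = rbind(CA = c(0, 0, 0), CB = c(1.5, 0, 0),
                                      CG = c(3, 0, 0), CD = c(4, 0, 0))),
    list(name3 = "GLY", atoms = rbind(CA = c(0, 50, 0))),
    list(name3 = "LEU", atoms = rbind(CA = c(8, 0, 0), CB = c(6.5, 0, 0),
                                      CG = c(5.2, 0, 0), CD = c(4.6, 0, 0)))))
  # pairs within 4.5: CG-CB'(2.2? ) count by oracle
  oracle <- brute_force_contacts(ch)
  norm <- derive_normalization(list(ch))
  expect_equal(unclass(norm)["LEU", "LEU"], oracle$atom_pair_count[1])
  expect_true(is.na(unclass(norm)["ALA", "ALA"]))
  expect_error(derive_normalization(list()), "empty")

  # pooled maximum across 10 chains equals brute-force pooling
  chains <- fixture_chains(5)
  norm10 <- derive_normalization(chains)
  pool <- do.call(rbind, lapply(chains, function(c2) {
    ct <- brute_force_contacts(c2)
    ct$name3_a <- c2$residues$name3[ct$res_a + 1]
    ct$name3_b <- c2$residues$name3[ct$res_b + 1]
    ct
  }))
  for (k in seq_len(nrow(pool))) {
    t1 <- pool$name3_a[k]; t2 <- pool$name3_b[k]
    expect_gte(unclass(norm10)[t1, t2], pool$atom_pair_count[k])
  }
  # every table entry is attained by some pooled contact
  vals <- unclass(norm10)
  for (t1 in rownames(vals)) for (t2 in colnames(vals)) {
    if (!is.na(vals[t1, t2])) {
      hit <- (pool$name3_a == t1 & pool$name3_b == t2) |
        (pool$name3_a == t2 & pool$name3_b == t1)
      expect_equal(max(pool$atom_pair_count[hit]), vals[t1, t2])
    }
  }
})

test_that("edge weights follow the contact-count ratio", {
  ch <- point_chain(rbind(c(0, 0, 0), c(20, 0, 0), c(4.0, 0, 0)))
  norm <- matrix(5, 20, 20, dimnames = list(aa_table()$name3,
                                            aa_table()$name3))
  class(norm) <- c("norm_table", class(norm))
  psn <- build_psn(ch, norm)
  expect_equal(psn$adjacency["1", "3"], 1 / 5)
  # count equal to the normalization maximum -> weight 1
  norm1 <- norm; norm1[] <- 1
  psn1 <- build_psn(ch, norm1)
  expect_equal(psn1$adjacency["1", "3"], 1.0)
  # count above the maximum -> clamped with a warning
  ch2 <- chain_from_atoms(list(
    list(name3 = "ALA", atoms = rbind(CA = c(0, 0, 0), CB = c(1, 0, 0))),
    list(name3 = "GLY", atoms = rbind(CA = c(0, 40, 0))),
    list(name3 = "ALA", atoms = rbind(CA = c(3, 0, 0), CB = c(2.5, 0, 0)))))
  expect_warning(psn2 <- build_psn(ch2, norm1), "clamp")
  expect_equal(max(psn2$adjacency), 1.0)
  # missing normalization entry errors naming the pair
  norm_na <- norm; norm_na["ALA", "ALA"] <- NA
  expect_error(build_psn(ch, norm_na), "ALA-ALA")
})

test_that("hub flags flip exactly at the degree threshold", {
  a <- matrix(0, 13, 13)
  a[1, 2:12] <- 1; a[2:12, 1] <- 1   # node 1 has degree 11
  a[2, 3:12] <- 0.5; a[3:12, 2] <- 0.5  # node 2 has degree 11 too
  a[2, 12] <- 0; a[12, 2] <- 0          # now degree 10
  psn <- psn_from_adjacency(a)
  nm <- node_metrics(psn)
  expect_true(nm$hub[1])    # degree 11
  expect_false(nm$hub[2])   # degree 10
})

test_that("node metrics match an independent recount of the adjacency", {
  psn <- random_psn(25, p = 0.3, seed = 9)
  nm <- node_metrics(psn)
  expect_equal(nm$degree,
               unname(apply(psn$adjacency, 1, function(r) sum(r > 0))))
  expect_equal(nm$strength, unname(apply(psn$adjacency, 1, sum)))
  # two incident edges of weight 0.5 each
  a <- matrix(0, 3, 3); a[1, 2] <- a[2, 1] <- 0.5; a[2, 3] <- a[3, 2] <- 0.5
  nm2 <- node_metrics(psn_from_adjacency(a))
  expect_equal(nm2$degree[2], 2L)
  expect_equal(nm2$strength[2], 1.0)
  # isolated node
  expect_equal(nm2$degree[1], 1L)
  b <- matrix(0, 2, 2)
  nm3 <- node_metrics(psn_from_adjacency(b))
  expect_equal(nm3$degree, c(0L, 0L))
  expect_equal(nm3$strength, c(0, 0))
  expect_false(any(nm3$hub))
})

test_that("constructed PSNs satisfy the structural invariants", {
  for (seed in 1:3) {
    ch <- make_chain(40, seed = seed,
                     sequence = paste(sample(aa_table()$name1, 40,
                                             replace = TRUE), collapse = ""))
    psn <- build_psn(ch, derive_normalization(list(ch)))
    a <- psn$adjacency
    expect_identical(a, t(a))
    expect_true(all(diag(a) == 0))
    w <- a[upper.tri(a) & a > 0]
    expect_true(all(w > 0 & w <= 1))
    nm <- node_metrics(psn)
    expect_equal(sum(nm$degree), 2 * psn_edge_count(psn))
    expect_equal(sum(nm$strength), 2 * sum(a[upper.tri(a)]))
  }
})

test_that("the PSN is invariant under rigid-body motion of the chain", {
  ch <- make_chain(35, seed = 4,
                   sequence = paste(sample(aa_table()$name1, 35,
                                           replace = TRUE), collapse = ""))
  norm <- derive_normalization(list(ch))
  psn <- build_psn(ch, norm)
  th <- 1.1
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3,
              byrow = TRUE)
  moved <- ch
  xyz <- as.matrix(ch$atoms[, c("x", "y", "z")]) %*% t(R)
  moved$atoms$x <- xyz[, 1] - 30
  moved$atoms$y <- xyz[, 2] + 11
  moved$atoms$z <- xyz[, 3] + 5
  psn2 <- build_psn(moved, norm)
  expect_equal(psn2$adjacency, psn$adjacency, tolerance = 1e-12)
})

test_that("raising the cutoff never removes an edge; raising the hub
           threshold never creates a hub", {
  ch <- make_chain(30, seed = 6,
                   sequence = paste(sample(aa_table()$name1, 30,
                                           replace = TRUE), collapse = ""))
  norm <- derive_normalization(list(ch), cutoff = 6.0)
  lo <- build_psn(ch, norm, cutoff = 4.5)
  hi <- build_psn(ch, norm, cutoff = 6.0)
  expect_true(all(hi$adjacency[lo$adjacency > 0] > 0))
  h11 <- sum(node_metrics(build_psn(ch, norm, hub_threshold = 3))$hub)
  h12 <- sum(node_metrics(build_psn(ch, norm, hub_threshold = 4))$hub)
  expect_gte(h11, h12)
})

test_that("PSN exports round-trip edge information", {
  ch <- make_chain(20, seed = 2,
                   sequence = paste(sample(aa_table()$name1, 20,
                                           replace = TRUE), collapse = ""))
  psn <- build_psn(ch, derive_normalization(list(ch)))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_psn_edges(psn, tsv)
  back <- read.table(tsv, sep = "\t", header = TRUE)
  expect_equal(nrow(back), psn_edge_count(psn))
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_psn_graphml(psn, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), psn_edge_count(psn))
  # normalization table TSV round trip
  ntsv <- withr::local_tempfile(fileext = ".tsv")
  norm <- derive_normalization(fixture_chains(3))
  write_norm_table(norm, ntsv)
  back_norm <- read_norm_table(ntsv)
  expect_equal(unclass(back_norm), unclass(norm)[rownames(back_norm),
                                                 colnames(back_norm)],
               ignore_attr = TRUE)
})
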