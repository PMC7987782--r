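# helper: spectra with prescribed orthonormal vectors and eigenvalues
fake_spectrum <- function(values, vectors) {
  structure(list(values = values, vectors = vectors, n = length(values),
                 variant = "normalized",
                 degenerate = any(diff(sort(values)) < 1e-6)),
            class = "psn_spectrum")
}

test_that("normalized Laplacian spectra match closed forms", {
  # two nodes, one edge of any weight -> {0, 2}
  a <- matrix(c(0, 0.37, 0.37, 0), 2)
  s <- laplacian_spectrum(a)
  expect_equal(s$values, c(0, 2), tolerance = 1e-10)
  # unit-weight triangle -> {0, 1.5, 1.5}
  tri <- matrix(1, 3, 3) - diag(3)
  s3 <- laplacian_spectrum(tri)
  expect_equal(s3$values, c(0, 1.5, 1.5), tolerance = 1e-10)
  # edgeless graph: zero-matrix convention, all eigenvalues 0
  z <- laplacian_spectrum(matrix(0, 4, 4))
  expect_equal(z$values, rep(0, 4))
  # range [0, 2] and orthonormal vectors on random graphs
  for (seed in 1:5) {
    a <- random_adjacency(12, 0.4, seed)
    s <- laplacian_spectrum(a)
    expect_true(all(s$values > -1e-8 & s$values < 2 + 1e-8))
    expect_equal(crossprod(s$vectors), diag(12), tolerance = 1e-8)
    sc <- laplacian_spectrum(a, variant = "combinatorial")
    expect_gte(min(sc$values), -1e-8)
  }
  expect_error(laplacian_spectrum(matrix(0, 1, 1)), "2 nodes")
})

test_that("edge difference score follows the pinned convention", {
  # identical -> 0 exactly
  a <- random_adjacency(8, 0.5, 3)
  expect_identical(eds(a, a), 0)
  # single shared edge at weights 1.0 vs 0.5:
  # ||A-B||_F = sqrt(2 * 0.25), denominator sqrt(1.0 * 0.5) -> 1.0
  m1 <- matrix(0, 4, 4); m1[1, 2] <- m1[2, 1] <- 1
  m2 <- matrix(0, 4, 4); m2[1, 2] <- m2[2, 1] <- 0.5
  expect_equal(eds(m1, m2), 1.0, tolerance = 1e-12)
  # full-matrix denominator halves the normalizer's scale
  expect_equal(eds(m1, m2, denominator = "full_matrix"),
               sqrt(2 * 0.25) / sqrt(2 * 1), tolerance = 1e-12)
  # symmetry
  b <- random_adjacency(8, 0.5, 4)
  expect_equal(eds(a, b), eds(b, a), tolerance = 1e-12)
  # edgeless graph signals a distinct condition
  expect_error(eds(a, matrix(0, 8, 8)), class = "psndelta_edgeless_error")
})

test_that("correspondence score is 1 for identical and -1 for reversed
           matchings", {
  a <- random_adjacency(10, 0.5, 5)
  s <- laplacian_spectrum(a)
  expect_equal(crs(s, s), 1.0)
  # orthonormal vectors arranged so rank i of A matches rank n+1-i of B
  for (n in c(4, 7, 10)) {
    va <- diag(n)
    vb <- va[, n:1]
    sa <- fake_spectrum(seq(0, 1.9, length.out = n), va)
    sb <- fake_spectrum(seq(0, 1.9, length.out = n), vb)
    expect_equal(crs(sa, sb), -1, tolerance = 1e-12)
  }
  expect_error(crs(fake_spectrum(0, matrix(1)), fake_spectrum(0, matrix(1))),
               "n < 2")
})

test_that("eigenvalue-weighted cosine score hits its bounds", {
  a <- random_adjacency(9, 0.5, 6)
  s <- laplacian_spectrum(a)
  expect_equal(ewcs(s, s), 0)
  # all weight on a single orthogonal pair -> 1
  va <- diag(3); vb <- va[, c(2, 1, 3)]
  sa <- fake_spectrum(c(0, 1, 1), va)   # only rank-1 pair carries weight
  sb <- fake_spectrum(c(0, 1, 1), vb)
  m <- data.frame(rank_a = 1:3, rank_b = 1:3,
                  abs_cos = c(0, 1, 1))  # forced matching: cos 0 on weight
  expect_equal(ewcs(sa, sb, matching = m), 1.0)
  # zero total weight -> 0 by convention
  sa1 <- fake_spectrum(c(1, 1), diag(2))
  expect_equal(ewcs(sa1, sa1), 0)
})

test_that("greedy eigenvector matching equals exhaustive assignment on
           well-separated spectra", {
  found <- 0
  seed <- 0
  while (found < 6 && seed < 60) {
    seed <- seed + 1
    n <- 4 + seed %% 3
    a <- random_adjacency(n, 0.6, seed)
    b <- a
    set.seed(seed + 500)
    i <- sample(n, 1); j <- sample(setdiff(1:n, i), 1)
    b[i, j] <- b[j, i] <- runif(1, 0.05, 1)
    sa <- laplacian_spectrum(a); sb <- laplacian_spectrum(b)
    gaps <- c(diff(sa$values), diff(sb$values))
    if (any(gaps < 1e-3)) next   # only non-degenerate fixtures
    found <- found + 1
    greedy <- match_eigenvectors(sa, sb)
    exact <- exhaustive_matching(sa, sb)
    expect_equal(greedy$rank_b, exact$rank_b)
    expect_equal(crs(sa, sb, greedy), crs_direct(exact, n),
                 tolerance = 1e-10)
    expect_equal(ewcs(sa, sb, greedy), ewcs_direct(sa, sb, exact),
                 tolerance = 1e-10)
  }
  expect_gte(found, 6)
})

test_that("NDS obeys the identity law and the component formula", {
  for (seed in 1:4) {
    ch <- make_chain(25, seed = seed,
                     sequence = paste(sample(aa_table()$name1, 25,
                                             replace = TRUE), collapse = ""))
    psn <- build_psn(ch, derive_normalization(list(ch)))
    r <- nds_score(psn, psn)
    expect_identical(r$eds, 0)
    expect_identical(r$crs, 1)
    expect_identical(r$ewcs, 0)
    expect_identical(r$nds, 0)
  }
  # arithmetic of the combination
  a <- random_adjacency(10, 0.5, 7)
  b <- random_adjacency(10, 0.5, 8)
  r <- nds_score(a, b)
  expect_equal(r$nds, sqrt(r$eds^2 + r$ewcs^2 + (1 - r$crs)^2),
               tolerance = 1e-12)
  # components eds 0.6, crs 0.2, ewcs 0 -> nds 1 (combination formula)
  expect_equal(sqrt(0.6^2 + 0 + (1 - 0.2)^2), 1.0)
})

test_that("NDS is symmetric and permutation-consistent", {
  a <- random_adjacency(12, 0.4, 9)
  b <- random_adjacency(12, 0.4, 10)
  r_ab <- nds_score(a, b); r_ba <- nds_score(b, a)
  expect_equal(r_ab$eds, r_ba$eds, tolerance = 1e-10)
  expect_equal(r_ab$crs, r_ba$crs, tolerance = 1e-10)
  expect_equal(r_ab$ewcs, r_ba$ewcs, tolerance = 1e-10)
  expect_equal(r_ab$nds, r_ba$nds, tolerance = 1e-10)
  set.seed(11)
  p <- sample(12)
  r_p <- nds_score(a[p, p], b[p, p])
  expect_equal(r_p$eds, r_ab$eds, tolerance = 1e-8)
  expect_equal(r_p$crs, r_ab$crs, tolerance = 1e-8)
  expect_equal(r_p$ewcs, r_ab$ewcs, tolerance = 1e-8)
})

test_that("score bounds hold over randomized graph pairs", {
  set.seed(12)
  for (k in 1:200) {
    n <- sample(5:12, 1)
    a <- random_adjacency(n, runif(1, 0.2, 0.8), seed = 2000 + k)
    b <- random_adjacency(n, runif(1, 0.2, 0.8), seed = 3000 + k)
    if (sum(a) == 0 || sum(b) == 0) next
    r <- nds_score(a, b)
    expect_gte(r$crs, -1 - 1e-9); expect_lte(r$crs, 1 + 1e-9)
    expect_gte(r$ewcs, 0); expect_lte(r$ewcs, 1 + 1e-9)
    if (r$eds <= 1) expect_lte(r$nds, sqrt(3) + 1e-9)
  }
})
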