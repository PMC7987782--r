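# Spectral Network Dissimilarity Score between two weighted networks on an
# identical node set.
#
# Three components: EDS compares edge weights directly (normalised Frobenius
# norm of the adjacency difference); CRS and EWCS compare the Laplacian
# spectra -- CRS as a Spearman-type correlation of matched eigenvector ranks,
# EWCS as an eigenvalue-weighted aggregate of (1 - |cosine|) between matched
# eigenvectors. NDS = sqrt(EDS^2 + EWCS^2 + (1 - CRS)^2), 0 for identical
# networks and bounded by sqrt(3) while every component stays within [0, 1].

.as_adjacency <- function(x) {
  if (inherits(x, "psn")) x$adjacency
  else if (is.matrix(x)) x
  else stop("expected a psn or an adjacency matrix")
}

#' Laplacian spectrum of a network
#'
#' Computes the eigendecomposition of the graph Laplacian. The default is
#' the symmetric normalized Laplacian `L = I - D^(-1/2) A D^(-1/2)`, whose
#' eigenvalues lie in [0, 2]; rows and columns of isolated nodes (strength
#' zero) are set to zero so each isolated node contributes an exact
#' eigenpair (0, indicator vector). The combinatorial Laplacian `D - A` is
#' available as an option.
#'
#' @param psn a `psn` or a symmetric non-negative adjacency matrix, n >= 2.
#' @param variant `"normalized"` or `"combinatorial"`.
#' @return list of class `psn_spectrum`: `values` (ascending), `vectors`
#'   (orthonormal columns, column k paired with value k), `n`, `variant`,
#'   and `degenerate` (TRUE when some eigenvalue gap < 1e-6).
#' @export
laplacian_spectrum <- function(psn, variant = c("normalized",
                                                "combinatorial")) {
  variant <- match.arg(variant)
  a <- .as_adjacency(psn)
  n <- nrow(a)
  if (n < 2) stop("need at least 2 nodes")
  s <- rowSums(a)
  if (variant == "normalized") {
    L <- matrix(0, n, n)
    nz <- s > 0
    if (any(nz)) {
      dm <- 1 / sqrt(s[nz])
      L[nz, nz] <- diag(sum(nz)) -
        (dm * a[nz, nz, drop = FALSE]) %*% diag(dm, nrow = sum(nz))
      L[nz, nz] <- (L[nz, nz] + t(L[nz, nz])) / 2
    }
  } else {
    L <- diag(s) - a
  }
  e <- eigen(L, symmetric = TRUE)
  ord <- order(e$values)
  values <- e$values[ord]
  vectors <- e$vectors[, ord, drop = FALSE]
  structure(list(values = values, vectors = vectors, n = n,
                 variant = variant,
                 degenerate = any(diff(values) < 1e-6)),
            class = "psn_spectrum")
}

#' Edge difference score
#'
#' `EDS = ||A - B||_F / sqrt(S_A * S_B)` where `S` sums the edge weights of
#' a graph. By default each undirected edge is summed once in the
#' denominator while the numerator is the full-matrix Frobenius norm;
#' `denominator = "full_matrix"` sums both triangles instead.
#'
#' @param psn_a,psn_b `psn` objects or adjacency matrices on the same node
#'   set.
#' @param denominator `"edges_once"` (default) or `"full_matrix"`.
#' @return non-negative scalar; errors with class `psndelta_edgeless_error`
#'   when either graph has no edge.
#' @export
eds <- function(psn_a, psn_b, denominator = c("edges_once", "full_matrix")) {
  denominator <- match.arg(denominator)
  a <- .as_adjacency(psn_a); b <- .as_adjacency(psn_b)
  if (!all(dim(a) == dim(b))) stop("node sets differ")
  sa <- sum(a) / 2; sb <- sum(b) / 2
  if (denominator == "full_matrix") { sa <- 2 * sa; sb <- 2 * sb }
  if (sa == 0 || sb == 0)
    stop(structure(class = c("psndelta_edgeless_error", "error", "condition"),
                   list(message = "edge difference score undefined: a graph has no edges",
                        call = sys.call())))
  sqrt(sum((a - b)^2)) / sqrt(sa * sb)
}

# ---------------------------------------------------------------------------
# Eigenvector matching

#' Match eigenvectors of two spectra
#'
#' Greedy one-to-one pairing by maximal absolute cosine: the globally
#' largest |cosine| pair is fixed first, then the next among the remaining
#' vectors, until all are paired. Ties prefer the smaller rank difference,
#' then the smaller rank in the first spectrum. Eigenvector sign is
#' immaterial (absolute cosine throughout); cosines within 1e-12 of 1 are
#' snapped to exactly 1 so self-comparison is exact.
#'
#' @param spec_a,spec_b `psn_spectrum` objects with equal `n`.
#' @return data.frame `rank_a`, `rank_b`, `abs_cos` (one row per pair,
#'   ordered by `rank_a`) with attribute `degenerate`.
#' @details Within a cluster of (near-)equal eigenvalues the individual
#'   eigenvectors are an arbitrary orthonormal basis of the eigenspace, so
#'   their relative rank order carries no information. After the greedy
#'   pass the matching is therefore canonicalized: inside each degenerate
#'   cluster (eigenvalue gaps below 1e-6, on either side) the paired ranks
#'   are redistributed in sorted order, which minimizes the Spearman rank
#'   penalty over the equivalent decompositions.
#' @export
match_eigenvectors <- function(spec_a, spec_b) {
  if (spec_a$n != spec_b$n) stop("spectra have different sizes")
  n <- spec_a$n
  M <- abs(crossprod(spec_a$vectors, spec_b$vectors))
  M[M > 1] <- 1
  M[M > 1 - 1e-12] <- 1
  rank_b <- integer(n)
  free_a <- rep(TRUE, n); free_b <- rep(TRUE, n)
  for (step in seq_len(n)) {
    sub <- M
    sub[!free_a, ] <- -Inf
    sub[, !free_b] <- -Inf
    best <- max(sub)
    cand <- which(sub == best, arr.ind = TRUE)
    if (nrow(cand) > 1) {
      dd <- abs(cand[, 1] - cand[, 2])
      cand <- cand[order(dd, cand[, 1], cand[, 2]), , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    rank_b[i] <- j
    free_a[i] <- FALSE; free_b[j] <- FALSE
  }
  # cosines belong to the cosine-driven pairing; the canonicalized ranks
  # only replace the arbitrary within-cluster rank order for the Spearman
  # penalty (eigenvalues inside a cluster are tied, so EWCS weights are
  # unaffected by the reassignment)
  abs_cos <- M[cbind(seq_len(n), rank_b)]
  rank_b <- .canonicalize_degenerate(rank_b, spec_a$values, spec_b$values)
  out <- data.frame(rank_a = seq_len(n), rank_b = rank_b,
                    abs_cos = abs_cos)
  attr(out, "degenerate") <- isTRUE(spec_a$degenerate) ||
    isTRUE(spec_b$degenerate)
  out
}

# clusters of consecutive ranks whose eigenvalue gaps are below tol
.eigen_clusters <- function(values, tol = 1e-6) {
  split(seq_along(values), cumsum(c(1, diff(values) >= tol)))
}

.canonicalize_degenerate <- function(rank_b, values_a, values_b,
                                     tol = 1e-6) {
  for (pass in 1:2) {
    # A-side: within each degenerate cluster of A, sort the matched b-ranks
    for (cl in .eigen_clusters(values_a, tol)) {
      if (length(cl) > 1) rank_b[cl] <- sort(rank_b[cl])
    }
    # B-side: within each degenerate cluster of B, reassign its b-ranks to
    # the a-ranks matched into it in ascending order
    for (cl in .eigen_clusters(values_b, tol)) {
      if (length(cl) > 1) {
        a_ranks <- which(rank_b %in% cl)
        rank_b[sort(a_ranks)] <- sort(rank_b[a_ranks])
      }
    }
  }
  rank_b
}

#' Correspondence score of two spectra
#'
#' Spearman-type correlation of the matched eigenvector ranks:
#' `CRS = 1 - 6 * sum((rank_a - rank_b)^2) / (n (n^2 - 1))`, ranks taken in
#' ascending eigenvalue order and paired by [match_eigenvectors()]. 1 for
#' identical spectra, -1 when the matching exactly reverses the ranks.
#'
#' @param spec_a,spec_b `psn_spectrum` objects, n >= 2.
#' @param matching optional precomputed matching (shared with [ewcs()]).
#' @return scalar in [-1, 1].
#' @export
crs <- function(spec_a, spec_b, matching = NULL) {
  n <- spec_a$n
  if (n < 2) stop("correspondence score degenerate for n < 2")
  if (is.null(matching)) matching <- match_eigenvectors(spec_a, spec_b)
  1 - 6 * sum((matching$rank_a - matching$rank_b)^2) / (n * (n^2 - 1))
}

#' Eigenvalue-weighted cosine score
#'
#' Weighted root-mean-square of `(1 - |cos theta_k|)` over matched
#' eigenvector pairs k, with weights `w_k = |1 - lambda_k^A| *
#' |1 - lambda_k^B|`:
#' `EWCS = sqrt( sum(w (1 - |cos|)^2) / sum(w) )`. Zero when all matched
#' cosines are 1 (identical networks) and when all weights vanish; bounded
#' by 1. `form = "mean"` gives the plain weighted mean of `(1 - |cos|)`
#' instead.
#'
#' @param spec_a,spec_b `psn_spectrum` objects with equal `n`.
#' @param matching optional precomputed matching (shared with [crs()]).
#' @param form `"rms"` (default) or `"mean"`.
#' @return scalar in [0, 1].
#' @export
ewcs <- function(spec_a, spec_b, matching = NULL, form = c("rms", "mean")) {
  form <- match.arg(form)
  if (spec_a$n != spec_b$n) stop("spectra have different sizes")
  if (is.null(matching)) matching <- match_eigenvectors(spec_a, spec_b)
  w <- abs(1 - spec_a$values[matching$rank_a]) *
    abs(1 - spec_b$values[matching$rank_b])
  if (sum(w) == 0) return(0)
  one_minus_cos <- 1 - matching$abs_cos
  if (form == "rms") sqrt(sum(w * one_minus_cos^2) / sum(w))
  else sum(w * one_minus_cos) / sum(w)
}

#' Network dissimilarity score
#'
#' `NDS = sqrt(EDS^2 + EWCS^2 + (1 - CRS)^2)` between two weighted networks
#' on an identical node set: 0 for identical networks, bounded by sqrt(3)
#' whenever EDS <= 1. EDS is never clamped; the result records whether it
#' exceeded 1.
#'
#' @param psn_a,psn_b `psn` objects or adjacency matrices on identical node
#'   sets, each with at least one edge, n >= 2.
#' @param variant Laplacian variant, see [laplacian_spectrum()].
#' @param eds_denominator see [eds()].
#' @param ewcs_form see [ewcs()].
#' @return list of class `nds_result`: `eds`, `crs`, `ewcs`, `nds`, `n`,
#'   `eds_exceeds_one`, `degenerate` (eigenvalue gaps < 1e-6 encountered:
#'   matching within an eigenspace is arbitrary), and the
#'   `eigenvector_matching` table.
#' @export
nds_score <- function(psn_a, psn_b, variant = "normalized",
                      eds_denominator = "edges_once", ewcs_form = "rms") {
  a <- .as_adjacency(psn_a); b <- .as_adjacency(psn_b)
  if (!all(dim(a) == dim(b))) stop("node sets differ")
  if (!is.null(dimnames(a)) && !is.null(dimnames(b)) &&
      !identical(rownames(a), rownames(b)))
    stop("node labels differ between the two networks")
  eds_v <- eds(a, b, denominator = eds_denominator)
  sa <- laplacian_spectrum(a, variant = variant)
  sb <- laplacian_spectrum(b, variant = variant)
  m <- match_eigenvectors(sa, sb)
  crs_v <- crs(sa, sb, matching = m)
  ewcs_v <- ewcs(sa, sb, matching = m, form = ewcs_form)
  structure(
    list(eds = eds_v, crs = crs_v, ewcs = ewcs_v,
         nds = sqrt(eds_v^2 + ewcs_v^2 + (1 - crs_v)^2),
         n = nrow(a), eds_exceeds_one = eds_v > 1,
         degenerate = isTRUE(attr(m, "degenerate")),
         eigenvector_matching = m),
    class = "nds_result")
}

#' @export
print.nds_result <- function(x, ...) {
  cat(sprintf("<nds_result> n = %d\n", x$n))
  cat(sprintf("  EDS  %.4f%s\n", x$eds,
              if (x$eds_exceeds_one) "  (exceeds 1)" else ""))
  cat(sprintf("  CRS  %.4f\n", x$crs))
  cat(sprintf("  EWCS %.4f\n", x$ewcs))
  cat(sprintf("  NDS  %.4f%s\n", x$nds,
              if (x$degenerate)
                "  (degenerate eigenvalues: matching may be arbitrary)"
              else ""))
  invisible(x)
}
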