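# Topologically equivalent residues between two chains, and superposed RMSD.
#
# For point mutants of the same protein a global sequence alignment pins the
# equivalent residues exactly; the optional refine mode iteratively drops
# pairs that superpose poorly, approximating a structure-based aligned core.

#' Map topologically equivalent residues between two chains
#'
#' Globally aligns the one-letter sequences (Needleman-Wunsch, BLOSUM62,
#' affine gap open 10 / extend 0.5 via Biostrings); aligned non-gap columns
#' become residue pairs. With `mode = "sequence+refine"` the mapped C-alpha
#' sets are iteratively superposed and pairs deviating by more than
#' `refine_cutoff` Angstrom are dropped until convergence (at most
#' `max_rounds` rounds).
#'
#' @param wt,mut `chain_model` objects.
#' @param mode `"sequence"` or `"sequence+refine"`.
#' @param gap_open,gap_extend affine gap penalties.
#' @param refine_cutoff Angstrom cut-off for dropping pairs in refine mode.
#' @param max_rounds maximum refine iterations.
#' @return A `residue_mapping`: data.frame of paired 0-based residue indices
#'   (`wt_index`, `mut_index`) plus identity columns, with attributes `n`,
#'   `coverage_wt`, `coverage_mut`.
#' @export
align_chains <- function(wt, mut, mode = c("sequence", "sequence+refine"),
                         gap_open = 10, gap_extend = 0.5,
                         refine_cutoff = 5, max_rounds = 10) {
  mode <- match.arg(mode)
  s1 <- chain_sequence(wt)
  s2 <- chain_sequence(mut)
  if (!nchar(s1) || !nchar(s2)) stop("empty chain sequence")
  data("BLOSUM62", package = "Biostrings", envir = environment())
  pa <- Biostrings::pairwiseAlignment(
    s1, s2, type = "global", substitutionMatrix = BLOSUM62,
    gapOpening = gap_open, gapExtension = gap_extend)
  a1 <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  a2 <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  i1 <- 0L; i2 <- 0L
  wt_idx <- integer(0); mut_idx <- integer(0)
  for (k in seq_along(a1)) {
    g1 <- a1[k] == "-"; g2 <- a2[k] == "-"
    if (!g1) i1 <- i1 + 1L
    if (!g2) i2 <- i2 + 1L
    if (!g1 && !g2) {
      wt_idx <- c(wt_idx, i1 - 1L)
      mut_idx <- c(mut_idx, i2 - 1L)
    }
  }
  if (!length(wt_idx)) stop("alignment produced zero residue pairs")

  if (mode == "sequence+refine") {
    ca_wt <- atom_coords(wt, "CA")
    ca_mut <- atom_coords(mut, "CA")
    for (round in seq_len(max_rounds)) {
      keep_ca <- !is.na(ca_wt[wt_idx + 1L, 1]) &
        !is.na(ca_mut[mut_idx + 1L, 1])
      if (sum(keep_ca) < 3) stop("fewer than 3 superposable pairs")
      sp <- superpose(ca_wt[wt_idx[keep_ca] + 1L, , drop = FALSE],
                      ca_mut[mut_idx[keep_ca] + 1L, , drop = FALSE])
      moved <- transform_coords(ca_mut[mut_idx + 1L, , drop = FALSE], sp)
      dev <- sqrt(rowSums((ca_wt[wt_idx + 1L, , drop = FALSE] - moved)^2))
      drop <- !is.na(dev) & dev > refine_cutoff
      if (!any(drop)) break
      wt_idx <- wt_idx[!drop]; mut_idx <- mut_idx[!drop]
      if (length(wt_idx) < 3) stop("fewer than 3 pairs after refinement")
    }
  }
  if (length(wt_idx) < 3) stop("fewer than 3 aligned pairs")

  out <- data.frame(
    wt_index = wt_idx, mut_index = mut_idx,
    wt_seq_number = wt$residues$seq_number[wt_idx + 1L],
    wt_icode = wt$residues$icode[wt_idx + 1L],
    wt_name3 = wt$residues$name3[wt_idx + 1L],
    mut_seq_number = mut$residues$seq_number[mut_idx + 1L],
    mut_icode = mut$residues$icode[mut_idx + 1L],
    mut_name3 = mut$residues$name3[mut_idx + 1L],
    stringsAsFactors = FALSE)
  if (anyDuplicated(out$wt_index) || anyDuplicated(out$mut_index))
    stop("mapping is not one-to-one")
  attr(out, "n") <- nrow(out)
  attr(out, "coverage_wt") <- nrow(out) / n_residues(wt)
  attr(out, "coverage_mut") <- nrow(out) / n_residues(mut)
  class(out) <- c("residue_mapping", "data.frame")
  out
}

#' Export a residue mapping as TSV
#' @param mapping a `residue_mapping`.
#' @param path output path.
#' @param wt_chain,mut_chain chain ids to record.
#' @return `path`, invisibly.
#' @export
write_mapping <- function(mapping, path, wt_chain = "A", mut_chain = "A") {
  out <- data.frame(wt_chain = wt_chain,
                    wt_resnum = mapping$wt_seq_number,
                    wt_icode = mapping$wt_icode,
                    wt_name3 = mapping$wt_name3,
                    mut_chain = mut_chain,
                    mut_resnum = mapping$mut_seq_number,
                    mut_icode = mapping$mut_icode,
                    mut_name3 = mapping$mut_name3)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Kabsch superposition

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD of
#' `coords_b` onto `coords_a` (reflections disallowed).
#'
#' @param coords_a,coords_b n x 3 matrices with rows corresponding by index,
#'   n >= 3.
#' @return list of class `superposition` with `rotation` (3x3, det +1),
#'   `translation` (length-3), and `rmsd` (Angstrom). Apply with
#'   [transform_coords()]: `x %*% t(R) + t`.
#' @export
superpose <- function(coords_a, coords_b) {
  stopifnot(is.matrix(coords_a), is.matrix(coords_b),
            ncol(coords_a) == 3, ncol(coords_b) == 3,
            nrow(coords_a) == nrow(coords_b))
  n <- nrow(coords_a)
  if (n < 3) stop("need at least 3 points for superposition")
  ca <- colMeans(coords_a); cb <- colMeans(coords_b)
  A <- sweep(coords_a, 2, ca); B <- sweep(coords_b, 2, cb)
  if (all(abs(B) < 1e-12) || all(abs(A) < 1e-12))
    stop("degenerate (coincident) point set")
  H <- crossprod(B, A)  # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- ca - as.vector(R %*% cb)
  moved <- B %*% t(R)
  rmsd <- sqrt(mean(rowSums((A - moved)^2)))
  structure(list(rotation = R, translation = t_vec, rmsd = rmsd),
            class = "superposition")
}

#' Apply a superposition to coordinates
#' @param coords n x 3 matrix.
#' @param sp a `superposition`.
#' @return transformed n x 3 matrix.
#' @export
transform_coords <- function(coords, sp) {
  sweep(coords %*% t(sp$rotation), 2, sp$translation, "+")
}

#' Superposed C-alpha RMSD over mapped residues
#'
#' Extracts the C-alpha coordinates of the mapped residue pairs (pairs
#' lacking a C-alpha are dropped with a warning), superposes them and
#' returns the RMSD.
#'
#' @param wt,mut `chain_model` objects.
#' @param mapping a `residue_mapping` from [align_chains()].
#' @return RMSD in Angstrom.
#' @export
ca_rmsd <- function(wt, mut, mapping) {
  ca_wt <- atom_coords(wt, "CA")[mapping$wt_index + 1L, , drop = FALSE]
  ca_mut <- atom_coords(mut, "CA")[mapping$mut_index + 1L, , drop = FALSE]
  ok <- !is.na(ca_wt[, 1]) & !is.na(ca_mut[, 1])
  if (any(!ok))
    warning(sum(!ok), " mapped pair(s) lack a C-alpha atom; dropped")
  if (sum(ok) < 3) stop("fewer than 3 usable C-alpha pairs")
  superpose(ca_wt[ok, , drop = FALSE], ca_mut[ok, , drop = FALSE])$rmsd
}
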