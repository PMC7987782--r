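# Solvent accessibility by the Shrake-Rupley rolling-probe method.

# Deterministic quasi-uniform points on the unit sphere (Fibonacci lattice).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Per-atom solvent-accessible surface area over heavy atoms.
atom_sasa <- function(xyz, radii, probe_radius = 1.4, n_points = 960) {
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  r_ext <- radii + probe_radius
  out <- numeric(n)
  # neighbour lists via a coarse distance screen
  maxr <- max(r_ext)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (r_ext[i] + maxr)^2 & d2 > 0)
    nb <- nb[sqrt(d2[nb]) < r_ext[i] + r_ext[nb]]
    p <- pts * r_ext[i]
    p[, 1] <- p[, 1] + xyz[i, 1]
    p[, 2] <- p[, 2] + xyz[i, 2]
    p[, 3] <- p[, 3] + xyz[i, 3]
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj2 <- (p[acc, 1] - xyz[j, 1])^2 + (p[acc, 2] - xyz[j, 2])^2 +
        (p[acc, 3] - xyz[j, 3])^2
      acc[acc] <- dj2 > r_ext[j]^2
    }
    out[i] <- 4 * pi * r_ext[i]^2 * sum(acc) / n_points
  }
  out
}

#' Per-residue solvent accessibility and exposure class
#'
#' Computes Shrake-Rupley solvent-accessible surface area over the heavy
#' atoms of a chain, converts it to relative accessibility against the
#' residue type's theoretical maximum, and classifies each residue as
#' buried (relative SASA below `rsa_threshold`) or exposed.
#'
#' @param chain a `chain_model` with at least one heavy atom.
#' @param probe_radius solvent probe radius in Angstrom (default 1.4, water).
#' @param rsa_threshold buried/exposed boundary on relative SASA
#'   (default 0.10).
#' @param n_points sphere sample points per atom (default 960).
#' @return data.frame of class `exposure_profile` with one row per residue:
#'   `res_index`, `seq_number`, `icode`, `name3`, `sasa` (square Angstrom),
#'   `rsa`, `class` (`"buried"`/`"exposed"`, `NA` when the residue type has
#'   no reference maximum).
#' @export
compute_exposure <- function(chain, probe_radius = 1.4, rsa_threshold = 0.10,
                             n_points = 960) {
  a <- chain$atoms[chain$atoms$is_heavy, , drop = FALSE]
  if (nrow(a) == 0) stop("chain has no heavy atoms")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  sasa_atom <- atom_sasa(xyz, vdw_radius(a$element),
                         probe_radius = probe_radius, n_points = n_points)
  res <- chain$residues
  sasa <- vapply(res$res_index,
                 function(i) sum(sasa_atom[a$res_index == i]), numeric(1))
  ref <- .aa()$max_asa[match(res$name3, .aa()$name3)]
  rsa <- sasa / ref
  cls <- ifelse(rsa < rsa_threshold, "buried", "exposed")
  if (anyNA(ref)) {
    message("no reference maximum SASA for: ",
            paste(unique(res$name3[is.na(ref)]), collapse = ", "))
    cls[is.na(ref)] <- NA_character_
  }
  out <- data.frame(res_index = res$res_index, seq_number = res$seq_number,
                    icode = res$icode, name3 = res$name3,
                    sasa = sasa, rsa = rsa, class = cls,
                    stringsAsFactors = FALSE)
  class(out) <- c("exposure_profile", "data.frame")
  out
}
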