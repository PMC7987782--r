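# Amino-acid reference data shared across modules.

#' Standard amino-acid table
#'
#' Three-letter and one-letter codes for the 20 standard amino acids,
#' side-chain heavy-atom counts, and theoretical maximum solvent-accessible
#' surface areas (Tien et al. 2013, theoretical column) used as the
#' denominator of relative solvent accessibility.
#'
#' @return A data.frame with columns `name3`, `name1`, `n_sidechain_heavy`,
#'   `max_asa` (square Angstrom).
#' @export
aa_table <- function() {
  data.frame(
    name3 = c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
              "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
              "TYR", "VAL"),
    name1 = c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
              "M", "F", "P", "S", "T", "W", "Y", "V"),
    n_sidechain_heavy = c(1L, 7L, 4L, 4L, 2L, 5L, 5L, 0L, 6L,
                          4L, 4L, 5L, 4L, 7L, 3L, 2L, 3L, 10L, 8L, 3L),
    max_asa = c(129, 274, 195, 193, 167, 225, 223, 104, 224,
                197, 201, 236, 224, 240, 159, 155, 172, 285, 263, 174),
    stringsAsFactors = FALSE
  )
}

# internal lookups
.aa <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- aa_table()
    tab
  }
})

aa_three_to_one <- function(name3) {
  tab <- .aa()
  tab$name1[match(toupper(name3), tab$name3)]
}

aa_one_to_three <- function(name1) {
  tab <- .aa()
  tab$name3[match(toupper(name1), tab$name1)]
}

is_standard_aa <- function(name3) toupper(name3) %in% .aa()$name3

# van der Waals radii by element (Angstrom); used for contacts' SASA only.
vdw_radius <- function(element) {
  radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
             SE = 1.90, H = 1.20, D = 1.20)
  r <- radii[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}
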