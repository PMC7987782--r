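# Reading, validating and writing protein chains.
#
# Parsing of the PDB/mmCIF formats is delegated to bio3d; this module owns
# the chain-level policy: altloc resolution, hydrogen flagging, dropping of
# hetero/non-standard residues, and the residue ordering contract.

#' Construct a chain model
#'
#' A chain model is the physical input to every downstream step: an ordered
#' set of resolved residues with their atom coordinates plus structure-level
#' quality metadata (resolution, refinement R factors).
#'
#' @param atoms data.frame with columns `res_index` (0-based position in the
#'   chain's resolved-residue order), `seq_number` (author residue number),
#'   `icode` (insertion code, "" if none), `name3`, `atom` (atom name),
#'   `element`, `x`, `y`, `z` (Angstrom), `occupancy`, `altloc`, `is_heavy`.
#' @param pdb_id accession string.
#' @param chain_id chain identifier.
#' @param resolution,r_free,r_work quality metadata (`NA` when absent).
#' @return An object of class `chain_model` with an `atoms` data.frame and a
#'   per-residue `residues` data.frame.
#' @export
chain_model <- function(atoms, pdb_id = "", chain_id = "A",
                        resolution = NA_real_, r_free = NA_real_,
                        r_work = NA_real_) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0)
  need <- c("res_index", "seq_number", "icode", "name3", "atom", "element",
            "x", "y", "z", "occupancy", "altloc", "is_heavy")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols))
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  atoms$res_index <- as.integer(atoms$res_index)
  atoms$seq_number <- as.integer(atoms$seq_number)
  residues <- unique(atoms[, c("res_index", "seq_number", "icode", "name3")])
  residues <- residues[order(residues$res_index), , drop = FALSE]
  rownames(residues) <- NULL
  if (!identical(residues$res_index, seq_len(nrow(residues)) - 1L))
    stop("res_index must be contiguous 0..n-1 in residue order")
  structure(
    list(pdb_id = pdb_id, chain_id = chain_id, atoms = atoms,
         residues = residues, resolution = resolution,
         r_free = r_free, r_work = r_work),
    class = "chain_model"
  )
}

#' @export
print.chain_model <- function(x, ...) {
  cat(sprintf("<chain_model> %s chain %s: %d residues, %d atoms (%d heavy)\n",
              x$pdb_id, x$chain_id, nrow(x$residues), nrow(x$atoms),
              sum(x$atoms$is_heavy)))
  if (!is.na(x$resolution))
    cat(sprintf("  resolution %.2f A, R_free %s, R_work %s\n", x$resolution,
                format(x$r_free), format(x$r_work)))
  invisible(x)
}

#' Number of residues in a chain
#' @param chain a `chain_model`.
#' @return integer residue count.
#' @export
n_residues <- function(chain) nrow(chain$residues)

#' One-letter sequence of a chain
#' @param chain a `chain_model`.
#' @return character scalar, one letter per resolved residue.
#' @export
chain_sequence <- function(chain) {
  paste(aa_three_to_one(chain$residues$name3), collapse = "")
}

# Residue identity key used for cross-referencing (author numbering).
residue_key <- function(seq_number, icode) paste0(seq_number, trimws(icode))

#' Coordinates of one named atom per residue
#'
#' @param chain a `chain_model`.
#' @param atom_name atom name to extract (default `"CA"`).
#' @return n_residues x 3 matrix; rows of residues lacking the atom are `NA`.
#' @export
atom_coords <- function(chain, atom_name = "CA") {
  m <- matrix(NA_real_, nrow = n_residues(chain), ncol = 3)
  sel <- chain$atoms$atom == atom_name & chain$atoms$is_heavy
  a <- chain$atoms[sel, , drop = FALSE]
  a <- a[!duplicated(a$res_index), , drop = FALSE]
  m[a$res_index + 1L, ] <- as.matrix(a[, c("x", "y", "z")])
  m
}

# ---------------------------------------------------------------------------
# Reading

.parse_pdb_header <- function(lines) {
  res <- NA_real_; rfree <- NA_real_; rwork <- NA_real_
  m <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(m)) {
    tail_txt <- sub(".*RESOLUTION\\.?", "", m[1])
    v <- regmatches(tail_txt, regexpr("[0-9]+\\.?[0-9]*", tail_txt))
    if (length(v)) res <- as.numeric(v)
  }
  m <- grep("^REMARK   3   R VALUE\\s+\\(WORKING SET\\)", lines, value = TRUE)
  if (length(m)) {
    v <- sub(".*:\\s*", "", m[1])
    rwork <- suppressWarnings(as.numeric(v))
  }
  m <- grep("^REMARK   3   FREE R VALUE\\s+:", lines, value = TRUE)
  if (length(m)) {
    v <- sub(".*:\\s*", "", m[1])
    rfree <- suppressWarnings(as.numeric(v))
  }
  list(resolution = res, r_free = rfree, r_work = rwork)
}

.parse_cif_header <- function(lines) {
  grab <- function(tag) {
    m <- grep(paste0("^", tag, "\\s"), lines, value = TRUE)
    if (!length(m)) return(NA_real_)
    suppressWarnings(as.numeric(sub(paste0("^", tag, "\\s+"), "", m[1])))
  }
  list(resolution = grab("_refine\\.ls_d_res_high"),
       r_free = grab("_refine\\.ls_R_factor_R_free"),
       r_work = grab("_refine\\.ls_R_factor_R_work"))
}

#' Read protein chains from a structure file
#'
#' Parses a PDB or mmCIF file and returns one `chain_model` per polymer
#' chain. Only the 20 standard amino acids are retained (selenomethionine is
#' mapped to methionine); ligands, waters and other non-standard residues are
#' dropped with a warning. Alternate locations are resolved to the highest
#' occupancy copy (first in file on ties). Hydrogens are kept but flagged
#' `is_heavy = FALSE` so contact and surface computations ignore them.
#'
#' @param path file path.
#' @param dialect `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @param pdb_id accession to record; defaults to the file stem.
#' @return list of `chain_model`, named by chain id.
#' @export
read_structure <- function(path, dialect = c("auto", "pdb", "mmcif"),
                           pdb_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  if (is.null(pdb_id)) pdb_id <- sub("\\.[^.]*$", "", basename(path))

  parsed <- tryCatch(
    if (dialect == "pdb") bio3d::read.pdb(path, verbose = FALSE)
    else bio3d::read.cif(path, verbose = FALSE),
    error = function(e) stop("cannot parse ", path, " as ", dialect, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  lines <- readLines(path, warn = FALSE)
  hdr <- if (dialect == "pdb") .parse_pdb_header(lines)
         else .parse_cif_header(lines)

  at <- parsed$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", path)
  # selenomethionine comes through as HETATM in some depositions
  mse <- parsed$atom[parsed$atom$type == "HETATM" &
                       parsed$atom$resid == "MSE", , drop = FALSE]
  if (nrow(mse)) at <- rbind(at, mse)
  at$resid[at$resid == "MSE"] <- "MET"

  nonstd <- unique(at$resid[!is_standard_aa(at$resid)])
  if (length(nonstd)) {
    warning("dropping non-standard residues: ",
            paste(nonstd, collapse = ", "))
    at <- at[is_standard_aa(at$resid), , drop = FALSE]
  }
  if (nrow(at) == 0) stop("no standard amino-acid residues in ", path)
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1

  chains <- list()
  for (ch in unique(at$chain)) {
    a <- at[at$chain == ch, , drop = FALSE]
    a$.file_order <- seq_len(nrow(a))
    # altloc: highest occupancy per (residue, atom name); first in file on ties
    key <- paste(a$resno, a$insert, a$elety, sep = "\r")
    ord <- order(key, -a$o, a$.file_order)
    a <- a[ord, , drop = FALSE]
    a <- a[!duplicated(key[ord]), , drop = FALSE]
    a <- a[order(a$.file_order), , drop = FALSE]
    if (nrow(a) == 0) {
      warning("chain ", ch, " has no standard residues; omitted")
      next
    }
    elem <- a$elesy
    if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
      elem <- sub("^[0-9]*", "", a$elety)
      elem <- substr(elem, 1, 1)
    }
    elem[is.na(elem) | elem == ""] <-
      substr(sub("^[0-9]*", "", a$elety[is.na(elem) | elem == ""]), 1, 1)
    is_heavy <- !(toupper(elem) %in% c("H", "D"))
    # residue order: author numbering with insertion codes, as deposited
    rkey <- paste(a$resno, a$insert, sep = "\r")
    ridx <- match(rkey, unique(rkey)) - 1L
    atoms <- data.frame(
      res_index = ridx, seq_number = a$resno, icode = a$insert,
      name3 = a$resid, atom = a$elety, element = toupper(elem),
      x = a$x, y = a$y, z = a$z, occupancy = a$o, altloc = a$alt,
      is_heavy = is_heavy, stringsAsFactors = FALSE
    )
    chains[[ch]] <- chain_model(atoms, pdb_id = pdb_id, chain_id = ch,
                                resolution = hdr$resolution,
                                r_free = hdr$r_free, r_work = hdr$r_work)
  }
  if (!length(chains)) stop("no usable chains in ", path)
  chains
}

#' Write a chain as fixed-column PDB text
#'
#' @param chain a `chain_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb_chain <- function(chain, path) {
  a <- chain$atoms
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.na(chain$resolution))
    writeLines(sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.",
                       chain$resolution), con)
  if (!is.na(chain$r_work))
    writeLines(sprintf(
      "REMARK   3   R VALUE            (WORKING SET) : %.3f",
      chain$r_work), con)
  if (!is.na(chain$r_free))
    writeLines(sprintf(
      "REMARK   3   FREE R VALUE                     : %.3f",
      chain$r_free), con)
  name_fmt <- function(nm) {
    # standard PDB justification: columns 13-16, element right-aligned at 14
    ifelse(nchar(nm) >= 4, substr(nm, 1, 4), sprintf(" %-3s", nm))
  }
  lines <- sprintf(
    "ATOM  %5d %s%s%3s %s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)), name_fmt(a$atom),
    ifelse(a$altloc == "", " ", substr(a$altloc, 1, 1)),
    a$name3, substr(chain$chain_id, 1, 1), a$seq_number,
    ifelse(a$icode == "", " ", substr(a$icode, 1, 1)),
    a$x, a$y, a$z, a$occupancy, 0, a$element)
  writeLines(lines, con)
  writeLines("END", con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Quality filter

#' Crystal-structure quality predicate
#'
#' A chain passes when its resolution is known and at or below
#' `max_resolution` and, when both refinement factors are present, the
#' difference `r_free - r_work` does not exceed `max_r_diff`. Missing
#' resolution fails; missing R factors pass with a warning.
#'
#' @param chain a `chain_model`.
#' @param max_resolution Angstrom cut-off (default 3.0).
#' @param max_r_diff maximum allowed `r_free - r_work` (default 0.05).
#' @return logical scalar.
#' @export
quality_filter <- function(chain, max_resolution = 3.0, max_r_diff = 0.05) {
  if (is.na(chain$resolution) || chain$resolution > max_resolution)
    return(FALSE)
  if (is.na(chain$r_free) || is.na(chain$r_work)) {
    warning("R factors missing for ", chain$pdb_id, " chain ",
            chain$chain_id, "; passing on resolution alone")
    return(TRUE)
  }
  # boundary inclusive up to floating-point representation of the fractions
  (chain$r_free - chain$r_work) <= max_r_diff + 1e-9
}
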