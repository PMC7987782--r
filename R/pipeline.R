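# Orchestration: full wildtype-vs-mutant comparison and batch runs.

#' Pipeline configuration
#'
#' Collects every tunable parameter of the comparison pipeline with its
#' default. `norm_table = NULL` derives the normalization table from the
#' two input chains themselves (the analysed "dataset" of a pairwise run),
#' which guarantees coverage of every occurring residue-type pair; pass a
#' `norm_table` or a TSV path to use a fixed table instead.
#'
#' @param cutoff contact distance, Angstrom.
#' @param min_seq_separation minimum sequence separation for contacts.
#' @param hub_threshold minimum hub degree.
#' @param norm_table `NULL`, a `norm_table`, or a TSV path.
#' @param align_mode `"sequence"` or `"sequence+refine"`.
#' @param probe_radius,rsa_threshold,sasa_points solvent accessibility
#'   parameters.
#' @param with_exposure compute per-residue exposure (default TRUE).
#' @param strict apply [quality_filter()] as a hard gate instead of a
#'   warning.
#' @param max_resolution,max_r_diff quality-filter parameters.
#' @param laplacian,eds_denominator,ewcs_form spectral score conventions,
#'   see [nds_score()].
#' @return named list of class `psn_config`.
#' @export
psn_config <- function(cutoff = 4.5, min_seq_separation = 2,
                       hub_threshold = 11, norm_table = NULL,
                       align_mode = "sequence", probe_radius = 1.4,
                       rsa_threshold = 0.10, sasa_points = 960,
                       with_exposure = TRUE, strict = FALSE,
                       max_resolution = 3.0, max_r_diff = 0.05,
                       laplacian = "normalized",
                       eds_denominator = "edges_once", ewcs_form = "rms") {
  structure(as.list(environment()), class = "psn_config")
}

.resolve_chain <- function(x, chain_id = NULL, dialect = "auto") {
  if (inherits(x, "chain_model")) return(x)
  chains <- read_structure(x, dialect = dialect)
  if (is.null(chain_id)) return(chains[[1]])
  if (!chain_id %in% names(chains))
    stop("chain ", chain_id, " not found in ", x)
  chains[[chain_id]]
}

#' Compare a wildtype/mutant structure pair
#'
#' Runs the full pipeline: read structures, quality screen, residue
#' mapping, PSN construction, restriction to the common node set, edge and
#' hub partitions, per-site deltas, spectral dissimilarity (NDS) and
#' C-alpha RMSD.
#'
#' @param wt,mut `chain_model` objects or structure file paths.
#' @param wt_chain,mut_chain chain ids when paths are given (default: first
#'   chain).
#' @param sites optional site annotation data.frame (see [site_deltas()])
#'   or TSV path with columns `seq_number`, `icode`, `role`.
#' @param config a [psn_config()].
#' @return list of class `comparison_report`: inputs and quality metadata,
#'   mapping summary, `ca_rmsd`, `nds` (an `nds_result`), `edges`
#'   (`edge_partition`), `hubs` (`hub_partition`), `site_deltas`, and
#'   provenance (parameters, package version, timestamp).
#' @export
compare_pair <- function(wt, mut, wt_chain = NULL, mut_chain = NULL,
                         sites = NULL, config = psn_config()) {
  wt <- .resolve_chain(wt, wt_chain)
  mut <- .resolve_chain(mut, mut_chain)
  if (is.character(sites)) {
    sites <- utils::read.table(sites, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  }
  for (side in list(wt = wt, mut = mut)) {
    ok <- suppressWarnings(quality_filter(side, config$max_resolution,
                                          config$max_r_diff))
    if (!ok) {
      msg <- sprintf("%s chain %s fails the quality filter", side$pdb_id,
                     side$chain_id)
      if (config$strict) stop(msg) else warning(msg)
    }
  }
  norm <- config$norm_table
  if (is.null(norm)) {
    norm <- derive_normalization(
      list(wt, mut), cutoff = config$cutoff,
      min_seq_separation = config$min_seq_separation)
  } else if (is.character(norm)) {
    norm <- read_norm_table(norm)
  }
  mapping <- align_chains(wt, mut, mode = config$align_mode)
  psn_wt <- build_psn(wt, norm, cutoff = config$cutoff,
                      min_seq_separation = config$min_seq_separation,
                      hub_threshold = config$hub_threshold)
  psn_mut <- build_psn(mut, norm, cutoff = config$cutoff,
                       min_seq_separation = config$min_seq_separation,
                       hub_threshold = config$hub_threshold)
  common <- restrict_common(psn_wt, psn_mut, mapping)
  edges <- partition_edges(common$wt, common$mut)
  hubs <- partition_hubs(common$wt, common$mut)
  exp_wt <- exp_mut <- NULL
  if (isTRUE(config$with_exposure)) {
    exp_wt <- compute_exposure(wt, config$probe_radius,
                               config$rsa_threshold, config$sasa_points)
    exp_mut <- compute_exposure(mut, config$probe_radius,
                                config$rsa_threshold, config$sasa_points)
  }
  deltas <- site_deltas(common$wt, common$mut, exp_wt, exp_mut, sites)
  nds_res <- nds_score(common$wt, common$mut, variant = config$laplacian,
                       eds_denominator = config$eds_denominator,
                       ewcs_form = config$ewcs_form)
  rmsd <- ca_rmsd(wt, mut, mapping)
  structure(
    list(inputs = list(wt_id = wt$pdb_id, wt_chain = wt$chain_id,
                       mut_id = mut$pdb_id, mut_chain = mut$chain_id),
         quality = list(
           wt = list(resolution = wt$resolution, r_free = wt$r_free,
                     r_work = wt$r_work),
           mut = list(resolution = mut$resolution, r_free = mut$r_free,
                      r_work = mut$r_work)),
         mapping = list(n = attr(mapping, "n"),
                        coverage_wt = attr(mapping, "coverage_wt"),
                        coverage_mut = attr(mapping, "coverage_mut")),
         ca_rmsd = rmsd, nds = nds_res, edges = edges, hubs = hubs,
         site_deltas = deltas, residue_mapping = mapping,
         provenance = list(
           config = config[setdiff(names(config), "norm_table")],
           norm_provenance = attr(norm, "provenance"),
           package_version = as.character(utils::packageVersion("psndelta")),
           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))),
    class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %s:%s vs %s:%s\n", x$inputs$wt_id,
              x$inputs$wt_chain, x$inputs$mut_id, x$inputs$mut_chain))
  cat(sprintf("  common residues n = %d (coverage %.2f / %.2f)\n",
              x$mapping$n, x$mapping$coverage_wt, x$mapping$coverage_mut))
  cat(sprintf("  C-alpha RMSD %.3f A | NDS %.4f (EDS %.4f, CRS %.4f, EWCS %.4f)\n",
              x$ca_rmsd, x$nds$nds, x$nds$eds, x$nds$crs, x$nds$ewcs))
  cat(sprintf("  edges: retained %d, lost %d, gained %d\n",
              x$edges$n_retained, x$edges$n_lost, x$edges$n_gained))
  cat(sprintf("  hubs:  retained %d, lost %d, gained %d\n",
              x$hubs$n_retained, x$hubs$n_lost, x$hubs$n_gained))
  invisible(x)
}

#' Serialize a comparison report to JSON
#'
#' @param report a `comparison_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  x <- unclass(report)
  x$nds <- unclass(x$nds)
  x$edges <- unclass(x$edges)
  x$hubs <- unclass(x$hubs)
  x$site_deltas <- as.data.frame(x$site_deltas)
  x$residue_mapping <- as.data.frame(x$residue_mapping)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' Batch comparison over a manifest of pairs
#'
#' @param manifest data.frame (or TSV path) with columns `pair_id`,
#'   `wt_path`, `mut_path` and optional `wt_chain`, `mut_chain`. Entries in
#'   the path columns may also be `chain_model` objects when a data.frame
#'   is supplied from code (list columns).
#' @param config a [psn_config()].
#' @param keep_going log failures and continue (default TRUE).
#' @return list with `reports` (named list of `comparison_report`) and
#'   `summary` (one row per successful pair: n, rmsd, nds components, edge
#'   and hub counts) carrying mean/SD attributes `mean_rmsd`, `sd_rmsd`,
#'   `mean_nds`, `sd_nds`.
#' @export
batch_compare <- function(manifest, config = psn_config(),
                          keep_going = TRUE) {
  if (is.character(manifest)) {
    manifest <- utils::read.table(manifest, sep = "\t", header = TRUE,
                                  stringsAsFactors = FALSE)
  }
  if (!nrow(manifest)) stop("empty manifest")
  reports <- list()
  rows <- list()
  for (k in seq_len(nrow(manifest))) {
    id <- as.character(manifest$pair_id[[k]])
    res <- tryCatch(
      compare_pair(manifest$wt_path[[k]], manifest$mut_path[[k]],
                   wt_chain = if ("wt_chain" %in% names(manifest))
                     manifest$wt_chain[[k]] else NULL,
                   mut_chain = if ("mut_chain" %in% names(manifest))
                     manifest$mut_chain[[k]] else NULL,
                   config = config),
      error = function(e) e)
    if (inherits(res, "error")) {
      if (!keep_going) stop("pair ", id, ": ", conditionMessage(res))
      message("pair ", id, " failed: ", conditionMessage(res))
      next
    }
    reports[[id]] <- res
    rows[[id]] <- data.frame(
      pair_id = id, n = res$mapping$n, ca_rmsd = res$ca_rmsd,
      nds = res$nds$nds, eds = res$nds$eds, crs = res$nds$crs,
      ewcs = res$nds$ewcs, edges_lost = res$edges$n_lost,
      edges_gained = res$edges$n_gained, hubs_lost = res$hubs$n_lost,
      hubs_gained = res$hubs$n_gained, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no pair in the manifest could be compared")
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  attr(summary, "mean_rmsd") <- mean(summary$ca_rmsd)
  attr(summary, "sd_rmsd") <- stats::sd(summary$ca_rmsd)
  attr(summary, "mean_nds") <- mean(summary$nds)
  attr(summary, "sd_nds") <- stats::sd(summary$nds)
  list(reports = reports, summary = summary)
}

#' Download a PDB entry (requires network access)
#'
#' Convenience fetcher for reproducing published per-case comparisons; the
#' core pipeline itself is offline-complete.
#'
#' @param pdb_id four-character accession.
#' @param dir destination directory.
#' @return path to the downloaded file.
#' @export
fetch_pdb <- function(pdb_id, dir = tempdir()) {
  dest <- file.path(dir, paste0(toupper(pdb_id), ".pdb"))
  if (file.exists(dest)) return(dest)
  url <- paste0("https://files.rcsb.org/download/", toupper(pdb_id), ".pdb")
  utils::download.file(url, dest, quiet = TRUE, mode = "wb")
  dest
}
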