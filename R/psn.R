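# Weighted all-atom protein structure network construction.
#
# Two residues are linked when any pair of their heavy atoms lies within the
# contact cut-off (default 4.5 A) and the residues are non-adjacent in
# sequence. The edge weight is the atom-contact count normalised by the
# highest count ever observed for that amino-acid-type pair.

#' Count heavy-atom contacts between non-adjacent residues
#'
#' For every unordered residue pair separated by at least
#' `min_seq_separation` positions in the resolved-residue order, counts the
#' heavy-atom pairs at Euclidean distance `<= cutoff`. Pairs with no contact
#' are omitted.
#'
#' @param chain a `chain_model`.
#' @param cutoff contact distance in Angstrom (default 4.5, closed boundary).
#' @param min_seq_separation minimum |sequence index difference| (default 2,
#'   i.e. residues i and i+1 never form an edge).
#' @return data.frame with columns `res_a`, `res_b` (0-based sequence
#'   indices, `res_a < res_b`), `name3_a`, `name3_b`, `atom_pair_count`.
#' @export
find_atom_contacts <- function(chain, cutoff = 4.5, min_seq_separation = 2) {
  a <- chain$atoms[chain$atoms$is_heavy, , drop = FALSE]
  if (nrow(a) == 0) stop("chain has no heavy atoms")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  ridx <- a$res_index
  n_at <- nrow(a)
  n_res <- n_residues(chain)
  cut2 <- cutoff^2
  counts <- new.env(parent = emptyenv())
  tally <- integer(0)
  keys <- integer(0)
  # block-wise pairwise distances to bound memory on large chains
  block <- 1500L
  starts <- seq(1L, n_at, by = block)
  for (bi in starts) {
    ii <- bi:min(bi + block - 1L, n_at)
    for (bj in starts) {
      if (bj < bi) next
      jj <- bj:min(bj + block - 1L, n_at)
      d2 <- outer(rowSums(xyz[ii, , drop = FALSE]^2),
                  rowSums(xyz[jj, , drop = FALSE]^2), "+") -
        2 * tcrossprod(xyz[ii, , drop = FALSE], xyz[jj, , drop = FALSE])
      hit <- which(d2 <= cut2, arr.ind = TRUE)
      if (!nrow(hit)) next
      ai <- ii[hit[, 1]]; aj <- jj[hit[, 2]]
      keep <- ai < aj & abs(ridx[ai] - ridx[aj]) >= min_seq_separation
      if (!any(keep)) next
      ra <- pmin(ridx[ai[keep]], ridx[aj[keep]])
      rb <- pmax(ridx[ai[keep]], ridx[aj[keep]])
      k <- ra * n_res + rb
      tk <- table(k)
      keys <- c(keys, as.integer(names(tk)))
      tally <- c(tally, as.integer(tk))
    }
  }
  if (!length(keys)) {
    return(data.frame(res_a = integer(0), res_b = integer(0),
                      name3_a = character(0), name3_b = character(0),
                      atom_pair_count = integer(0)))
  }
  agg <- tapply(tally, keys, sum)
  key <- as.integer(names(agg))
  res_a <- key %/% n_res
  res_b <- key %% n_res
  out <- data.frame(
    res_a = res_a, res_b = res_b,
    name3_a = chain$residues$name3[res_a + 1L],
    name3_b = chain$residues$name3[res_b + 1L],
    atom_pair_count = as.integer(agg), stringsAsFactors = FALSE)
  out <- out[order(out$res_a, out$res_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# Normalization table

#' Derive an edge-weight normalization table from a structure set
#'
#' The normalization value for an amino-acid-type pair is the highest
#' atom-contact count observed between residues of those types anywhere in
#' the supplied chains; it is the denominator of the edge-weight formula.
#'
#' @param chains list of `chain_model` (callers apply [quality_filter()]
#'   beforehand when emulating a curated structure set).
#' @param cutoff contact distance in Angstrom.
#' @param min_seq_separation as in [find_atom_contacts()].
#' @return A `norm_table`: symmetric 20x20 matrix of positive integers with
#'   three-letter dimnames; pairs never observed are `NA`. The provenance
#'   string is stored in `attr(, "provenance")`.
#' @export
derive_normalization <- function(chains, cutoff = 4.5,
                                 min_seq_separation = 2) {
  if (!length(chains)) stop("empty chain collection")
  types <- .aa()$name3
  m <- matrix(NA_real_, 20, 20, dimnames = list(types, types))
  for (chain in chains) {
    ct <- find_atom_contacts(chain, cutoff = cutoff,
                             min_seq_separation = min_seq_separation)
    for (k in seq_len(nrow(ct))) {
      t1 <- ct$name3_a[k]; t2 <- ct$name3_b[k]
      cur <- m[t1, t2]
      if (is.na(cur) || ct$atom_pair_count[k] > cur) {
        m[t1, t2] <- ct$atom_pair_count[k]
        m[t2, t1] <- ct$atom_pair_count[k]
      }
    }
  }
  attr(m, "provenance") <- sprintf(
    "derive_normalization over %d chains, cutoff %.2f A", length(chains),
    cutoff)
  class(m) <- c("norm_table", class(m))
  m
}

#' Write / read a normalization table as TSV
#'
#' 20x20 tab-separated matrix with three-letter row and column labels.
#'
#' @param norm a `norm_table`.
#' @param path file path.
#' @return `path` (write) or a `norm_table` (read).
#' @export
write_norm_table <- function(norm, path) {
  utils::write.table(unclass(norm)[.aa()$name3, .aa()$name3], path,
                     sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_norm_table
#' @export
read_norm_table <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  if (!identical(sort(rownames(m)), sort(colnames(m))))
    stop("normalization table rows/columns disagree")
  m <- m[rownames(m), rownames(m)]
  if (any(!is.na(m) & m < 1)) stop("normalization values must be >= 1")
  if (any(abs(m - t(m)) > 0, na.rm = TRUE))
    stop("normalization table is not symmetric")
  attr(m, "provenance") <- paste0("read from ", path)
  class(m) <- c("norm_table", class(m))
  m
}

#' Default normalization table
#'
#' The package's bundled table, derived by [derive_normalization()] from the
#' synthetic fixture set ([fixture_chains()]). Reproducing any published
#' absolute NDS magnitude depends on the normalization table in use; edge
#' counts and node degrees do not.
#'
#' @return a `norm_table`.
#' @export
default_normalization <- function() {
  path <- system.file("extdata", "default_norm_synthetic.tsv",
                      package = "psndelta")
  if (nzchar(path)) return(read_norm_table(path))
  derive_normalization(fixture_chains())
}

# ---------------------------------------------------------------------------
# Graph construction

#' Build the weighted protein structure network of a chain
#'
#' One node per resolved residue (contact-less residues remain as isolated
#' nodes). Edge weight is `atom_pair_count / norm[type_a, type_b]`, clamped
#' to 1 with a warning if a count exceeds the table maximum. A node is a hub
#' when its degree (edge count) is at least `hub_threshold`.
#'
#' @param chain a `chain_model`.
#' @param norm a `norm_table`; every type pair occurring in the chain's
#'   contacts must be present, otherwise an error names the missing pair.
#' @param cutoff,min_seq_separation contact criterion, see
#'   [find_atom_contacts()].
#' @param hub_threshold minimum degree of a hub (default 11).
#' @return An object of class `psn`: node table, symmetric weighted
#'   adjacency matrix, raw atom-contact count matrix, and parameters.
#' @export
build_psn <- function(chain, norm = default_normalization(), cutoff = 4.5,
                      min_seq_separation = 2, hub_threshold = 11) {
  ct <- find_atom_contacts(chain, cutoff = cutoff,
                           min_seq_separation = min_seq_separation)
  n <- n_residues(chain)
  labels <- residue_key(chain$residues$seq_number, chain$residues$icode)
  adj <- matrix(0, n, n, dimnames = list(labels, labels))
  cnt <- matrix(0L, n, n, dimnames = list(labels, labels))
  if (nrow(ct)) {
    denom <- unclass(norm)[cbind(ct$name3_a, ct$name3_b)]
    if (anyNA(denom)) {
      bad <- which(is.na(denom))[1]
      stop("normalization table has no entry for pair ",
           ct$name3_a[bad], "-", ct$name3_b[bad])
    }
    w <- ct$atom_pair_count / denom
    if (any(w > 1)) {
      warning(sum(w > 1), " edge weight(s) exceeded 1 and were clamped ",
              "(contact count above the normalization maximum)")
      w <- pmin(w, 1)
    }
    ia <- ct$res_a + 1L; ib <- ct$res_b + 1L
    adj[cbind(ia, ib)] <- w; adj[cbind(ib, ia)] <- w
    cnt[cbind(ia, ib)] <- ct$atom_pair_count
    cnt[cbind(ib, ia)] <- ct$atom_pair_count
  }
  nodes <- data.frame(
    node = labels, res_index = chain$residues$res_index,
    seq_number = chain$residues$seq_number, icode = chain$residues$icode,
    name3 = chain$residues$name3, stringsAsFactors = FALSE)
  new_psn(nodes, adj, cnt, hub_threshold = hub_threshold, cutoff = cutoff,
          chain_id = chain$chain_id, pdb_id = chain$pdb_id)
}

new_psn <- function(nodes, adjacency, counts = NULL, hub_threshold = 11,
                    cutoff = NA_real_, chain_id = "", pdb_id = "") {
  stopifnot(nrow(adjacency) == nrow(nodes),
            isTRUE(all.equal(adjacency, t(adjacency))),
            all(diag(adjacency) == 0), all(adjacency >= 0))
  structure(
    list(nodes = nodes, adjacency = adjacency, counts = counts,
         hub_threshold = hub_threshold, cutoff = cutoff,
         chain_id = chain_id, pdb_id = pdb_id),
    class = "psn")
}

#' @export
print.psn <- function(x, ...) {
  nm <- node_metrics(x)
  cat(sprintf(
    "<psn> %s chain %s: %d nodes, %d edges, %d hubs (degree >= %d)\n",
    x$pdb_id, x$chain_id, nrow(x$nodes), psn_edge_count(x), sum(nm$hub),
    x$hub_threshold))
  invisible(x)
}

#' Per-node degree, strength and hub flag
#'
#' Degree is the number of incident edges; strength is the sum of incident
#' edge weights; a hub has degree at or above the network's hub threshold.
#'
#' @param psn a `psn`.
#' @return data.frame with columns `node`, `degree`, `strength`, `hub`, in
#'   node order.
#' @export
node_metrics <- function(psn) {
  a <- psn$adjacency
  data.frame(node = psn$nodes$node,
             degree = as.integer(rowSums(a > 0)),
             strength = rowSums(a),
             hub = rowSums(a > 0) >= psn$hub_threshold,
             stringsAsFactors = FALSE)
}

#' Edge list of a PSN
#' @param psn a `psn`.
#' @return data.frame `node_a`, `node_b`, `atom_pair_count`, `weight` with
#'   each undirected edge listed once.
#' @export
psn_edges <- function(psn) {
  a <- psn$adjacency
  idx <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
  cnt <- if (is.null(psn$counts)) rep(NA_integer_, nrow(idx))
         else psn$counts[idx]
  out <- data.frame(node_a = psn$nodes$node[idx[, 1]],
                    node_b = psn$nodes$node[idx[, 2]],
                    atom_pair_count = cnt, weight = a[idx],
                    stringsAsFactors = FALSE)
  out[order(out$node_a, out$node_b), , drop = FALSE]
}

psn_edge_count <- function(psn) sum(psn$adjacency > 0) / 2

#' Export a PSN
#'
#' `write_psn_graphml()` writes GraphML via igraph; `write_psn_edges()`
#' writes the edge list as TSV.
#'
#' @param psn a `psn`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_psn_graphml <- function(psn, path) {
  g <- igraph::graph_from_adjacency_matrix(psn$adjacency, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_psn_graphml
#' @export
write_psn_edges <- function(psn, path) {
  utils::write.table(psn_edges(psn), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
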