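# Wildtype/mutant network comparison on the common node set: edge and hub
# partitions, per-site degree/strength/exposure deltas.

#' Restrict two PSNs to their topologically equivalent residues
#'
#' Induces both networks on the mapped residue pairs, in mapping order, and
#' unifies the node labels to the pair index so downstream comparisons
#' operate on identical node sets. The mutated position is a common node:
#' node identity is positional, not residue-type-based.
#'
#' @param psn_wt,psn_mut `psn` objects.
#' @param mapping a `residue_mapping` whose residues all exist in the
#'   respective PSNs.
#' @return list with elements `wt` and `mut`, both `psn` objects on
#'   `attr(mapping, "n")` nodes labelled `p1..pn`; node tables retain the
#'   original residue identities of each side.
#' @export
restrict_common <- function(psn_wt, psn_mut, mapping) {
  iw <- match(mapping$wt_index, psn_wt$nodes$res_index)
  im <- match(mapping$mut_index, psn_mut$nodes$res_index)
  if (anyNA(iw)) stop("mapped wildtype residue missing from its PSN")
  if (anyNA(im)) stop("mapped mutant residue missing from its PSN")
  labels <- paste0("p", seq_len(nrow(mapping)))
  take <- function(psn, idx, side_nodes) {
    adj <- psn$adjacency[idx, idx, drop = FALSE]
    dimnames(adj) <- list(labels, labels)
    cnt <- if (is.null(psn$counts)) NULL else {
      cm <- psn$counts[idx, idx, drop = FALSE]
      dimnames(cm) <- list(labels, labels)
      cm
    }
    nodes <- cbind(data.frame(node = labels, stringsAsFactors = FALSE),
                   side_nodes)
    new_psn(nodes, adj, cnt, hub_threshold = psn$hub_threshold,
            cutoff = psn$cutoff, chain_id = psn$chain_id,
            pdb_id = psn$pdb_id)
  }
  wt_nodes <- psn_wt$nodes[iw, c("res_index", "seq_number", "icode",
                                 "name3")]
  mut_nodes <- psn_mut$nodes[im, c("res_index", "seq_number", "icode",
                                   "name3")]
  rownames(wt_nodes) <- rownames(mut_nodes) <- NULL
  list(wt = take(psn_wt, iw, wt_nodes), mut = take(psn_mut, im, mut_nodes))
}

.check_common <- function(psn_wt, psn_mut) {
  if (!identical(psn_wt$nodes$node, psn_mut$nodes$node))
    stop("PSNs are not on an identical node set; run restrict_common first")
}

#' Partition edges into retained / lost / gained
#'
#' Edge identity is decided by node-pair presence (nonzero weight), not by
#' weight equality: edges present in both networks are retained, edges
#' unique to the wildtype are lost in the mutant, edges unique to the mutant
#' are gained. Weight changes on retained edges are reported separately in
#' the `dweight` table.
#'
#' @param psn_wt,psn_mut `psn` objects on an identical node set.
#' @return list of class `edge_partition`: data.frames `retained`, `lost`,
#'   `gained` (columns `node_a`, `node_b`), counts `n_retained`, `n_lost`,
#'   `n_gained`, and `dweight` (retained edges with `weight_wt`,
#'   `weight_mut`, `dweight`).
#' @export
partition_edges <- function(psn_wt, psn_mut) {
  .check_common(psn_wt, psn_mut)
  a <- psn_wt$adjacency; b <- psn_mut$adjacency
  up <- upper.tri(a)
  in_a <- up & a > 0; in_b <- up & b > 0
  as_edges <- function(mask) {
    idx <- which(mask, arr.ind = TRUE)
    data.frame(node_a = rownames(a)[idx[, 1]],
               node_b = colnames(a)[idx[, 2]], stringsAsFactors = FALSE)
  }
  ret_mask <- in_a & in_b
  ret <- as_edges(ret_mask)
  idx <- which(ret_mask, arr.ind = TRUE)
  dweight <- data.frame(ret, weight_wt = a[idx], weight_mut = b[idx],
                        dweight = b[idx] - a[idx])
  structure(
    list(retained = ret, lost = as_edges(in_a & !in_b),
         gained = as_edges(in_b & !in_a),
         n_retained = sum(ret_mask), n_lost = sum(in_a & !in_b),
         n_gained = sum(in_b & !in_a), dweight = dweight),
    class = "edge_partition")
}

#' @export
print.edge_partition <- function(x, ...) {
  cat(sprintf("<edge_partition> retained %d, lost %d, gained %d\n",
              x$n_retained, x$n_lost, x$n_gained))
  invisible(x)
}

#' Partition hubs into retained / lost / gained
#'
#' Hubs are computed on the two (restricted) networks at their shared hub
#' threshold and partitioned by membership: present in both (retained),
#' unique to the wildtype (lost), unique to the mutant (gained).
#'
#' @param psn_wt,psn_mut `psn` objects on an identical node set with the
#'   same `hub_threshold`.
#' @return list of class `hub_partition`: node vectors `retained`, `lost`,
#'   `gained` and their counts.
#' @export
partition_hubs <- function(psn_wt, psn_mut) {
  .check_common(psn_wt, psn_mut)
  if (psn_wt$hub_threshold != psn_mut$hub_threshold)
    stop("hub thresholds differ between the two PSNs")
  hw <- node_metrics(psn_wt); hm <- node_metrics(psn_mut)
  in_a <- hw$node[hw$hub]; in_b <- hm$node[hm$hub]
  structure(
    list(retained = intersect(in_a, in_b),
         lost = setdiff(in_a, in_b),
         gained = setdiff(in_b, in_a),
         n_retained = length(intersect(in_a, in_b)),
         n_lost = length(setdiff(in_a, in_b)),
         n_gained = length(setdiff(in_b, in_a))),
    class = "hub_partition")
}

#' @export
print.hub_partition <- function(x, ...) {
  cat(sprintf("<hub_partition> retained %d, lost %d, gained %d\n",
              x$n_retained, x$n_lost, x$n_gained))
  invisible(x)
}

#' Per-site degree, strength and exposure changes
#'
#' One row per common node with wildtype and mutant degree, strength, their
#' differences, exposure class on each side (when profiles are supplied) and
#' a role tag from the site annotation.
#'
#' @param psn_wt,psn_mut `psn` objects on an identical node set (from
#'   [restrict_common()], whose node tables carry the original residue
#'   identities).
#' @param exposure_wt,exposure_mut optional `exposure_profile` objects of
#'   the full chains.
#' @param sites optional data.frame with columns `seq_number`, `icode`
#'   (optional), `role` (`"mutation_site"` or `"functional_site"`),
#'   addressed against the wildtype numbering. Sites not in the common node
#'   set produce a warning and a row of `NA` values.
#' @return data.frame of class `site_delta_table`; attribute
#'   `ddegree_range_by_role` summarises min/max ddegree per role.
#' @export
site_deltas <- function(psn_wt, psn_mut, exposure_wt = NULL,
                        exposure_mut = NULL, sites = NULL) {
  .check_common(psn_wt, psn_mut)
  mw <- node_metrics(psn_wt); mm <- node_metrics(psn_mut)
  wt_key <- residue_key(psn_wt$nodes$seq_number, psn_wt$nodes$icode)
  mut_key <- residue_key(psn_mut$nodes$seq_number, psn_mut$nodes$icode)
  role <- rep("other", nrow(mw))
  if (!is.null(sites) && nrow(sites)) {
    icode <- if ("icode" %in% names(sites)) sites$icode else ""
    skey <- residue_key(sites$seq_number, icode)
    hit <- match(skey, wt_key)
    if (anyNA(hit))
      warning("site(s) not in the common node set: ",
              paste(skey[is.na(hit)], collapse = ", "))
    role[hit[!is.na(hit)]] <- sites$role[!is.na(hit)]
  }
  lookup_class <- function(profile, key) {
    if (is.null(profile)) return(rep(NA_character_, length(key)))
    pkey <- residue_key(profile$seq_number, profile$icode)
    profile$class[match(key, pkey)]
  }
  out <- data.frame(
    node = mw$node, wt_res = wt_key, mut_res = mut_key, role = role,
    name3_wt = psn_wt$nodes$name3, name3_mut = psn_mut$nodes$name3,
    degree_wt = mw$degree, degree_mut = mm$degree,
    ddegree = mm$degree - mw$degree,
    strength_wt = mw$strength, strength_mut = mm$strength,
    dstrength = mm$strength - mw$strength,
    exposure_wt = lookup_class(exposure_wt, wt_key),
    exposure_mut = lookup_class(exposure_mut, mut_key),
    stringsAsFactors = FALSE)
  if (!is.null(sites) && nrow(sites)) {
    missing_sites <- sites[is.na(match(
      residue_key(sites$seq_number,
                  if ("icode" %in% names(sites)) sites$icode else ""),
      wt_key)), , drop = FALSE]
    if (nrow(missing_sites)) {
      na_row <- out[rep(NA_integer_, nrow(missing_sites)), , drop = FALSE]
      na_row$wt_res <- residue_key(
        missing_sites$seq_number,
        if ("icode" %in% names(missing_sites)) missing_sites$icode else "")
      na_row$role <- missing_sites$role
      out <- rbind(out, na_row)
      rownames(out) <- NULL
    }
  }
  rng <- do.call(rbind, lapply(split(out$ddegree, out$role), function(d) {
    d <- d[!is.na(d)]
    if (!length(d)) return(data.frame(min_ddegree = NA_integer_,
                                      max_ddegree = NA_integer_))
    data.frame(min_ddegree = min(d), max_ddegree = max(d))
  }))
  attr(out, "ddegree_range_by_role") <- rng
  class(out) <- c("site_delta_table", "data.frame")
  out
}
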