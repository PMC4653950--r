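# TSS model: tag normalization, cluster calling, representative TSSs,
# breadth, activity, and cross-strain positional conservation.

#' Normalize raw 5'-tag counts to a fixed library total
#'
#' Counts are scaled so the library sums to `target_total` tags (default
#' 300,000, the working single-cell mRNA complement), putting expression on
#' an approximate cell-copy scale: 30 raw tags in a 9-million-tag library
#' become 1.0, and 2 tags among 6 million become 0.1, the activity cutoff.
#'
#' @param tags data frame with columns `pos`, `strand`, `count`.
#' @param target_total normalization target.
#' @return the input with an added `expr` column; the `expr` column sums to
#'   `target_total`.
#' @export
normalize_tags <- function(tags, target_total = 300000) {
  total <- sum(tags$count)
  if (!is.finite(total) || total <= 0) {
    stop("empty tag library: total raw count must be positive")
  }
  tags$expr <- tags$count * target_total / total
  tags
}

#' Average normalized expression across tissues
#'
#' Position-and-strand-wise arithmetic mean over the supplied tracks; a
#' position absent from a track contributes 0 for that tissue.
#'
#' @param tracks list of normalized tag data frames (`pos`, `strand`,
#'   `expr`).
#' @return data frame `pos`, `strand`, `expr` (the mean), sorted by
#'   position.
#' @export
merge_tissue_expression <- function(tracks) {
  k <- length(tracks)
  stopifnot(k >= 1L)
  all <- do.call(rbind, lapply(tracks, function(d) {
    data.frame(pos = d$pos, strand = d$strand, expr = d$expr,
               stringsAsFactors = FALSE)
  }))
  agg <- stats::aggregate(expr ~ pos + strand, data = all, FUN = sum)
  agg$expr <- agg$expr / k
  agg <- agg[order(agg$pos, agg$strand), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Call TSS clusters from a merged expression track
#'
#' Positions with merged expression above `min_expr` are grouped, per
#' strand, so that neighbouring cluster members are at most `gap` bp apart
#' and different clusters are separated by more than `gap` bp.
#'
#' @param merged merged track from [merge_tissue_expression()].
#' @param min_expr exclusive expression threshold (default 0.1).
#' @param gap maximum within-cluster neighbour distance in bp (default 20).
#' @return data frame `pos`, `strand`, `expr`, `cluster` (integer id);
#'   zero rows when nothing passes the threshold.
#' @export
call_tss_clusters <- function(merged, min_expr = 0.1, gap = 20L) {
  stopifnot(nrow(merged) >= 1L)
  keep <- merged$expr > min_expr
  d <- merged[keep, , drop = FALSE]
  if (nrow(d) == 0L) {
    d$cluster <- integer(0)
    return(d)
  }
  d <- d[order(d$strand, d$pos), , drop = FALSE]
  new_cluster <- c(TRUE, diff(d$pos) > gap | d$strand[-1L] != d$strand[-nrow(d)])
  d$cluster <- cumsum(new_cluster)
  d <- d[order(d$pos, d$strand), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Select representative TSSs from called clusters
#'
#' Each cluster nominates its highest-expression position (leftmost on
#' ties); candidates are then retained greedily in descending expression
#' order, discarding any candidate within `min_dist` bp of an
#' already-retained representative, so that the final set is pairwise more
#' than `min_dist` bp apart and maximal under that rule.
#'
#' @param clusters output of [call_tss_clusters()].
#' @param min_dist exclusion radius in bp (default 500).
#' @return data frame `pos`, `strand`, `expr`, `cluster`, sorted by
#'   position, with one row per retained representative.
#' @export
select_representative_tss <- function(clusters, min_dist = 500L) {
  if (nrow(clusters) == 0L) return(clusters)
  parts <- split(seq_len(nrow(clusters)), clusters$cluster)
  cand_idx <- vapply(parts, function(ii) {
    e <- clusters$expr[ii]
    ii[which(e == max(e))[1L]]   # leftmost maximum (rows sorted by pos)
  }, integer(1))
  cand <- clusters[cand_idx, , drop = FALSE]
  ord <- order(-cand$expr, cand$pos)
  cand <- cand[ord, , drop = FALSE]
  kept_pos <- numeric(0)
  kept <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (length(kept_pos) == 0L ||
        min(abs(cand$pos[i] - kept_pos)) > min_dist) {
      kept[i] <- TRUE
      kept_pos <- c(kept_pos, cand$pos[i])
    }
  }
  res <- cand[kept, , drop = FALSE]
  res <- res[order(res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Breadth of a TSS cluster in one tissue
#'
#' Tags are accumulated from the cluster's 5' end to its 3' end
#' (strand-oriented); the 5' and 3' cluster ends are the first positions at
#' which the cumulative sum reaches 5 % and 95 % of the total, and the
#' breadth is the distance between them.  Zero when the cluster carries no
#' expression in the tissue.
#'
#' @param pos member positions of one cluster.
#' @param expr matching per-position expression in the focal tissue.
#' @param strand cluster strand (`"+"` or `"-"`).
#' @return breadth in bp.
#' @export
cluster_breadth <- function(pos, expr, strand = "+") {
  total <- sum(expr)
  if (!is.finite(total) || total <= 0) return(0)
  ord <- order(pos, decreasing = (strand == "-"))
  p <- pos[ord]
  cum <- cumsum(expr[ord])
  e5 <- p[which(cum >= 0.05 * total)[1L]]
  e3 <- p[which(cum >= 0.95 * total)[1L]]
  abs(e3 - e5)
}

#' Per-tissue activity sets and Venn-region counts
#'
#' A representative TSS is active in a tissue when its expression there is
#' at least `min_expr` (boundary inclusive).
#'
#' @param expr_matrix numeric matrix, one row per representative TSS and one
#'   column per tissue.
#' @param min_expr activity cutoff (default 0.1).
#' @return list with `active` (logical matrix), `sets` (row indices active
#'   per tissue) and `venn` (counts of the 7 non-empty membership patterns,
#'   named by binary pattern over the tissue columns).
#' @export
active_tss_sets <- function(expr_matrix, min_expr = 0.1) {
  act <- expr_matrix >= min_expr
  k <- ncol(act)
  pattern <- apply(act, 1L, function(r) paste(as.integer(r), collapse = ""))
  all_patterns <- apply(expand.grid(rep(list(0:1), k))[, k:1, drop = FALSE],
                        1L, paste, collapse = "")
  all_patterns <- setdiff(all_patterns, paste(rep("0", k), collapse = ""))
  venn <- vapply(all_patterns, function(p) sum(pattern == p), integer(1))
  sets <- lapply(seq_len(k), function(j) which(act[, j]))
  names(sets) <- colnames(expr_matrix)
  list(active = act, sets = sets, venn = venn)
}

#' Positional conservation of representative TSSs between strains
#'
#' Maps each focal-strain representative into the sister strain's
#' coordinates and measures the distance to the nearest sister
#' representative, reporting the cumulative fraction at the supplied
#' thresholds and, when group labels are given, a one-tailed rank-sum test
#' of whether group-1 (nucleocyclic) TSSs are more positionally conserved
#' (smaller distances) than the rest.
#'
#' @param focal_pos positions of focal-strain representatives.
#' @param sister_pos positions of sister-strain representatives.
#' @param coord_map `NULL` for the identity map, or a function mapping
#'   focal coordinates to sister coordinates (`NA` = unmapped, excluded and
#'   counted).
#' @param groups optional integer group labels (1 = nucleocyclic) parallel
#'   to `focal_pos`.
#' @param thresholds distance thresholds for the cumulative fractions.
#' @return list with `distance` (per mapped TSS), `cum_fraction` (named
#'   fractions), `n_excluded`, and `group_test` (rank-sum result or `NULL`).
#' @export
compare_strain_tss_distance <- function(focal_pos, sister_pos,
                                        coord_map = NULL, groups = NULL,
                                        thresholds = c(0, 10, 50, 100)) {
  mapped <- if (is.null(coord_map)) focal_pos else coord_map(focal_pos)
  ok <- !is.na(mapped)
  n_excluded <- sum(!ok)
  dist <- nearest_distance(mapped[ok], sister_pos)
  cum <- vapply(thresholds, function(th) mean(dist <= th), numeric(1))
  names(cum) <- paste0("le_", thresholds)
  group_test <- NULL
  if (!is.null(groups)) {
    gg <- groups[ok]
    if (sum(gg == 1L, na.rm = TRUE) >= 2L &&
        sum(gg > 1L, na.rm = TRUE) >= 2L) {
      group_test <- rank_sum_test(dist[which(gg == 1L)],
                                  dist[which(gg > 1L)],
                                  alternative = "less")
    }
  }
  list(distance = dist, cum_fraction = cum, n_excluded = n_excluded,
       group_test = group_test)
}

#' Build the per-representative TSS table for one strain
#'
#' Convenience assembly used by the pipeline: per-tissue cluster expression
#' (normalized sum over cluster members), breadth, and activity for every
#' representative TSS.
#'
#' @param reps representative TSSs from [select_representative_tss()].
#' @param clusters all called clusters (the representatives' clusters are
#'   looked up by id).
#' @param tissue_tracks named list (per tissue) of normalized tag data
#'   frames (`pos`, `strand`, `expr`).
#' @param min_expr activity cutoff.
#' @return data frame: `id`, `pos`, `strand`, `cluster`, and per tissue
#'   `expr_<tissue>`, `breadth_<tissue>`, `active_<tissue>`.
#' @export
representative_tss_table <- function(reps, clusters, tissue_tracks,
                                     min_expr = 0.1) {
  out <- data.frame(id = seq_len(nrow(reps)), pos = reps$pos,
                    strand = reps$strand, cluster = reps$cluster,
                    stringsAsFactors = FALSE)
  members <- split(seq_len(nrow(clusters)), clusters$cluster)
  cluster_key <- paste(clusters$pos, clusters$strand)
  for (t in names(tissue_tracks)) {
    tr <- tissue_tracks[[t]]
    hit <- match(cluster_key, paste(tr$pos, tr$strand))
    member_expr <- ifelse(is.na(hit), 0, tr$expr[hit])
    expr_t <- numeric(nrow(reps))
    breadth_t <- numeric(nrow(reps))
    for (i in seq_len(nrow(reps))) {
      ii <- members[[as.character(reps$cluster[i])]]
      e <- member_expr[ii]
      expr_t[i] <- sum(e)
      breadth_t[i] <- cluster_breadth(clusters$pos[ii], e, reps$strand[i])
    }
    out[[paste0("expr_", t)]] <- expr_t
    out[[paste0("breadth_", t)]] <- breadth_t
    out[[paste0("active_", t)]] <- expr_t >= min_expr
  }
  out
}
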