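# Single-linkage MOTU delimitation over K2P distances. A threshold sweep is
# scored by barcode-gap width and partition stability (plateau length); the
# lowest rank-sum score wins. This is a transparent surrogate for automatic
# partitioning tools whose selection rule is likewise "lowest score wins".

# connected components of the graph linking pairs with d <= t (or d < t when
# strict); plain union-find, deterministic
connected_components <- function(d, threshold, strict = FALSE) {
  n <- nrow(d)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ut <- upper.tri(d)
  hit <- if (strict) d < threshold else d <= threshold
  idx <- which(ut & hit, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    a <- find(idx[k, 1])
    b <- find(idx[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  vapply(seq_len(n), find, integer(1))
}

make_partition <- function(labels, comp, threshold) {
  ids <- vapply(split(labels, comp), function(m) sort(m)[1], character(1))
  membership <- stats::setNames(ids[as.character(comp)], labels)
  clusters <- split(labels, membership)
  clusters <- clusters[order(names(clusters))]
  structure(list(threshold = threshold,
                 membership = membership,
                 clusters = clusters,
                 n_clusters = length(clusters)),
            class = "motu_partition")
}

#' Partition sequences into MOTUs by single-linkage at a threshold
#'
#' Clusters are the connected components of the graph that links every pair at
#' K2P distance `d <= threshold` (chain linkage, as in graph-connectivity
#' delimiters such as RESL). Cluster ids are deterministic: each cluster is
#' named after its lexicographically smallest member label.
#'
#' @param matrix A `k2p_dist` object or symmetric distance matrix.
#' @param threshold Linking distance, `>= 0`. The conventional quick-run COI
#'   cut-off is 0.03 (3 percent).
#' @param strict Link on `d < threshold` instead of `d <= threshold`.
#' @return An object of class `motu_partition` with `threshold`, `membership`
#'   (named vector id -> cluster id), `clusters` (list) and `n_clusters`.
#' @export
single_linkage_partition <- function(matrix, threshold = 0.03, strict = FALSE) {
  if (threshold < 0) abort_argument("threshold must be non-negative")
  d <- as_dist_matrix(matrix)
  comp <- connected_components(d, threshold, strict)
  make_partition(rownames(d), comp, threshold)
}

#' @export
print.motu_partition <- function(x, ...) {
  cat(sprintf("MOTU partition at threshold %.4g: %d sequences in %d clusters\n",
              x$threshold, length(x$membership), x$n_clusters))
  invisible(x)
}

partition_gap <- function(pd, same, k, n) {
  if (k == 1 || k == n) return(-Inf)   # no gap evidence in a trivial partition
  within <- if (any(same)) max(pd[same]) else 0
  between <- if (any(!same)) min(pd[!same]) else Inf
  between - within
}

#' Sweep clustering thresholds and score the candidate partitions
#'
#' Runs [single_linkage_partition()] at every threshold (merging incrementally,
#' so the sweep costs one pass over the sorted pairwise distances), collapses
#' consecutive thresholds that yield the identical partition, and scores each
#' distinct partition by `rank(-gap_width) + rank(-plateau_length)` with
#' average ranks on ties. `gap_width` is the smallest between-cluster distance
#' minus the largest within-cluster distance (the realised barcode gap;
#' negative when clusters overlap), and `plateau_length` is the number of
#' consecutive sweep steps on which the partition is stable. Trivial
#' partitions (one cluster, or every sequence alone) carry no gap evidence and
#' get `gap_width = -Inf`; they are flagged `degenerate`. The result is sorted
#' by ascending score, ties broken by fewer clusters then smaller threshold,
#' so the first row is the chosen partition.
#'
#' @param matrix A `k2p_dist` object or symmetric distance matrix.
#' @param thresholds Strictly increasing non-negative thresholds. The default
#'   sweep 0.002-0.10 in steps of 0.002 brackets the empirical within-MOTU
#'   divergence of COI barcodes (under 3 percent).
#' @return A `data.frame` (class `motu_sweep`) with columns `threshold`,
#'   `n_clusters`, `gap_width`, `plateau_length`, `degenerate` and `score`,
#'   sorted ascending by score; the matching `motu_partition` objects are in
#'   `attr(, "partitions")`.
#' @export
sweep_partitions <- function(matrix, thresholds = seq(0.002, 0.10, by = 0.002)) {
  if (length(thresholds) == 0) abort_argument("thresholds must be non-empty")
  if (any(thresholds < 0) || (length(thresholds) > 1 && any(diff(thresholds) <= 0))) {
    abort_argument("thresholds must be strictly increasing and non-negative")
  }
  d <- as_dist_matrix(matrix)
  labels <- rownames(d)
  n <- nrow(d)
  ut <- upper.tri(d)
  pairs <- which(ut, arr.ind = TRUE)
  pd <- d[ut]
  ord <- order(pd)

  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  comps <- matrix(NA_integer_, length(thresholds), n)
  k <- 1L
  for (ti in seq_along(thresholds)) {
    while (k <= length(ord) && pd[ord[k]] <= thresholds[ti]) {
      a <- find(pairs[ord[k], 1])
      b <- find(pairs[ord[k], 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
      k <- k + 1L
    }
    comps[ti, ] <- vapply(seq_len(n), find, integer(1))
  }

  sig <- apply(comps, 1, function(cc) paste(match(cc, unique(cc)), collapse = ","))
  runs <- rle(sig)
  first_idx <- cumsum(c(1, utils::head(runs$lengths, -1)))
  parts <- vector("list", length(runs$values))
  rows <- vector("list", length(runs$values))
  for (r in seq_along(runs$values)) {
    ti <- first_idx[r]
    comp <- comps[ti, ]
    part <- make_partition(labels, comp, thresholds[ti])
    same <- outer(comp, comp, "==")[ut]
    gw <- partition_gap(pd, same, part$n_clusters, n)
    parts[[r]] <- part
    rows[[r]] <- data.frame(threshold = thresholds[ti],
                            n_clusters = part$n_clusters,
                            gap_width = gw,
                            plateau_length = runs$lengths[r],
                            degenerate = part$n_clusters == 1 || part$n_clusters == n)
  }
  res <- do.call(rbind, rows)
  res$score <- rank(-res$gap_width, ties.method = "average") +
    rank(-res$plateau_length, ties.method = "average")
  o <- order(res$score, res$n_clusters, res$threshold)
  res <- res[o, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "partitions") <- parts[o]
  class(res) <- c("motu_sweep", "data.frame")
  res
}

#' Range and best cluster count over the top scored partitions
#'
#' Mirrors the reporting convention of automatic partitioning runs: keep the
#' ten best-scored partitions, report the spread of their cluster counts and
#' the count of the score-minimal one.
#'
#' @param results A `motu_sweep` result (already sorted by score).
#' @param top Number of leading partitions to consider (default 10).
#' @return A list with `min`, `max` and `best` cluster counts, and
#'   `best_partition` (the winning `motu_partition`).
#' @export
partition_range <- function(results, top = 10) {
  if (is.null(results) || nrow(results) == 0) abort_argument("results must be non-empty")
  head_n <- utils::head(results$n_clusters, top)
  list(min = min(head_n), max = max(head_n), best = results$n_clusters[1],
       best_partition = attr(results, "partitions")[[1]])
}
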