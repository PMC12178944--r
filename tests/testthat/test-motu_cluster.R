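# helper: random symmetric "distance" matrix (single linkage needs no metricity)
rand_dist <- function(n, max_d = 0.2) {
  d <- matrix(0, n, n, dimnames = list(sprintf("t%02d", 1:n), sprintf("t%02d", 1:n)))
  d[upper.tri(d)] <- stats::runif(n * (n - 1) / 2, 0, max_d)
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  d
}

# planted 3-group matrix with a clean barcode gap
gapped_dist <- function(sizes = c(4, 3, 3), within = 0.02, between = c(0.10, 0.15)) {
  n <- sum(sizes)
  grp <- rep(seq_along(sizes), sizes)
  d <- matrix(0, n, n, dimnames = list(sprintf("t%02d", 1:n), sprintf("t%02d", 1:n)))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- if (grp[i] == grp[j]) stats::runif(1, 0, within) else
      stats::runif(1, between[1], between[2])
  }
  list(d = d, groups = grp)
}

test_that("single-linkage partitions are connected components with smallest-label ids", {
  d <- matrix(c(0, 0.01, 0.10,
                0.01, 0, 0.10,
                0.10, 0.10, 0), 3, 3, dimnames = list(c("s1", "s2", "s3"), c("s1", "s2", "s3")))
  p <- single_linkage_partition(d, 0.03)
  expect_equal(p$n_clusters, 2)
  expect_equal(unname(p$membership), c("s1", "s1", "s3"))
  expect_equal(p$clusters, list(s1 = c("s1", "s2"), s3 = "s3"))

  set.seed(5)
  r <- rand_dist(6)
  expect_equal(single_linkage_partition(r, 0)$n_clusters, 6)        # t = 0, distinct
  expect_equal(single_linkage_partition(r, max(r))$n_clusters, 1)   # t >= max
  # boundary: d == t links inclusively, strictly with strict = TRUE
  expect_equal(single_linkage_partition(d, 0.01)$n_clusters, 2)
  expect_equal(single_linkage_partition(d, 0.01, strict = TRUE)$n_clusters, 3)
})

test_that("partitions equal exhaustive component search and hclust on n <= 12", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(4:12, 1)
    d <- rand_dist(n)
    for (t in c(0.02, 0.05, 0.1, 0.15)) {
      p <- single_linkage_partition(d, t)
      comp <- match(unname(p$membership), unique(unname(p$membership)))
      expect_true(same_partition(comp, bfs_components(d, t)))
      # independent route: single-linkage dendrogram cut at height t
      hc <- stats::cutree(stats::hclust(stats::as.dist(d), method = "single"), h = t)
      expect_true(same_partition(comp, hc))
      # strict variant against the strict oracle
      ps <- single_linkage_partition(d, t, strict = TRUE)
      comp_s <- match(unname(ps$membership), unique(unname(ps$membership)))
      expect_true(same_partition(comp_s, bfs_components(d, t, strict = TRUE)))
    }
  }
})

test_that("cluster counts are monotone and partitions refine along a sweep", {
  set.seed(13)
  d <- rand_dist(15)
  thresholds <- seq(0.005, 0.2, by = 0.005)
  parts <- lapply(thresholds, function(t) single_linkage_partition(d, t))
  ns <- vapply(parts, `[[`, integer(1), "n_clusters")
  expect_true(all(diff(ns) <= 0))
  for (i in seq_along(parts)[-1]) {
    fine <- parts[[i - 1]]$membership
    coarse <- parts[[i]]$membership
    # refinement: members of one fine cluster never split across coarse clusters
    expect_true(all(tapply(coarse, fine, function(x) length(unique(x))) == 1))
  }
})

test_that("the sweep score prefers the partition respecting a planted barcode gap", {
  set.seed(21)
  g <- gapped_dist()
  sw <- sweep_partitions(g$d, seq(0.005, 0.15, by = 0.005))
  best <- attr(sw, "partitions")[[1]]
  comp <- match(unname(best$membership[rownames(g$d)]), unique(unname(best$membership[rownames(g$d)])))
  expect_true(same_partition(comp, g$groups))
  expect_false(sw$degenerate[1])
  expect_gt(sw$gap_width[1], 0.05)

  # all-equal distances: only the trivial partitions exist, flagged degenerate
  eq <- matrix(0.05, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(eq) <- 0
  sw_eq <- sweep_partitions(eq, c(0.01, 0.04, 0.06))
  expect_true(all(sw_eq$n_clusters %in% c(1, 4)))
  expect_true(all(sw_eq$degenerate))

  # a sweep of length one returns that partition with plateau 1
  one <- sweep_partitions(g$d, 0.03)
  expect_equal(nrow(one), 1)
  expect_equal(one$plateau_length, 1)
  expect_error(sweep_partitions(g$d, numeric(0)), class = "refaudit_argument_error")
  expect_error(sweep_partitions(g$d, c(0.05, 0.03)), class = "refaudit_argument_error")
})

test_that("partition_range reports the spread and best of the top partitions", {
  set.seed(2)
  g <- gapped_dist(sizes = c(5, 4, 4, 3))
  sw <- sweep_partitions(g$d, seq(0.005, 0.15, by = 0.005))
  pr <- partition_range(sw)
  expect_equal(pr$best, sw$n_clusters[1])
  expect_equal(pr$min, min(utils::head(sw$n_clusters, 10)))
  expect_equal(pr$max, max(utils::head(sw$n_clusters, 10)))
  expect_lte(pr$min, pr$best)
  expect_gte(pr$max, pr$best)
  expect_equal(pr$best, 4)   # the planted group count wins
  expect_error(partition_range(sw[0, ]), class = "refaudit_argument_error")
})
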