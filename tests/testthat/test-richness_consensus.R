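test_that("richness extrapolation follows the ratio formula in both precision modes", {
  est <- estimate_richness(1350, 3131, 2291)
  expect_equal(est$ratio, 1.36)
  expect_equal(est$estimate, 992L)
  est_full <- estimate_richness(1350, 3131, 2291, "full")
  expect_equal(est_full$estimate, 987L)
  expect_equal(est_full$estimate, as.integer(floor(1350 * 2291 / 3131)))
  # ratio 1 passes the query count through
  expect_equal(estimate_richness(10, 5, 5)$estimate, 10L)
  expect_error(estimate_richness(0, 5, 5), class = "refaudit_argument_error")

  # full-precision estimate equals the formula to within integer truncation
  set.seed(8)
  for (i in 1:20) {
    q <- sample(1:5000, 1); m <- sample(1:5000, 1); s <- sample(1:5000, 1)
    expect_equal(estimate_richness(q, m, s, "full")$estimate,
                 as.integer(floor(q * s / m + 1e-9)))
  }

  # degenerate bootstrap: constant MOTU counts give a degenerate interval
  set.seed(1)
  bs <- estimate_richness(100, 50, 50, bootstrap = 50,
                          motus_per_species = rep(1L, 50))
  expect_equal(unname(bs$bootstrap_interval), c(100, 100))
  expect_error(estimate_richness(1, 1, 1, bootstrap = 10),
               class = "refaudit_argument_error")
})

ann <- function(family, genus = NA, species = NA) {
  tax_row("Annelida", "Polychaeta",
          if (family == "Dorvilleidae") "Eunicida" else "Phyllodocida",
          family, genus, species)
}

test_that("majority-rule consensus walks ranks and excludes taxonomic outliers", {
  trio <- tax_table(ann("Syllidae"), ann("Syllidae"), ann("Dorvilleidae"))
  cons <- consensus_taxonomy(trio, min_share = 0.6)
  expect_equal(unname(cons$consensus["family"]), "Syllidae")
  expect_setequal(cons$flags, c("discordant", "outliers_excluded"))
  expect_equal(cons$outliers, c(FALSE, FALSE, TRUE))

  # no label reaches 0.6 at order: stop at the last agreeing rank (class)
  duo <- tax_table(ann("Syllidae"), ann("Dorvilleidae"))
  cons2 <- consensus_taxonomy(duo, min_share = 0.6)
  expect_equal(cons2$agreement_rank, "class")
  expect_equal(unname(cons2$consensus["class"]), "Polychaeta")
  expect_true(is.na(cons2$consensus["family"]))
  expect_equal(cons2$flags, "discordant")

  # unanimous members give full-depth support 1
  same <- tax_table(ann("Syllidae", "Syllis", "Syllis gracilis"),
                    ann("Syllidae", "Syllis", "Syllis gracilis"))
  cons3 <- consensus_taxonomy(same)
  expect_equal(cons3$agreement_rank, "species")
  expect_equal(cons3$support_share, 1)
  expect_equal(cons3$flags, character(0))

  # read-count weighting can flip the majority
  w <- consensus_taxonomy(trio, weights = c(1, 1, 8), min_share = 0.6)
  expect_equal(unname(w$consensus["family"]), "Dorvilleidae")

  expect_error(consensus_taxonomy(trio[0, ]), class = "refaudit_argument_error")
  expect_error(consensus_taxonomy(trio, min_share = 0.4), class = "refaudit_argument_error")
})

test_that("LCA truncates at the deepest unanimous rank", {
  pair <- tax_table(ann("Syllidae", "Syllis"), ann("Dorvilleidae", "Dorvillea"))
  lca <- lca_taxonomy(pair)
  expect_equal(unname(lca["class"]), "Polychaeta")
  expect_true(all(is.na(lca[c("order", "family", "genus", "species")])))

  one <- ann("Syllidae", "Syllis", "Syllis gracilis")
  expect_equal(lca_taxonomy(one), unlist(one))

  disjoint <- tax_table(tax_row("Annelida"), tax_row("Mollusca"))
  expect_true(all(is.na(lca_taxonomy(disjoint))))
})

test_that("consensus at unanimity never goes deeper than the LCA", {
  set.seed(17)
  fams <- c("Syllidae", "Dorvilleidae", "Nereididae")
  for (i in 1:25) {
    n <- sample(2:6, 1)
    members <- do.call(rbind, lapply(seq_len(n), function(j) {
      f <- sample(fams, 1)
      depth <- sample(2:6, 1)
      labs <- c("Annelida", "Polychaeta", "OrderX", f, paste0(f, "_gen"), paste0(f, "_sp"))
      tax_row(labs[seq_len(depth)])
    }))
    cons <- consensus_taxonomy(members, min_share = 1, outlier_rule = "keep")
    lca <- lca_taxonomy(members)
    depth_of <- function(x) sum(!is.na(x))
    expect_equal(depth_of(cons$consensus), depth_of(lca))
  }
})

test_that("consensus recovers planted family labels despite 10% mislabels", {
  set.seed(23)
  fams <- sprintf("Fam%02didae", 1:12)
  n_motu <- 80
  hits <- logical(n_motu)
  for (m in seq_len(n_motu)) {
    truth_fam <- sample(fams, 1)
    n_mem <- sample(5:10, 1)
    labels <- rep(truth_fam, n_mem)
    wrong <- stats::runif(n_mem) < 0.10
    labels[wrong] <- sample(setdiff(fams, truth_fam), sum(wrong), replace = TRUE)
    members <- do.call(rbind, lapply(labels, function(f) ann(f)))
    cons <- consensus_taxonomy(members, min_share = 0.6)
    hits[m] <- identical(unname(cons$consensus[["family"]]), truth_fam)
  }
  expect_gte(mean(hits), 0.95)
})

test_that("similarity hits are filtered on identity and cover jointly", {
  hits <- data.frame(query = c("q1", "q1", "q2"), subject = c("r1", "r2", "r3"),
                     identity = c(96, 96, 94), cover = c(91, 89, 99))
  kept <- filter_hits(hits)
  expect_equal(kept$subject, "r1")
  expect_equal(nrow(filter_hits(hits, 0, 0)), 3)
  expect_equal(nrow(filter_hits(hits[0, ])), 0)
  bad <- hits; bad$identity[2] <- NA
  expect_error(filter_hits(bad), "2", class = "refaudit_validation_error")
})

test_that("reference matching applies the sub-threshold same-species rule", {
  # q1 near refA (0.03), q2 far from everything (>= 0.06), q3 in a cluster with two species
  labs <- c("q1", "q2", "q3", "refA", "refB", "refC")
  d <- matrix(0.2, 6, 6, dimnames = list(labs, labs))
  diag(d) <- 0
  d["q1", "refA"] <- d["refA", "q1"] <- 0.03
  d["q2", "refA"] <- d["refA", "q2"] <- 0.06
  d["q3", "refB"] <- d["refB", "q3"] <- 0.02
  d["q3", "refC"] <- d["refC", "q3"] <- 0.04
  d["refB", "refC"] <- d["refC", "refB"] <- 0.045
  refs <- data.frame(record_id = c("refA", "refB", "refC"),
                     species_name = c("Alpha una", "Beta dua", "Gamma tria"),
                     published = c(TRUE, FALSE, TRUE),
                     in_region = c(FALSE, FALSE, TRUE))
  res <- match_to_reference(c("q1", "q2", "q3"), refs, d)
  expect_equal(res$matched_species[res$query_id == "q1"], "Alpha una")
  expect_false(res$ambiguous[res$query_id == "q1"])
  expect_true(is.na(res$matched_species[res$query_id == "q2"]))   # strict <
  expect_true(res$ambiguous[res$query_id == "q3"])
  # published + in-region references list first among ambiguous names
  expect_equal(res$matched_species[res$query_id == "q3"], "Gamma tria;Beta dua")
  expect_equal(res$min_distance[res$query_id == "q3"], 0.02)
})

test_that("refine_motus flags consensus species spread across MOTUs as cryptic", {
  taxa <- rbind(
    cbind(asv_id = c("a1", "a2"), tax_table(ann("Syllidae", "Syllis", "Syllis gracilis"),
                                            ann("Syllidae", "Syllis", "Syllis gracilis"))),
    cbind(asv_id = c("b1", "b2"), tax_table(ann("Syllidae", "Syllis", "Syllis gracilis"),
                                            ann("Syllidae", "Syllis", "Syllis gracilis"))),
    cbind(asv_id = c("c1", "c2"), tax_table(ann("Nereididae", "Nereis", "Nereis falsa"),
                                            ann("Nereididae", "Nereis", "Nereis falsa")))
  )
  part <- structure(list(threshold = 0.03,
                         membership = stats::setNames(c("a1", "a1", "b1", "b1", "c1", "c1"),
                                                      c("a1", "a2", "b1", "b2", "c1", "c2")),
                         clusters = list(a1 = c("a1", "a2"), b1 = c("b1", "b2"),
                                         c1 = c("c1", "c2")),
                         n_clusters = 3L),
                    class = "motu_partition")
  out <- refine_motus(taxa, part)
  expect_equal(nrow(out), 3)
  cryptic <- grepl("cryptic_candidate", out$flags)
  expect_equal(cryptic, c(TRUE, TRUE, FALSE))
  expect_equal(out$species[1], "Syllis gracilis")
})
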