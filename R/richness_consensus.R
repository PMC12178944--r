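# Species-richness extrapolation from MOTU counts, and MOTU taxonomy
# refinement: majority-rule consensus with outlier exclusion, LCA, similarity
# hit filtering and reference matching at a K2P ceiling.

#' Extrapolate species richness from MOTU counts
#'
#' Calibrates a MOTU-to-species ratio on a reference library (where both MOTU
#' and species counts are known) and divides the query MOTU count by it:
#' `estimate = n_query_motus / (n_ref_motus / n_ref_species)`, truncated to an
#' integer. With `precision_mode = "truncate2"` the ratio itself is first
#' truncated to two decimals, mirroring arithmetic done on a printed
#' two-decimal ratio; `"full"` keeps the exact ratio (the two modes can differ
#' by a few species and both are reported in practice).
#'
#' An optional bootstrap resamples the reference species with replacement
#' (requires `motus_per_species`, the per-species MOTU counts making up
#' `n_ref_motus`) and reports a percentile interval for the estimate.
#'
#' @param n_query_motus MOTU count in the query (e.g. metabarcoding) dataset.
#' @param n_ref_motus,n_ref_species MOTU and species counts in the reference
#'   library; all counts must be positive.
#' @param precision_mode `"truncate2"` (default) or `"full"`.
#' @param bootstrap Number of bootstrap resamples (0 = none).
#' @param motus_per_species Integer vector of MOTUs per reference species,
#'   needed when `bootstrap > 0`.
#' @param conf Confidence level for the percentile interval.
#' @return An object of class `richness_estimate`: a list with the counts,
#'   `ratio`, `estimate` and optionally `bootstrap_interval`.
#' @export
estimate_richness <- function(n_query_motus, n_ref_motus, n_ref_species,
                              precision_mode = c("truncate2", "full"),
                              bootstrap = 0, motus_per_species = NULL,
                              conf = 0.95) {
  precision_mode <- match.arg(precision_mode)
  if (any(c(n_query_motus, n_ref_motus, n_ref_species) < 1)) {
    abort_argument("all counts must be at least 1")
  }
  apply_mode <- function(r) if (precision_mode == "truncate2") trunc2(r) else r
  ratio <- apply_mode(n_ref_motus / n_ref_species)
  estimate <- as.integer(floor(n_query_motus / ratio + 1e-9))
  interval <- NULL
  if (bootstrap > 0) {
    if (is.null(motus_per_species)) {
      abort_argument("bootstrap requires motus_per_species")
    }
    est_b <- replicate(bootstrap, {
      r_b <- apply_mode(sum(sample(motus_per_species, replace = TRUE)) /
                          length(motus_per_species))
      floor(n_query_motus / r_b)
    })
    a <- (1 - conf) / 2
    interval <- unname(stats::quantile(est_b, c(a, 1 - a)))
  }
  structure(list(n_query_motus = n_query_motus, n_ref_motus = n_ref_motus,
                 n_ref_species = n_ref_species, ratio = ratio,
                 estimate = estimate, precision_mode = precision_mode,
                 bootstrap_interval = interval),
            class = "richness_estimate")
}

#' @export
print.richness_estimate <- function(x, ...) {
  cat(sprintf("Richness extrapolation: %d MOTUs / ratio %.4g (%d MOTUs / %d species) = %d species\n",
              x$n_query_motus, x$ratio, x$n_ref_motus, x$n_ref_species, x$estimate))
  if (!is.null(x$bootstrap_interval)) {
    cat(sprintf("  bootstrap interval: %.0f - %.0f\n",
                x$bootstrap_interval[1], x$bootstrap_interval[2]))
  }
  invisible(x)
}

as_taxonomy_df <- function(taxa) {
  if (is.character(taxa)) taxa <- as.data.frame(as.list(taxa), stringsAsFactors = FALSE)
  missing_ranks <- setdiff(TAX_RANKS, names(taxa))
  for (r in missing_ranks) taxa[[r]] <- NA_character_
  taxa[, TAX_RANKS, drop = FALSE]
}

#' Majority-rule consensus taxonomy for a MOTU
#'
#' Walks the ranks from phylum down. At each rank, the label whose weighted
#' share of *all* current members reaches `min_share` becomes the consensus;
#' members without a label at the rank count against support, so a consensus
#' at unanimity (`min_share = 1`) coincides with [lca_taxonomy()]. The walk
#' stops at the first rank where no label reaches `min_share`. Members whose
#' label conflicts with the consensus at a rank where consensus held are
#' outliers; under `outlier_rule = "exclude"` they are removed and the
#' consensus recomputed once (a single round keeps the operation predictable).
#'
#' @param taxa Taxonomies of the MOTU members: a `data.frame` with
#'   [TAX_RANKS] columns (`NA` for absent ranks).
#' @param weights Per-member weights (default 1 per member; read counts are
#'   deliberately not the default, since abundance is not evidence of
#'   identification quality).
#' @param min_share Minimum weighted share in `(0.5, 1]` (default 0.6).
#' @param outlier_rule `"exclude"` (default) or `"keep"`.
#' @return A list with `consensus` (named character vector over [TAX_RANKS]),
#'   `agreement_rank`, `support_share`, `flags` (subset of `discordant`,
#'   `outliers_excluded`) and `outliers` (logical over input members).
#' @export
consensus_taxonomy <- function(taxa, weights = NULL, min_share = 0.6,
                               outlier_rule = c("exclude", "keep")) {
  outlier_rule <- match.arg(outlier_rule)
  taxa <- as_taxonomy_df(taxa)
  if (nrow(taxa) == 0) abort_argument("at least one member is required")
  if (min_share <= 0.5 || min_share > 1) abort_argument("min_share must be in (0.5, 1]")
  w <- weights %||% rep(1, nrow(taxa))
  if (length(w) != nrow(taxa)) abort_argument("weights must match the number of members")

  pass <- function(keep) {
    cons <- stats::setNames(rep(NA_character_, length(TAX_RANKS)), TAX_RANKS)
    share <- NA_real_
    at <- NA_character_
    outl <- rep(FALSE, nrow(taxa))
    tot <- sum(w[keep])
    for (r in TAX_RANKS) {
      lab <- taxa[[r]]
      present <- keep & !is.na(lab)
      if (!any(present)) break
      s <- tapply(w[present], lab[present], sum) / tot
      winners <- names(s)[s >= min_share - 1e-12]
      if (length(winners) == 0) break
      win <- sort(winners)[1]   # ties broken toward the smaller label
      cons[[r]] <- win
      share <- unname(s[[win]])
      at <- r
      outl <- outl | (keep & !is.na(lab) & lab != win)
    }
    list(consensus = cons, agreement_rank = at, support_share = share, outliers = outl)
  }

  # discordance is judged before any exclusion, at family rank or above
  upper <- TAX_RANKS[1:4]
  discordant <- any(vapply(upper, function(r) {
    length(unique(stats::na.omit(taxa[[r]]))) > 1
  }, logical(1)))

  first <- pass(rep(TRUE, nrow(taxa)))
  flags <- character(0)
  if (discordant) flags <- c(flags, "discordant")
  result <- first
  if (outlier_rule == "exclude" && any(first$outliers)) {
    result <- pass(!first$outliers)
    result$outliers <- first$outliers
    flags <- c(flags, "outliers_excluded")
  }
  list(consensus = result$consensus, agreement_rank = result$agreement_rank,
       support_share = result$support_share, flags = flags,
       outliers = first$outliers)
}

#' Lowest common ancestor of a set of taxonomies
#'
#' Returns the taxonomy truncated at the deepest rank on which *all* inputs
#' carry the same (non-missing) label; ranks below it are absent. This is the
#' conservative rule used to resolve conflicting database matches.
#'
#' @param taxa A `data.frame` of taxonomies ([TAX_RANKS] columns).
#' @return Named character vector over [TAX_RANKS] (`NA` below the LCA).
#' @export
lca_taxonomy <- function(taxa) {
  taxa <- as_taxonomy_df(taxa)
  if (nrow(taxa) == 0) abort_argument("at least one taxonomy is required")
  out <- stats::setNames(rep(NA_character_, length(TAX_RANKS)), TAX_RANKS)
  for (r in TAX_RANKS) {
    lab <- taxa[[r]]
    u <- unique(lab)
    if (length(u) == 1 && !is.na(u)) out[[r]] <- u else break
  }
  out
}

#' Filter similarity-search hit tables
#'
#' Keeps hits meeting both a minimum identity and a minimum query cover; the
#' conventional thresholds for accepting a COI match are 95 percent identity
#' and 90 percent cover.
#'
#' @param hits A `data.frame` with numeric `identity` and `cover` columns
#'   (percentages in 0-100).
#' @param min_identity,min_cover Thresholds (hits are kept when `>=` both).
#' @return The retained rows.
#' @export
filter_hits <- function(hits, min_identity = 95, min_cover = 90) {
  if (!all(c("identity", "cover") %in% names(hits))) {
    abort_argument("hits must have 'identity' and 'cover' columns")
  }
  bad <- which(is.na(hits$identity) | is.na(hits$cover) |
                 hits$identity < 0 | hits$identity > 100 |
                 hits$cover < 0 | hits$cover > 100)
  if (length(bad) > 0) {
    abort_validation(sprintf("malformed hit row(s): %s", paste(bad, collapse = ", ")))
  }
  out <- hits[hits$identity >= min_identity & hits$cover >= min_cover, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match query sequences to reference species at a K2P ceiling
#'
#' A query matches a reference species when single-linkage clustering at
#' `max_distance` (strictly `d < max_distance`, the "same species below 5
#' percent divergence" rule) places it in a cluster containing that species'
#' reference records. Clusters containing several reference species yield an
#' ambiguous match listing all of them, ordered with published and in-region
#' references first when those attributes are available.
#'
#' @param query_ids Ids of the query sequences.
#' @param references A `data.frame` with `record_id`, `species_name` and
#'   optionally logical `published` and `in_region` columns.
#' @param matrix A `k2p_dist` object (or matrix) over the union of query ids
#'   and reference record ids.
#' @param max_distance K2P ceiling (default 0.05).
#' @return A `data.frame` with one row per query: `query_id`,
#'   `matched_species` (`;`-separated when ambiguous, `NA` when none),
#'   `ambiguous`, `min_distance`.
#' @export
match_to_reference <- function(query_ids, references, matrix, max_distance = 0.05) {
  d <- as_dist_matrix(matrix)
  labels <- rownames(d)
  missing <- setdiff(c(query_ids, references$record_id), labels)
  if (length(missing) > 0) {
    abort_argument(sprintf("distance matrix does not cover: %s",
                           paste(utils::head(missing, 5), collapse = ", ")))
  }
  part <- single_linkage_partition(d, max_distance, strict = TRUE)
  ref_pref <- data.frame(
    record_id = references$record_id,
    species_name = references$species_name,
    published = if ("published" %in% names(references)) references$published else FALSE,
    in_region = if ("in_region" %in% names(references)) references$in_region else FALSE,
    stringsAsFactors = FALSE
  )
  rows <- lapply(query_ids, function(q) {
    members <- names(part$membership)[part$membership == part$membership[[q]]]
    refs_in <- ref_pref[ref_pref$record_id %in% setdiff(members, q), , drop = FALSE]
    if (nrow(refs_in) == 0) {
      return(data.frame(query_id = q, matched_species = NA_character_,
                        ambiguous = FALSE, min_distance = NA_real_,
                        stringsAsFactors = FALSE))
    }
    per_species <- split(refs_in, refs_in$species_name)
    info <- data.frame(
      species = names(per_species),
      published = vapply(per_species, function(x) any(x$published), logical(1)),
      in_region = vapply(per_species, function(x) any(x$in_region), logical(1)),
      min_d = vapply(per_species, function(x) min(d[q, x$record_id]), numeric(1)),
      stringsAsFactors = FALSE
    )
    info <- info[order(-info$published, -info$in_region, info$species), , drop = FALSE]
    data.frame(query_id = q,
               matched_species = paste(info$species, collapse = ";"),
               ambiguous = nrow(info) > 1,
               min_distance = min(info$min_d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Refine MOTU taxonomy across a whole partition
#'
#' Applies [consensus_taxonomy()] to the members of every MOTU in a partition
#' and flags, across MOTUs, consensus species labels that are spread over more
#' than one MOTU (`cryptic_candidate` -- the metabarcoding analogue of a
#' grade-C species). When reference matches are supplied (see
#' [match_to_reference()]) the matched species is attached and flagged
#' `reference_match`.
#'
#' @param taxa Taxonomies of all sequences: a `data.frame` with an id column
#'   `asv_id` plus [TAX_RANKS] columns.
#' @param partition A `motu_partition` whose members are the `asv_id`s.
#' @param min_share,outlier_rule,weights Passed to [consensus_taxonomy()]
#'   (`weights` is a named vector over `asv_id`).
#' @param matches Optional result of [match_to_reference()] keyed by MOTU
#'   cluster id in a `query_id` column.
#' @return A `data.frame` with one row per MOTU: `motu_id`, `n_members`, the
#'   consensus labels at each rank, `agreement_rank`, `support_share`,
#'   `flags` (comma-separated), `matched_species`.
#' @export
refine_motus <- function(taxa, partition, min_share = 0.6,
                         outlier_rule = "exclude", weights = NULL,
                         matches = NULL) {
  if (!"asv_id" %in% names(taxa)) abort_argument("taxa must have an 'asv_id' column")
  rows <- lapply(names(partition$clusters), function(cid) {
    ids <- partition$clusters[[cid]]
    sub <- taxa[match(ids, taxa$asv_id), , drop = FALSE]
    w <- if (!is.null(weights)) unname(weights[ids]) else NULL
    cons <- consensus_taxonomy(sub[, intersect(names(sub), TAX_RANKS), drop = FALSE],
                               weights = w, min_share = min_share,
                               outlier_rule = outlier_rule)
    out <- data.frame(motu_id = cid, n_members = length(ids), stringsAsFactors = FALSE)
    for (r in TAX_RANKS) out[[r]] <- cons$consensus[[r]]
    out$agreement_rank <- cons$agreement_rank
    out$support_share <- cons$support_share
    out$flags <- paste(cons$flags, collapse = ",")
    out
  })
  res <- do.call(rbind, rows)
  # one consensus species name in several MOTUs: cryptic-complex candidate
  sp_counts <- table(res$species[!is.na(res$species)])
  cryptic <- !is.na(res$species) & res$species %in% names(sp_counts)[sp_counts > 1]
  res$flags <- ifelse(cryptic, paste0(res$flags, ifelse(nzchar(res$flags), ",", ""),
                                      "cryptic_candidate"), res$flags)
  res$matched_species <- NA_character_
  if (!is.null(matches)) {
    hit <- match(res$motu_id, matches$query_id)
    res$matched_species <- matches$matched_species[hit]
    got <- !is.na(res$matched_species)
    res$flags[got] <- paste0(res$flags[got],
                             ifelse(nzchar(res$flags[got]), ",", ""), "reference_match")
  }
  rownames(res) <- NULL
  res
}
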