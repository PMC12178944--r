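# Cluster-level concordance reporting and per-species A-E grading of a
# reference library, over BIN labels or computed MOTU partitions alike.

#' Classify clusters as singleton, concordant or discordant
#'
#' A cluster is a *singleton* when it holds exactly one record, *discordant*
#' when its records carry more than one nominal species name (names are only
#' counted when present), and *concordant* otherwise. The same species may
#' span several concordant clusters. The summary reports counts and
#' percentages of total clusters, rounded half-up to integer precision as
#' such reports conventionally print them.
#'
#' @param records A `data.frame` with a `cluster` column (no missing values)
#'   and a `species_name` column (`NA` allowed).
#' @return A list with `clusters` (per-cluster `data.frame`: `cluster_id`,
#'   `status`, `n_records`, `n_species`, `species`) and `summary` (list with
#'   `n_clusters`, `counts`, `percent`).
#' @export
discordance_report <- function(records) {
  if (!all(c("cluster", "species_name") %in% names(records))) {
    abort_argument("records must have 'cluster' and 'species_name' columns")
  }
  if (any(is.na(records$cluster) | records$cluster == "")) {
    abort_validation("every record must carry a cluster label")
  }
  by_cluster <- split(records$species_name, records$cluster)
  status_of <- function(sp) {
    n_rec <- length(sp)
    n_sp <- length(unique(sp[!is.na(sp) & sp != ""]))
    if (n_rec == 1) "singleton" else if (n_sp > 1) "discordant" else "concordant"
  }
  clusters <- data.frame(
    cluster_id = names(by_cluster),
    status = vapply(by_cluster, status_of, character(1)),
    n_records = vapply(by_cluster, length, integer(1)),
    n_species = vapply(by_cluster, function(sp) length(unique(sp[!is.na(sp) & sp != ""])),
                       integer(1)),
    stringsAsFactors = FALSE
  )
  clusters$species <- lapply(by_cluster, function(sp) sort(unique(sp[!is.na(sp) & sp != ""])))
  rownames(clusters) <- NULL
  statuses <- c("concordant", "discordant", "singleton")
  counts <- vapply(statuses, function(s) sum(clusters$status == s), integer(1))
  percent <- round_half_up(100 * counts / nrow(clusters))
  list(clusters = clusters,
       summary = list(n_clusters = nrow(clusters), counts = counts, percent = percent))
}

#' Grade species A-E by library concordance and depth
#'
#' Each named species is graded by the quality and congruence of its records
#' against the cluster labels, in a fixed decision order:
#' \describe{
#'   \item{E (discordant)}{any of its clusters also contains records of a
#'     different species -- a possible misidentification, paraphyly or
#'     polyphyly;}
#'   \item{D (insufficient data)}{not discordant, but fewer than three
#'     specimens;}
#'   \item{C (multiple clusters)}{assigned to more than one cluster, each
#'     exclusive to the species -- a cryptic-complex candidate;}
#'   \item{A (consolidated concordance)}{one exclusive cluster and more than
#'     ten specimens;}
#'   \item{B (basal concordance)}{one exclusive cluster, ten or fewer
#'     specimens.}
#' }
#' D outranking C means a data-poor multi-cluster species is reported as
#' insufficient rather than cryptic.
#'
#' @param records A `data.frame` with non-missing `species_name` and `cluster`
#'   columns (tag-coded or unnamed records must be filtered out upstream).
#' @return A `data.frame` with one row per species: `species_name`, `grade`,
#'   `n_specimens`, `n_clusters`, `clusters_exclusive`, `rationale`.
#' @export
grade_species <- function(records) {
  if (!all(c("cluster", "species_name") %in% names(records))) {
    abort_argument("records must have 'cluster' and 'species_name' columns")
  }
  if (any(is.na(records$species_name) | records$species_name == "")) {
    abort_validation("all records must carry a species name when grading")
  }
  if (any(is.na(records$cluster) | records$cluster == "")) {
    abort_validation("every record must carry a cluster label")
  }
  species_per_cluster <- lapply(split(records$species_name, records$cluster), unique)
  shared_cluster <- names(species_per_cluster)[
    vapply(species_per_cluster, length, integer(1)) > 1]
  by_species <- split(as.character(records$cluster), records$species_name)
  grade_one <- function(name, clusters) {
    n <- length(clusters)
    cl <- unique(clusters)
    exclusive <- !any(cl %in% shared_cluster)
    if (!exclusive) {
      g <- "E"; why <- "shares a cluster with another species"
    } else if (n < 3) {
      g <- "D"; why <- "fewer than three specimens"
    } else if (length(cl) > 1) {
      g <- "C"; why <- sprintf("%d exclusive clusters (cryptic-complex candidate)", length(cl))
    } else if (n > 10) {
      g <- "A"; why <- "one exclusive cluster, more than ten specimens"
    } else {
      g <- "B"; why <- "one exclusive cluster, ten or fewer specimens"
    }
    data.frame(species_name = name, grade = g, n_specimens = n,
               n_clusters = length(cl), clusters_exclusive = exclusive,
               rationale = why, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, Map(grade_one, names(by_species), by_species))
  rownames(out) <- NULL
  out
}

#' Summarise a grade table
#'
#' @param grades Output of [grade_species()].
#' @return A list with `n_species`, per-grade `counts` and `percent`
#'   (half-up, one decimal).
#' @export
grade_summary <- function(grades) {
  lv <- c("A", "B", "C", "D", "E")
  counts <- vapply(lv, function(g) sum(grades$grade == g), integer(1))
  list(n_species = nrow(grades), counts = counts,
       percent = round_half_up(100 * counts / nrow(grades), 1))
}

#' Ratio of clusters to species
#'
#' The cluster-to-species ratio measures how strongly a library is split
#' relative to its nominal taxonomy; ratios well above 1 signal oversplitting
#' or unrecognised (cryptic) diversity. `truncate2` truncates -- does not
#' round -- to two decimals, matching how such ratios are quoted alongside
#' printed tables.
#'
#' @param n_clusters,n_species Positive counts.
#' @param precision_mode `"truncate2"` (default) or `"full"`.
#' @return The ratio.
#' @export
ratio_clusters_to_species <- function(n_clusters, n_species,
                                      precision_mode = c("truncate2", "full")) {
  precision_mode <- match.arg(precision_mode)
  if (n_species < 1) abort_argument("n_species must be at least 1")
  r <- n_clusters / n_species
  if (precision_mode == "truncate2") trunc2(r) else r
}
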