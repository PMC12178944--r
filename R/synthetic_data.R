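# Synthetic reference libraries and ASV tables with planted truth: lineage
# structure, misidentifications, singletons, tag codes, pseudogenes and read
# counts. Sequences evolve under a K80 substitution process so that realised
# K2P distances concentrate near their targets; divergence constraints are
# enforced by post-hoc verification with rejection sampling.

#' Simulation parameters for synthetic barcode data
#'
#' The defaults emulate the statistical structure of a curated COI reference
#' library: intraspecific (within-lineage) divergence below 2 percent K2P,
#' interspecific divergence above 8 percent, 313 bp amplicons (the standard
#' mini-barcode length), and optional planted faults.
#'
#' @param n_species Number of species.
#' @param lineages_per_species Lineage count per species: a single integer, a
#'   vector to sample from uniformly, or a `function(n)` returning `n` counts.
#'   Species with more than one lineage are planted cryptic complexes.
#' @param within_divergence Maximum K2P distance within a lineage (default 0.02).
#' @param between_divergence Minimum K2P distance between lineages of
#'   different species -- and between lineages of the same cryptic complex --
#'   (default 0.08). Must exceed `within_divergence`.
#' @param records_per_species Records per species: integer vector sampled
#'   uniformly, or a `function(n)`.
#' @param fraction_singleton Fraction of species reduced to a single record.
#' @param fraction_mislabelled Fraction of species involved in a planted
#'   misidentification (donor/receiver pairs; one donor record is relabelled
#'   with the receiver's name, making both species discordant).
#' @param fraction_tag_coded Fraction of species renamed with an informal tag
#'   code (e.g. `"Genus sp. SIM-7"`).
#' @param fraction_pseudogene Fraction of records given an in-frame internal
#'   stop codon (planted NUMTs).
#' @param sequence_length Amplicon length in bp (default 313).
#' @param ts_tv_ratio Transition/transversion ratio of the substitution
#'   process (default 2, typical for COI).
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_species = 20,
                       lineages_per_species = 1,
                       within_divergence = 0.02,
                       between_divergence = 0.08,
                       records_per_species = 2:12,
                       fraction_singleton = 0,
                       fraction_mislabelled = 0,
                       fraction_tag_coded = 0,
                       fraction_pseudogene = 0,
                       sequence_length = 313,
                       ts_tv_ratio = 2) {
  fracs <- c(fraction_singleton, fraction_mislabelled, fraction_tag_coded,
             fraction_pseudogene)
  if (any(fracs < 0 | fracs > 1)) abort_argument("fractions must be in [0, 1]")
  if (within_divergence >= between_divergence) {
    abort_argument("within_divergence must be smaller than between_divergence")
  }
  if (n_species < 1 || sequence_length < 30) {
    abort_argument("need n_species >= 1 and sequence_length >= 30")
  }
  structure(list(n_species = n_species,
                 lineages_per_species = lineages_per_species,
                 within_divergence = within_divergence,
                 between_divergence = between_divergence,
                 records_per_species = records_per_species,
                 fraction_singleton = fraction_singleton,
                 fraction_mislabelled = fraction_mislabelled,
                 fraction_tag_coded = fraction_tag_coded,
                 fraction_pseudogene = fraction_pseudogene,
                 sequence_length = sequence_length,
                 ts_tv_ratio = ts_tv_ratio),
            class = "sim_params")
}

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS <- list(A = c("C", "T"), G = c("C", "T"),
                      C = c("A", "G"), T = c("A", "G"))

# substitute n_sub sites under a K80 process
mutate_k80 <- function(chars, n_sub, ts_tv_ratio = 2) {
  if (n_sub == 0) return(chars)
  sites <- sample(length(chars), n_sub)
  p_ts <- ts_tv_ratio / (ts_tv_ratio + 1)
  for (s in sites) {
    base <- chars[s]
    chars[s] <- if (stats::runif(1) < p_ts) TRANSITION[[base]] else
      sample(TRANSVERSIONS[[base]], 1)
  }
  chars
}

# coding sequences must be stop-free in frame 1 (the pseudogene screen would
# otherwise reject them); rewrite any stop codon's third base
make_stop_free <- function(chars, stops = c("TAA", "TAG", "TGA")) {
  n_codons <- length(chars) %/% 3
  for (i in seq_len(n_codons)) {
    codon <- paste(chars[(3 * i - 2):(3 * i)], collapse = "")
    if (codon %in% stops) chars[3 * i] <- "C"
  }
  chars
}

has_internal_stop <- function(chars, stops = c("TAA", "TAG", "TGA")) {
  n_codons <- length(chars) %/% 3
  if (n_codons < 2) return(FALSE)
  for (i in seq_len(n_codons - 1)) {
    if (paste(chars[(3 * i - 2):(3 * i)], collapse = "") %in% stops) return(TRUE)
  }
  FALSE
}

# mutate but stay stop-free (retry, then fall back to an exact copy)
mutate_clean <- function(chars, n_sub, ts_tv_ratio) {
  for (try in seq_len(50)) {
    cand <- mutate_k80(chars, n_sub, ts_tv_ratio)
    if (!has_internal_stop(cand)) return(cand)
  }
  chars
}

int2alpha <- function(i) {
  vapply(i, function(x) {
    out <- ""
    repeat {
      out <- paste0(letters[((x - 1) %% 26) + 1], out)
      x <- (x - 1) %/% 26
      if (x == 0) break
    }
    out
  }, character(1))
}

sim_taxonomy_scaffold <- function(n_species) {
  n_fam <- max(1, ceiling(n_species / 5))
  fam_of <- ((seq_len(n_species) - 1) %% n_fam) + 1
  data.frame(
    species_idx = seq_len(n_species),
    phylum = "Annelida",
    class = "Polychaeta",
    order = sprintf("Order%s", toupper(int2alpha(((fam_of - 1) %/% 3) + 1))),
    family = sprintf("Fam%sidae", int2alpha(fam_of)),
    genus = sprintf("Genus%s", int2alpha(seq_len(n_species))),
    species = sprintf("Genus%s %sensis", int2alpha(seq_len(n_species)),
                      int2alpha(seq_len(n_species))),
    stringsAsFactors = FALSE
  )
}

pair_k2p <- function(a, b) {
  k2p_from_codes(match(a, c("A", "C", "G", "T")), match(b, c("A", "C", "G", "T")))$d
}

# lineage ancestors: mutate a common root until all pairwise K2P distances
# clear between_divergence (+ a within-divergence margin so record-level noise
# cannot close the gap); bounded rejection sampling
draw_units <- function(n_units, p) {
  L <- p$sequence_length
  root <- make_stop_free(sample(c("A", "C", "G", "T"), L, replace = TRUE))
  m <- ceiling(L * p$between_divergence)
  floor_d <- p$between_divergence + p$within_divergence
  units <- vector("list", n_units)
  for (u in seq_len(n_units)) {
    for (try in seq_len(100)) {
      cand <- mutate_k80(root, m, p$ts_tv_ratio)
      ok <- !has_internal_stop(cand) &&
        (u == 1 || all(vapply(units[seq_len(u - 1)],
                              function(x) pair_k2p(cand, x) >= floor_d,
                              logical(1))))
      if (ok) break
      if (try == 100) abort_argument("could not place divergent lineages; relax parameters")
    }
    units[[u]] <- cand
  }
  units
}

resolve_counts <- function(spec, n) {
  if (is.function(spec)) return(spec(n))
  if (length(spec) == 1) return(rep(spec, n))
  sample(spec, n, replace = TRUE)
}

#' Simulate a barcode reference library with planted truth
#'
#' Generates `n_species` species, each with one or more divergent lineages
#' (units), draws records as noisy copies of their lineage ancestor, and
#' plants the requested faults: singletons, misidentifications (name swapped
#' to another species), tag-coded names and pseudogenes (internal stop
#' codons). The returned `truth` records, per record, the planted species and
#' lineage; the planted cluster partition (one cluster per lineage); the
#' grade each species must receive when clustered inside the divergence gap
#' (E for mislabel-involved species, D below three records, C for multi-
#' lineage species, A above ten records, B otherwise, judged on records that
#' survive filtering); and the planted fault sets. Identical parameters and
#' seed give identical output.
#'
#' @param params A [sim_params()] object.
#' @param seed Optional integer seed (sets the RNG via [set.seed()]).
#' @return A list with `records` (a barcode record table as from
#'   [read_barcode_table()]) and `truth`.
#' @export
simulate_library <- function(params = sim_params(), seed = NULL) {
  if (!inherits(params, "sim_params")) abort_argument("params must be a sim_params object")
  if (!is.null(seed)) set.seed(seed)
  p <- params
  scaffold <- sim_taxonomy_scaffold(p$n_species)
  k <- resolve_counts(p$lineages_per_species, p$n_species)
  unit_species <- rep(seq_len(p$n_species), k)
  units <- draw_units(length(unit_species), p)
  unit_ids <- sprintf("UNIT%03d", seq_along(units))

  n_rec <- resolve_counts(p$records_per_species, p$n_species)
  n_rec <- pmax(n_rec, 1L)
  singleton_sp <- sample(p$n_species, round(p$fraction_singleton * p$n_species))
  n_rec[singleton_sp] <- 1L

  max_noise <- max(0L, floor(p$sequence_length * p$within_divergence * 0.4))
  rec_species <- integer(0)
  rec_unit <- integer(0)
  for (s in seq_len(p$n_species)) {
    su <- which(unit_species == s)
    rec_species <- c(rec_species, rep(s, n_rec[s]))
    rec_unit <- c(rec_unit, rep_len(su, n_rec[s]))   # round-robin over lineages
  }
  n_total <- length(rec_species)
  seqs <- character(n_total)
  for (i in seq_len(n_total)) {
    chars <- mutate_clean(units[[rec_unit[i]]], sample(0:max_noise, 1), p$ts_tv_ratio)
    seqs[i] <- paste(chars, collapse = "")
  }

  record_id <- sprintf("SIM%05d", seq_len(n_total))
  species_name <- scaffold$species[rec_species]
  taxonomy <- scaffold[rec_species, c("phylum", "class", "order", "family", "genus"),
                       drop = FALSE]

  # tag codes: rename whole species with an informal code suffix
  tag_sp <- sample(p$n_species, round(p$fraction_tag_coded * p$n_species))
  for (s in tag_sp) {
    species_name[rec_species == s] <-
      sprintf("%s sp. SIM-%d", scaffold$genus[s], s)
  }

  # mislabels: donor record relabelled with the receiver species' identity
  n_pairs <- floor(round(p$fraction_mislabelled * p$n_species) / 2)
  donors <- receivers <- integer(0)
  mislabelled_records <- character(0)
  if (n_pairs > 0) {
    eligible <- setdiff(which(n_rec >= 2), tag_sp)
    if (length(eligible) < 2 * n_pairs) {
      abort_argument("not enough multi-record species to plant mislabels")
    }
    pick <- sample(eligible, 2 * n_pairs)
    donors <- pick[seq_len(n_pairs)]
    receivers <- pick[n_pairs + seq_len(n_pairs)]
    for (j in seq_len(n_pairs)) {
      victim <- which(rec_species == donors[j])[1]
      species_name[victim] <- scaffold$species[receivers[j]]
      taxonomy[victim, ] <- scaffold[receivers[j],
                                     c("phylum", "class", "order", "family", "genus")]
      mislabelled_records <- c(mislabelled_records, record_id[victim])
    }
  }

  # pseudogenes: plant an internal in-frame stop codon
  candidates <- setdiff(seq_len(n_total), match(mislabelled_records, record_id))
  pseudo_idx <- sample(candidates, round(p$fraction_pseudogene * n_total))
  for (i in pseudo_idx) {
    n_codons <- p$sequence_length %/% 3
    pos <- sample(2:(n_codons - 1), 1)
    substr(seqs[i], 3 * pos - 2, 3 * pos) <- "TAA"
  }

  records <- data.frame(
    record_id = record_id,
    species_name = species_name,
    phylum = taxonomy$phylum, class = taxonomy$class, order = taxonomy$order,
    family = taxonomy$family, genus = taxonomy$genus,
    bin_id = unit_ids[rec_unit],
    sequence = seqs,
    length_bp = nchar(seqs),
    flags = "",
    region = sample(c("Red Sea", "Arabian Gulf", "Gulf of Oman"), n_total, replace = TRUE),
    mined_from_genbank = stats::runif(n_total) < 0.3,
    stringsAsFactors = FALSE
  )

  # planted grades, judged on records surviving the upstream filter
  surviving <- setdiff(seq_len(n_total), pseudo_idx)
  affected <- scaffold$species[unique(c(donors, receivers))]
  surv_names <- species_name[surviving]
  surv_units <- rec_unit[surviving]
  graded_names <- setdiff(unique(surv_names), species_name[detect_tag_code(species_name)])
  planted_grade <- vapply(graded_names, function(nm) {
    idx <- surv_names == nm
    if (nm %in% affected) return("E")
    if (sum(idx) < 3) return("D")
    if (length(unique(surv_units[idx])) > 1) return("C")
    if (sum(idx) > 10) "A" else "B"
  }, character(1))

  truth <- list(
    records = data.frame(record_id = record_id,
                         species = scaffold$species[rec_species],
                         unit = unit_ids[rec_unit], stringsAsFactors = FALSE),
    partition = stats::setNames(unit_ids[rec_unit], record_id),
    grades = data.frame(species_name = graded_names, grade = unname(planted_grade),
                        stringsAsFactors = FALSE),
    mislabels = mislabelled_records,
    tag_coded_species = scaffold$species[tag_sp],
    pseudogene_records = record_id[pseudo_idx],
    params = p
  )
  list(records = records, truth = truth)
}

#' Simulate an ASV table with planted truth
#'
#' Draws amplicon sequence variants as noisy copies of planted lineage
#' ancestors (noise bounded by the within-lineage divergence), assigns read
#' counts across samples with a controlled fraction of low-read ASVs (total
#' reads below 10), and attaches taxonomy labels at mixed depths
#' (phylum-only through genus) with an optional planted mislabel rate at the
#' family rank.
#'
#' @param params A [sim_params()] object (governs lineages and divergences).
#' @param n_asvs Number of ASVs to draw.
#' @param n_samples Number of samples the reads are spread over.
#' @param low_read_fraction Fraction of ASVs given total reads in 1..9.
#' @param label_depth_probs Probabilities that an ASV is labelled down to
#'   phylum, class, order, family or genus (named vector, summing to 1).
#' @param label_noise Probability that a family/genus label is swapped with
#'   another family's (planted taxonomic mislabel).
#' @param seed Optional integer seed.
#' @return A list with `asvs` (a `data.frame`: `asv_id`, `sequence`,
#'   `total_reads`, `reads_<sample>` columns, taxonomy columns) and `truth`
#'   (`asv_id`, planted `unit`, `species`, `family`, `low_read`,
#'   `mislabelled`).
#' @export
simulate_asvs <- function(params = sim_params(), n_asvs = 200, n_samples = 3,
                          low_read_fraction = 0,
                          label_depth_probs = c(phylum = 0.15, class = 0.20,
                                                order = 0.15, family = 0.25,
                                                genus = 0.25),
                          label_noise = 0, seed = NULL) {
  if (!inherits(params, "sim_params")) abort_argument("params must be a sim_params object")
  if (!is.null(seed)) set.seed(seed)
  p <- params
  scaffold <- sim_taxonomy_scaffold(p$n_species)
  k <- resolve_counts(p$lineages_per_species, p$n_species)
  unit_species <- rep(seq_len(p$n_species), k)
  units <- draw_units(length(unit_species), p)
  unit_ids <- sprintf("UNIT%03d", seq_along(units))

  max_noise <- max(0L, floor(p$sequence_length * p$within_divergence * 0.4))
  asv_unit <- sort(rep_len(seq_along(units), n_asvs))
  seqs <- vapply(seq_len(n_asvs), function(i) {
    paste(mutate_clean(units[[asv_unit[i]]], sample(0:max_noise, 1), p$ts_tv_ratio),
          collapse = "")
  }, character(1))
  asv_id <- sprintf("ASV_%05d", seq_len(n_asvs))

  low <- logical(n_asvs)
  low[sample(n_asvs, round(low_read_fraction * n_asvs))] <- TRUE
  totals <- integer(n_asvs)
  totals[low] <- sample(1:9, sum(low), replace = TRUE)
  totals[!low] <- 10 + stats::rnbinom(sum(!low), mu = 400, size = 0.5)
  reads <- t(vapply(totals, function(tt) {
    as.integer(stats::rmultinom(1, tt, rep(1 / n_samples, n_samples)))
  }, integer(n_samples)))
  colnames(reads) <- sprintf("reads_S%02d", seq_len(n_samples))

  depth_ranks <- c("phylum", "class", "order", "family", "genus")
  depths <- sample(depth_ranks, n_asvs, replace = TRUE, prob = label_depth_probs)
  sp_of <- unit_species[asv_unit]
  tax <- scaffold[sp_of, c("phylum", "class", "order", "family", "genus"), drop = FALSE]
  mislabelled <- stats::runif(n_asvs) < label_noise
  n_fam <- length(unique(scaffold$family))
  if (any(mislabelled) && n_fam > 1) {
    for (i in which(mislabelled)) {
      other <- sample(setdiff(unique(scaffold$family), tax$family[i]), 1)
      donor <- scaffold[match(other, scaffold$family), ]
      tax$family[i] <- donor$family
      tax$genus[i] <- donor$genus
    }
  } else {
    mislabelled[] <- FALSE
  }
  for (i in seq_len(n_asvs)) {
    keep_to <- match(depths[i], depth_ranks)
    if (keep_to < length(depth_ranks)) {
      tax[i, (keep_to + 1):length(depth_ranks)] <- NA_character_
    }
  }

  asvs <- data.frame(asv_id = asv_id, sequence = seqs, total_reads = totals,
                     stringsAsFactors = FALSE)
  asvs <- cbind(asvs, as.data.frame(reads), tax)
  asvs$species <- NA_character_
  rownames(asvs) <- NULL
  truth <- data.frame(asv_id = asv_id, unit = unit_ids[asv_unit],
                      species = scaffold$species[sp_of],
                      family = scaffold$family[sp_of],
                      low_read = low, mislabelled = mislabelled,
                      stringsAsFactors = FALSE)
  list(asvs = asvs, truth = truth)
}
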