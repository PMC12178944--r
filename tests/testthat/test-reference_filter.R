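test_that("tag-coded names are detected and plain binomials are not", {
  expect_true(detect_tag_code("Tharyx sp. CIRR-IK-2019-1"))
  expect_true(detect_tag_code("Syllis gracilis LINEAGE-B2"))
  expect_false(detect_tag_code("Hydroides elegans"))
  expect_false(detect_tag_code("Tharyx sp."))        # no code token after sp.
  expect_false(detect_tag_code("Platynereis dumerilii complex"))
  # user-supplied pattern overrides the built-in rule
  expect_true(detect_tag_code("Syllis gracilis", pattern = "gracilis"))
})

test_that("the stop-codon screen follows the genetic code and ambiguity rules", {
  expect_equal(screen_pseudogene("ATGTAAGGG", 1, 5), "internal_stop")
  expect_equal(screen_pseudogene("ATGGGGGGG", 1, 5), "clean")
  expect_equal(screen_pseudogene("ATGNNNGGG", 1, 5), "clean")   # N can avoid a stop
  expect_equal(screen_pseudogene("ATGTARGGG", 1, 5), "internal_stop")  # TAR forced
  # TGA is tryptophan in the invertebrate mitochondrial code, a stop in the standard one
  expect_equal(screen_pseudogene("ATGTGAGGG", 1, 5), "clean")
  expect_equal(screen_pseudogene("ATGTGAGGG", 1, 1), "internal_stop")
  # terminal stop codons are not "internal"
  expect_equal(screen_pseudogene("ATGGGGTAA", 1, 5), "clean")
  # frame shifts move the codon grid
  expect_equal(screen_pseudogene("GATGTAAGGG", 2, 5), "internal_stop")
  expect_error(screen_pseudogene("ATGGGG", 4), class = "refaudit_argument_error")
})

test_that("the screen agrees with whole-sequence enumeration on short ambiguous inputs", {
  # oracle: a sequence has a forced internal stop iff EVERY resolution of its
  # ambiguity codes contains an internal stop
  enumerate_oracle <- function(seq, stops) {
    expand <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                   Y = c("C", "T"), W = c("A", "T"), N = c("A", "C", "G", "T"))
    chars <- strsplit(seq, "")[[1]]
    grids <- expand.grid(lapply(chars, function(ch) expand[[ch]]),
                         stringsAsFactors = FALSE)
    all(apply(grids, 1, function(row) {
      n_codons <- length(row) %/% 3
      any(vapply(seq_len(n_codons - 1), function(i) {
        paste(row[(3 * i - 2):(3 * i)], collapse = "") %in% stops
      }, logical(1)))
    }))
  }
  set.seed(42)
  alphabet <- c("A", "C", "G", "T", "R", "Y", "W", "N")
  for (rep in 1:40) {
    len <- 3 * sample(2:6, 1)
    seq <- paste(sample(alphabet, len, replace = TRUE,
                        prob = c(rep(0.22, 4), rep(0.03, 4))), collapse = "")
    expected <- if (enumerate_oracle(seq, c("TAA", "TAG"))) "internal_stop" else "clean"
    expect_equal(screen_pseudogene(seq, 1, 5), expected, info = seq)
  }
})

test_that("library filtering charges each record to its first failing rule", {
  recs <- make_records(5)
  recs$sequence[1] <- clean_coding_seq(250)
  recs$length_bp[1] <- 250
  recs$species_name[2] <- NA
  out <- filter_library(recs)
  expect_equal(out$report$kept, 3)
  expect_equal(out$report$rejected_by_rule[["length"]], 1)
  expect_equal(out$report$rejected_by_rule[["species_name"]], 1)
  expect_equal(out$report$rejected_ids$length, "R0001")

  # unnamed AND flagged: species_name rule comes first
  recs2 <- make_records(2)
  recs2$species_name[1] <- NA
  recs2$flags[1] <- "contamination"
  out2 <- filter_library(recs2)
  expect_equal(out2$report$rejected_by_rule[["species_name"]], 1)
  expect_equal(out2$report$rejected_by_rule[["flags"]], 0)

  # other rules: bin, flags, tag code, pseudogene
  recs3 <- make_records(5)
  recs3$bin_id[1] <- NA
  recs3$flags[2] <- "stop_codon"
  recs3$species_name[3] <- "Tharyx sp. CIRR-IK-2019-1"
  substr(recs3$sequence[4], 4, 6) <- "TAA"
  out3 <- filter_library(recs3)
  expect_equal(unname(out3$report$rejected_by_rule[c("bin", "flags", "tag_code", "pseudogene")]),
               rep(1L, 4))
  expect_equal(out3$report$kept, 1)

  empty <- filter_library(make_records(0))
  expect_equal(empty$report$kept, 0)
  expect_equal(sum(empty$report$rejected_by_rule), 0)
})

test_that("filter accounting balances and filtering is idempotent on fuzzed libraries", {
  for (seed in 1:5) {
    sim <- simulate_library(sim_params(n_species = 15, records_per_species = 1:6,
                                       fraction_tag_coded = 0.2,
                                       fraction_pseudogene = 0.1,
                                       fraction_singleton = 0.2), seed = seed)
    recs <- sim$records
    set.seed(seed + 100)
    # random extra corruption
    recs$species_name[sample(nrow(recs), 2)] <- NA
    drop <- sample(nrow(recs), 2)
    recs$sequence[drop] <- substr(recs$sequence[drop], 1, 120)
    recs$length_bp[drop] <- 120
    out <- filter_library(recs)
    expect_equal(out$report$kept + sum(out$report$rejected_by_rule), nrow(recs))
    again <- filter_library(out$kept)
    expect_equal(again$kept, out$kept)
    expect_equal(sum(again$report$rejected_by_rule), 0)
    # planted pseudogenes never survive
    expect_false(any(sim$truth$pseudogene_records %in% out$kept$record_id))
  }
})

test_that("ASV read filtering is a strict boundary on total reads", {
  asvs <- data.frame(asv_id = c("a", "b", "c"), total_reads = c(9, 10, 11))
  expect_equal(filter_asvs(asvs, 10)$asv_id, c("b", "c"))
  expect_equal(filter_asvs(asvs, 0), asvs)
  expect_error(filter_asvs(asvs, -1), class = "refaudit_argument_error")
})
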