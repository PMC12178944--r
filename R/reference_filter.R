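# Reference-library inclusion/exclusion rules and the stop-codon pseudogene
# screen. Records failing a rule are charged to the FIRST failing rule so the
# rejection log always balances against the input size.

# stop codons by NCBI translation table; 5 = invertebrate mitochondrial
STOP_CODONS <- list(
  `1` = c("TAA", "TAG", "TGA"),
  `2` = c("TAA", "TAG", "AGA", "AGG"),
  `5` = c("TAA", "TAG")
)

IUPAC_EXPAND <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Detect tag-coded species names
#'
#' Tag codes are informal suffixes appended to a species name to mark lineages
#' or populations (for example `"Tharyx sp. CIRR-IK-2019-1"`). They inflate
#' species counts and discordance reports, so tagged names are excluded before
#' auditing. A name is tag-coded when it contains `" sp."` followed by a code
#' token, or when a trailing token of two or more characters consists of
#' uppercase letters, digits and hyphens (mixing letters and digits/hyphens),
#' e.g. `"Syllis gracilis LINEAGE-B2"`.
#'
#' @param name Character vector of species names.
#' @param pattern Optional regular expression overriding the built-in rule;
#'   a name is then tag-coded iff it matches `pattern`.
#' @return Logical vector.
#' @export
detect_tag_code <- function(name, pattern = NULL) {
  if (!is.null(pattern)) return(grepl(pattern, name))
  sp_rule <- grepl("\\bsp\\.\\s*\\S+", name)
  last_token <- vapply(strsplit(trimws(name), "\\s+"), function(t) {
    if (length(t) < 3) return("")
    t[length(t)]
  }, character(1))
  trail_rule <- grepl("^[A-Z0-9-]{2,}$", last_token) &
    grepl("[A-Z]", last_token) & grepl("[0-9-]", last_token)
  sp_rule | trail_rule
}

#' Screen a sequence for internal stop codons
#'
#' Translates the (gap-stripped) sequence in the given reading frame under the
#' given genetic code and reports `"internal_stop"` when a stop codon occurs
#' before the final codon -- the signature of a nuclear pseudogene (NUMT) in
#' protein-coding barcode data. An ambiguous codon only counts as a stop when
#' every resolution of its IUPAC codes is a stop codon; a codon that can be
#' read through is given the benefit of the doubt.
#'
#' @param sequence DNA string (gaps allowed, removed before translation).
#' @param frame Reading frame, 1, 2 or 3.
#' @param genetic_code NCBI translation table id: 1 (standard), 2 (vertebrate
#'   mitochondrial) or 5 (invertebrate mitochondrial, the default for COI in
#'   invertebrates).
#' @return `"clean"` or `"internal_stop"`.
#' @export
screen_pseudogene <- function(sequence, frame = 1, genetic_code = 5) {
  if (!frame %in% 1:3) abort_argument("frame must be 1, 2 or 3")
  stops <- STOP_CODONS[[as.character(genetic_code)]]
  if (is.null(stops)) abort_argument(sprintf("unsupported genetic code: %s", genetic_code))
  seq <- gsub("[-.]", "", normalise_sequence(sequence))
  if (nchar(seq) < 3) abort_argument("sequence must be at least 3 bp after gap removal")
  chars <- seq_chars(seq)[frame:nchar(seq)]
  n_codons <- length(chars) %/% 3
  if (n_codons < 2) return("clean")
  for (i in seq_len(n_codons - 1)) {   # internal codons only
    codon <- chars[(3 * i - 2):(3 * i)]
    combos <- expand.grid(IUPAC_EXPAND[[codon[1]]], IUPAC_EXPAND[[codon[2]]],
                          IUPAC_EXPAND[[codon[3]]], stringsAsFactors = FALSE)
    resolved <- paste0(combos[[1]], combos[[2]], combos[[3]])
    if (all(resolved %in% stops)) return("internal_stop")
  }
  "clean"
}

#' Filtering criteria for a barcode reference library
#'
#' @param min_length_bp Records must be strictly longer than this (default 300,
#'   the conventional "barcode compliant" floor for COI-5P).
#' @param require_species_name Drop records without a species-level name.
#' @param require_bin Drop records without a cluster (BIN) label.
#' @param exclude_flags QC flags that disqualify a record.
#' @param exclude_tag_codes Drop records whose name is tag-coded
#'   (see [detect_tag_code()]).
#' @param screen_pseudogenes Run the stop-codon screen ([screen_pseudogene()]).
#' @param genetic_code Translation table for the screen (default 5).
#' @param frame Reading frame for the screen.
#' @param any_frame When `TRUE`, a record passes the screen if any of the three
#'   frames is stop-free (useful for mined sequences of unknown frame).
#' @param tag_pattern Optional regex overriding the tag-code rule.
#' @return An object of class `filter_criteria`.
#' @export
filter_criteria <- function(min_length_bp = 300,
                            require_species_name = TRUE,
                            require_bin = TRUE,
                            exclude_flags = c("contamination", "stop_codon", "indel"),
                            exclude_tag_codes = TRUE,
                            screen_pseudogenes = TRUE,
                            genetic_code = 5,
                            frame = 1,
                            any_frame = FALSE,
                            tag_pattern = NULL) {
  if (min_length_bp <= 0) abort_argument("min_length_bp must be positive")
  structure(list(min_length_bp = min_length_bp,
                 require_species_name = require_species_name,
                 require_bin = require_bin,
                 exclude_flags = exclude_flags,
                 exclude_tag_codes = exclude_tag_codes,
                 screen_pseudogenes = screen_pseudogenes,
                 genetic_code = genetic_code,
                 frame = frame,
                 any_frame = any_frame,
                 tag_pattern = tag_pattern),
            class = "filter_criteria")
}

#' Filter a barcode reference library
#'
#' Applies the inclusion rules in a fixed order -- length, species name,
#' cluster (BIN) label, QC flags, tag code, stop-codon pseudogene screen --
#' and charges each rejected record to the first rule it fails. The report
#' therefore balances exactly: `kept + sum(rejected_by_rule) == nrow(records)`,
#' and filtering the kept set again is a no-op.
#'
#' @param records Barcode record table (see [read_barcode_table()]).
#' @param criteria A [filter_criteria()] object.
#' @return A list with `kept` (the surviving record table) and `report`
#'   (a list with `kept`, `rejected_by_rule` and `rejected_ids`).
#' @export
filter_library <- function(records, criteria = filter_criteria()) {
  rules <- c("length", "species_name", "bin", "flags", "tag_code", "pseudogene")
  rejected_ids <- stats::setNames(vector("list", length(rules)), rules)
  if (nrow(records) == 0) {
    return(list(kept = records,
                report = list(kept = 0L,
                              rejected_by_rule = stats::setNames(integer(length(rules)), rules),
                              rejected_ids = rejected_ids)))
  }
  fail_rule <- rep(NA_character_, nrow(records))
  note <- function(which, rule) {
    fail_rule[is.na(fail_rule) & which] <<- rule
  }
  note(records$length_bp <= criteria$min_length_bp, "length")
  if (criteria$require_species_name) {
    note(is.na(records$species_name) | records$species_name == "", "species_name")
  }
  if (criteria$require_bin) {
    note(is.na(records$bin_id) | records$bin_id == "", "bin")
  }
  has_flag <- vapply(strsplit(ifelse(is.na(records$flags), "", records$flags), ","),
                     function(f) any(trimws(f) %in% criteria$exclude_flags),
                     logical(1))
  note(has_flag, "flags")
  if (criteria$exclude_tag_codes) {
    named <- !is.na(records$species_name) & records$species_name != ""
    tagged <- logical(nrow(records))
    tagged[named] <- detect_tag_code(records$species_name[named], criteria$tag_pattern)
    note(tagged, "tag_code")
  }
  if (criteria$screen_pseudogenes) {
    todo <- which(is.na(fail_rule))
    pseudo <- logical(nrow(records))
    for (i in todo) {
      frames <- if (criteria$any_frame) 1:3 else criteria$frame
      verdicts <- vapply(frames, function(f) {
        screen_pseudogene(records$sequence[i], f, criteria$genetic_code)
      }, character(1))
      pseudo[i] <- !any(verdicts == "clean")
    }
    note(pseudo, "pseudogene")
  }
  kept <- records[is.na(fail_rule), , drop = FALSE]
  rownames(kept) <- NULL
  counts <- stats::setNames(integer(length(rules)), rules)
  for (r in rules) {
    ids <- records$record_id[!is.na(fail_rule) & fail_rule == r]
    counts[[r]] <- length(ids)
    rejected_ids[[r]] <- ids
  }
  list(kept = kept,
       report = list(kept = nrow(kept), rejected_by_rule = counts,
                     rejected_ids = rejected_ids))
}

#' Filter ASVs by total read count
#'
#' Retains amplicon sequence variants whose total read count is at least
#' `min_reads` (the conventional metabarcoding noise filter removes ASVs with
#' fewer than 10 reads). Input order is preserved.
#'
#' @param asvs ASV table with a `total_reads` column.
#' @param min_reads Minimum total reads (default 10; ASVs with fewer are dropped).
#' @return The retained rows of `asvs`.
#' @export
filter_asvs <- function(asvs, min_reads = 10) {
  if (min_reads < 0) abort_argument("min_reads must be non-negative")
  out <- asvs[asvs$total_reads >= min_reads, , drop = FALSE]
  rownames(out) <- NULL
  out
}
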