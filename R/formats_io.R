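#' Default column dialect for BOLD-style barcode tables
#'
#' Public BOLD TSV exports name their columns as below; other sources can remap
#' any entry. Entries `id`, `species`, `bin` and `sequence` are required; the
#' remaining entries are optional and yield `NA` columns when the file lacks
#' them.
#'
#' @return Named list mapping logical field names to header names.
#' @export
bold_dialect <- function() {
  list(
    id = "processid",
    species = "species_name",
    bin = "bin_uri",
    sequence = "nuc",
    phylum = "phylum_name",
    class = "class_name",
    order = "order_name",
    family = "family_name",
    genus = "genus_name",
    flags = "flags",
    region = "region",
    genbank = "institution_storing"
  )
}

#' Read a BOLD-style barcode record table
#'
#' Parses a TSV of reference barcode records into the package's record table:
#' one row per record with columns `record_id`, `species_name`, the
#' [TAX_RANKS] up to genus, `bin_id`, `sequence`, `length_bp`, `flags`
#' (comma-separated subset of `contamination`, `stop_codon`, `indel`),
#' `region` and `mined_from_genbank`. Sequences are uppercased, `U` is
#' normalised to `T` and non-IUPAC characters are rejected; `length_bp` is the
#' number of non-gap characters. Empty cells in the species/BIN columns become
#' `NA` (absent).
#'
#' @param path Path to a tab-separated file with a header row.
#' @param dialect Named list mapping logical column names to header names;
#'   see [bold_dialect()].
#' @return A `data.frame` of barcode records.
#' @export
read_barcode_table <- function(path, dialect = bold_dialect()) {
  if (!file.exists(path)) abort_argument(sprintf("file not found: %s", path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("", "NA"), colClasses = "character")
  required <- c("id", "species", "bin", "sequence")
  for (key in required) {
    col <- dialect[[key]]
    if (is.null(col) || !(col %in% names(tab))) {
      abort_format(sprintf("barcode table is missing required column '%s' (mapped from '%s')",
                           col %||% key, key))
    }
  }
  get_col <- function(key) {
    col <- dialect[[key]]
    if (!is.null(col) && col %in% names(tab)) tab[[col]] else rep(NA_character_, nrow(tab))
  }
  ids <- get_col("id")
  if (anyNA(ids)) abort_validation("barcode table has rows with an empty record id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort_validation(sprintf("duplicate record ids: %s", paste(dup, collapse = ", ")))
  }
  seqs <- get_col("sequence")
  if (anyNA(seqs)) abort_validation("barcode table has rows with an empty sequence")
  seqs <- normalise_sequence(seqs)
  genbank_raw <- get_col("genbank")
  records <- data.frame(
    record_id = ids,
    species_name = trimws(get_col("species")),
    phylum = get_col("phylum"),
    class = get_col("class"),
    order = get_col("order"),
    family = get_col("family"),
    genus = get_col("genus"),
    bin_id = get_col("bin"),
    sequence = seqs,
    length_bp = vapply(seqs, ungapped_length, integer(1), USE.NAMES = FALSE),
    flags = ifelse(is.na(get_col("flags")), "", get_col("flags")),
    region = get_col("region"),
    mined_from_genbank = !is.na(genbank_raw) & grepl("GenBank", genbank_raw, fixed = TRUE),
    stringsAsFactors = FALSE
  )
  rownames(records) <- NULL
  records
}

#' Read a FASTA file into a named character vector
#'
#' Wraps [ape::read.FASTA()] and adds the validation this pipeline needs:
#' duplicate headers and empty sequences are errors rather than silently
#' accepted. Sequences are returned uppercase with `U` normalised to `T`.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort_argument(sprintf("file not found: %s", path))
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0) return(stats::setNames(character(0), character(0)))
  seqs <- vapply(as.character(dna), paste, character(1), collapse = "")
  dup <- unique(names(seqs)[duplicated(names(seqs))])
  if (length(dup) > 0) {
    abort_validation(sprintf("duplicate FASTA headers: %s", paste(dup, collapse = ", ")))
  }
  if (any(nchar(seqs) == 0)) {
    abort_validation(sprintf("empty sequence for: %s",
                             paste(names(seqs)[nchar(seqs) == 0], collapse = ", ")))
  }
  normalise_sequence(stats::setNames(toupper(seqs), names(seqs)))
}

#' Write sequences to FASTA
#'
#' `write_fasta(read_fasta(f), g)` followed by `read_fasta(g)` is the identity
#' on valid files.
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    abort_validation("all sequences must be named")
  }
  if (anyDuplicated(names(seqs))) abort_validation("duplicate sequence names")
  if (any(nchar(seqs) == 0)) abort_validation("empty sequences cannot be written")
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  invisible(path)
}

CHECKLIST_STATUSES <- c("accepted", "nomen_nudum", "interim_unpublished",
                        "temporary_name", "uncertain", "taxon_inquirendum")

#' Read a regional species checklist
#'
#' Reads a CSV or TSV checklist with (case-insensitive) columns `species`,
#' `genus`, `family` and `status`, keeping only entries whose status is in
#' `status_filter`. Status tokens come from a closed vocabulary (`accepted`,
#' `nomen_nudum`, `interim_unpublished`, `temporary_name`, `uncertain`,
#' `taxon_inquirendum`); anything else is a validation error. Names with an
#' unclear taxonomic status are excluded by default so they never inflate
#' species counts. An optional `synonyms` column (entries separated by `=`,
#' `;`, `|` or `,`) is parsed into a list column of alternative names.
#'
#' @param path Path to a `.csv` (comma) or other (tab) delimited file.
#' @param status_filter Character vector of statuses to keep.
#' @return A `data.frame` with columns `species_name`, `genus`, `family`,
#'   `status` and list column `synonyms`.
#' @export
read_checklist <- function(path, status_filter = "accepted") {
  if (!file.exists(path)) abort_argument(sprintf("file not found: %s", path))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                           na.strings = c("", "NA"), quote = "\"", comment.char = "")
  names(tab) <- tolower(names(tab))
  find_col <- function(nm, aliases = nm) {
    hit <- intersect(aliases, names(tab))
    if (length(hit) == 0) abort_format(sprintf("checklist is missing required column '%s'", nm))
    tab[[hit[1]]]
  }
  species <- trimws(find_col("species", c("species", "species_name", "scientificname")))
  genus <- find_col("genus")
  family <- find_col("family")
  status <- tolower(gsub("[ \\-]", "_", trimws(find_col("status"))))
  bad <- setdiff(unique(status[!is.na(status)]), CHECKLIST_STATUSES)
  if (length(bad) > 0) {
    abort_validation(sprintf("unknown checklist status token(s): %s", paste(bad, collapse = ", ")))
  }
  if (any(is.na(species))) abort_validation("checklist has entries without a species name")
  synonyms <- if ("synonyms" %in% names(tab)) {
    lapply(tab[["synonyms"]], function(x) {
      if (is.na(x)) return(character(0))
      parts <- trimws(strsplit(x, "[=;|,]")[[1]])
      parts[nzchar(parts)]
    })
  } else {
    rep(list(character(0)), nrow(tab))
  }
  out <- data.frame(species_name = species, genus = genus, family = family,
                    status = status, stringsAsFactors = FALSE)
  out$synonyms <- synonyms
  keep <- out$status %in% status_filter
  # synonyms that duplicate the accepted name itself carry no information
  out$synonyms <- lapply(seq_len(nrow(out)),
                         function(i) setdiff(out$synonyms[[i]], out$species_name[i]))
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialise a tree to a newick string
#'
#' @param tree A `phylo` tree (see [ape::read.tree()]).
#' @return A single newick string, terminated by `;`.
#' @export
write_newick <- function(tree) {
  if (!inherits(tree, "phylo")) abort_argument("tree must be a 'phylo' object")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup) > 0) {
    abort_validation(sprintf("duplicate leaf labels: %s", paste(dup, collapse = ", ")))
  }
  ape::write.tree(tree)
}

#' Parse a newick string
#'
#' @param text A newick string.
#' @return A `phylo` tree.
#' @export
read_newick <- function(text) {
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) abort_format("could not parse newick string")
  tree
}
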