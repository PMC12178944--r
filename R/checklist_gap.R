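# Cross-reference a regional checklist against a barcode library and report
# coverage at species, genus and family rank.

#' Canonicalise a scientific name
#'
#' Normalises a name for comparison: trims and collapses whitespace, removes
#' parenthesised chunks (subgenus interpolations, author-year citations),
#' strips trailing authorship (anything from a comma on, and capitalised
#' tokens after the epithet), then maps through `synonym_map` when the result
#' is a known synonym. Comparisons in [coverage()] run on canonical forms so
#' alternative representations of the same name collapse together.
#'
#' @param name Character vector of names.
#' @param synonym_map Named character vector mapping synonym -> canonical name.
#' @return Character vector of canonical names.
#' @export
canonicalise <- function(name, synonym_map = NULL) {
  x <- gsub("\\([^)]*\\)", " ", name)
  x <- sub(",.*$", "", x)
  x <- gsub("\\s+", " ", trimws(x))
  x <- vapply(strsplit(x, " ", fixed = TRUE), function(tok) {
    if (length(tok) > 2) {
      auth <- which(grepl("^[A-Z]", tok[-(1:2)]))
      if (length(auth) > 0) tok <- tok[seq_len(auth[1] + 1)]
    }
    paste(tok, collapse = " ")
  }, character(1))
  if (!is.null(synonym_map)) {
    hit <- match(x, names(synonym_map))
    x[!is.na(hit)] <- unname(synonym_map[hit[!is.na(hit)]])
  }
  x
}

#' Checklist coverage of a barcode library
#'
#' Reports, for each rank, how much of a regional checklist is represented in
#' a (filtered) barcode library. A checklist species is *barcoded* when its
#' canonical name -- or any of its synonyms -- occurs among the library's
#' species names. A genus or family is barcoded when at least one of its
#' checklist species is barcoded, or when the library contains any record of
#' that genus/family name (so a rank can be covered through congeners absent
#' from the checklist, which is why genus and family percentages typically
#' exceed the species percentage).
#'
#' @param checklist A `data.frame` with `species_name`, `genus`, `family`
#'   columns and optionally a `synonyms` list column
#'   (see [read_checklist()]).
#' @param library Barcode record table with `species_name` and, if available,
#'   `genus` and `family` columns.
#' @param synonym_map Optional named vector mapping synonym -> canonical name,
#'   applied to both sides.
#' @param digits Percent precision (default 0, i.e. whole percentages;
#'   half-up rounding).
#' @return A list with per-rank lists (`species`, `genus`, `family`, each
#'   `total`, `barcoded`, `percent`) and a per-family breakdown `data.frame`
#'   `by_family` (`family`, `n_species_total`, `n_species_barcoded`,
#'   `n_sequences`).
#' @export
coverage <- function(checklist, library, synonym_map = NULL, digits = 0) {
  if (is.null(checklist) || nrow(checklist) == 0) {
    abort_argument("checklist must be non-empty")
  }
  cl_species <- canonicalise(checklist$species_name, synonym_map)
  lib_named <- !is.na(library$species_name) & library$species_name != ""
  lib_species <- unique(canonicalise(library$species_name[lib_named], synonym_map))

  syn_lists <- if (!is.null(checklist$synonyms)) checklist$synonyms else
    rep(list(character(0)), nrow(checklist))
  barcoded <- vapply(seq_len(nrow(checklist)), function(i) {
    cand <- c(cl_species[i], canonicalise(syn_lists[[i]], synonym_map))
    any(cand %in% lib_species)
  }, logical(1))

  lib_genera <- if ("genus" %in% names(library)) {
    unique(library$genus[lib_named & !is.na(library$genus)])
  } else {
    unique(vapply(strsplit(lib_species, " ", fixed = TRUE), `[`, character(1), 1))
  }
  lib_families <- if ("family" %in% names(library)) {
    unique(library$family[lib_named & !is.na(library$family)])
  } else character(0)

  rank_cov <- function(values, lib_values) {
    vocab <- unique(values[!is.na(values)])
    hit <- vapply(vocab, function(v) {
      any(barcoded[values == v], na.rm = TRUE) || v %in% lib_values
    }, logical(1))
    list(total = length(vocab), barcoded = sum(hit),
         percent = round_half_up(100 * sum(hit) / length(vocab), digits))
  }

  species_cov <- list(total = length(unique(cl_species)),
                      barcoded = sum(barcoded),
                      percent = round_half_up(100 * sum(barcoded) / length(unique(cl_species)),
                                              digits))
  genus_cov <- rank_cov(checklist$genus, lib_genera)
  family_cov <- rank_cov(checklist$family, lib_families)

  fams <- unique(checklist$family[!is.na(checklist$family)])
  lib_fam_col <- if ("family" %in% names(library)) library$family else rep(NA_character_, nrow(library))
  by_family <- data.frame(
    family = fams,
    n_species_total = vapply(fams, function(f) sum(checklist$family == f, na.rm = TRUE), integer(1)),
    n_species_barcoded = vapply(fams, function(f) {
      sum(barcoded & !is.na(checklist$family) & checklist$family == f)
    }, integer(1)),
    n_sequences = vapply(fams, function(f) sum(!is.na(lib_fam_col) & lib_fam_col == f), integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(by_family) <- NULL
  list(species = species_cov, genus = genus_cov, family = family_cov,
       by_family = by_family, digits = digits)
}
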