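# shared internals: rank vocabulary, rounding, sequence validation, errors

#' Taxonomic ranks used throughout the package
#'
#' Ordered from the most inclusive to the least inclusive rank. Taxonomies are
#' represented as data frames (or named character vectors) with these columns;
#' an absent rank is `NA`.
#'
#' @format A character vector of length 6.
#' @export
TAX_RANKS <- c("phylum", "class", "order", "family", "genus", "species")

# round half away from zero (reports print e.g. 70.5% -> 71%); base round()
# would round to even
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

# truncate (not round) to two decimals; mirrors ratio arithmetic done on
# printed two-decimal values
trunc2 <- function(x) floor(x * 100 + 1e-9) / 100

IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")
GAP_CHARS <- c("-", ".")

abort_format <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("refaudit_format_error", "refaudit_error", "error")))
}

abort_validation <- function(msg) {
  stop(errorCondition(msg, class = c("refaudit_validation_error", "refaudit_error", "error")))
}

abort_argument <- function(msg) {
  stop(errorCondition(msg, class = c("refaudit_argument_error", "refaudit_error", "error")))
}

# uppercase, U -> T, reject non-IUPAC characters (fail fast on corrupt data)
normalise_sequence <- function(x, what = "sequence") {
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  chars <- unique(strsplit(paste(x, collapse = ""), "", fixed = TRUE)[[1]])
  bad <- setdiff(chars, c(IUPAC_CHARS, GAP_CHARS))
  if (length(bad) > 0) {
    abort_validation(sprintf("%s contains non-IUPAC characters: %s",
                             what, paste(bad, collapse = ", ")))
  }
  x
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# non-gap length of a possibly gapped sequence
ungapped_length <- function(x) {
  nchar(gsub("[-.]", "", x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
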