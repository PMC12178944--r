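# Kimura two-parameter (K80) distances with pairwise deletion, and
# neighbour-joining trees over the resulting matrices.

# integer encoding: A=1 C=2 G=3 T=4, everything else NA. Transitions (A<->G,
# C<->T) are exactly the pairs whose codes differ by 2.
encode_dna <- function(x) {
  match(seq_chars(normalise_sequence(x)), c("A", "C", "G", "T"))
}

k2p_from_codes <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  if (n == 0) {
    abort_validation("no comparable (unambiguous, ungapped) sites between the two sequences")
  }
  dif <- a[ok] - b[ok]
  ts <- sum(abs(dif) == 2)
  tv <- sum(dif != 0) - ts
  P <- ts / n
  Q <- tv / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    return(list(d = Inf, sites_used = n, P = P, Q = Q, saturated = TRUE))
  }
  list(d = -0.5 * log(w1 * sqrt(w2)), sites_used = n, P = P, Q = Q, saturated = FALSE)
}

#' Kimura two-parameter distance between two aligned sequences
#'
#' Computes the K80 distance `d = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q))`,
#' where `P` and `Q` are the proportions of transitions and transversions over
#' the pairwise-complete sites: positions where both sequences carry an
#' unambiguous `A`/`C`/`G`/`T`. Gaps and ambiguity codes are excluded site by
#' site (pairwise deletion), so partially overlapping fragments are compared
#' over their shared region only. When the log argument is non-positive the
#' distance is saturated and reported as `Inf` with `saturated = TRUE` (such
#' pairs always split in downstream clustering).
#'
#' @param seq_a,seq_b Aligned sequences of equal length.
#' @return A list with `d`, `sites_used`, `P`, `Q` and `saturated`.
#' @export
k2p_distance <- function(seq_a, seq_b) {
  a <- encode_dna(seq_a)
  b <- encode_dna(seq_b)
  if (length(a) != length(b)) {
    abort_argument("sequences must be aligned to the same length")
  }
  k2p_from_codes(a, b)
}

#' Pairwise K2P distance matrix
#'
#' Computes the full symmetric matrix of [k2p_distance()] values over a set of
#' aligned sequences, with the per-pair count of comparable sites alongside.
#' Saturated pairs are `Inf` and raise a single warning naming them.
#'
#' @param sequences Named character vector (or list) of aligned sequences of
#'   equal length; at least two.
#' @return An object of class `k2p_dist`: a list with `labels`, `d` (symmetric
#'   distance matrix) and `sites_used`.
#' @export
pairwise_matrix <- function(sequences) {
  sequences <- unlist(sequences)
  n <- length(sequences)
  if (n < 2) abort_argument("at least two sequences are required")
  if (is.null(names(sequences))) names(sequences) <- as.character(seq_len(n))
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1) {
    abort_argument("all sequences must have the same aligned length")
  }
  labels <- names(sequences)
  codes <- t(vapply(sequences, encode_dna, integer(lens[1])))
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  sites <- matrix(0L, n, n, dimnames = list(labels, labels))
  diag(sites) <- rowSums(!is.na(codes))
  saturated_pairs <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      res <- tryCatch(k2p_from_codes(codes[i, ], codes[j, ]),
                      refaudit_validation_error = function(e) {
                        abort_validation(sprintf("pair (%s, %s): %s",
                                                 labels[i], labels[j], conditionMessage(e)))
                      })
      d[i, j] <- d[j, i] <- res$d
      sites[i, j] <- sites[j, i] <- res$sites_used
      if (res$saturated) {
        saturated_pairs <- c(saturated_pairs, sprintf("(%s, %s)", labels[i], labels[j]))
      }
    }
  }
  if (length(saturated_pairs) > 0) {
    warning(sprintf("%d saturated pair(s) reported as Inf: %s",
                    length(saturated_pairs),
                    paste(utils::head(saturated_pairs, 5), collapse = " ")))
  }
  structure(list(labels = labels, d = d, sites_used = sites), class = "k2p_dist")
}

#' @export
print.k2p_dist <- function(x, ...) {
  cat(sprintf("K2P distance matrix: %d sequences, mean distance %.4f\n",
              length(x$labels), mean(x$d[upper.tri(x$d)][is.finite(x$d[upper.tri(x$d)])])))
  invisible(x)
}

as_dist_matrix <- function(x) {
  if (inherits(x, "k2p_dist")) x$d else as.matrix(x)
}

#' Neighbour-joining tree from a distance matrix
#'
#' Builds an unrooted tree by the classic Saitou-Nei agglomeration
#' (via [ape::nj()]). Negative branch lengths, which NJ can produce on
#' non-additive matrices, are clamped to zero; the total clamped length is
#' recorded in the `"negative_length_clamped"` attribute.
#'
#' @param matrix A `k2p_dist` object or a symmetric numeric matrix with
#'   row/column names; all entries must be finite.
#' @return A `phylo` tree.
#' @export
nj_tree <- function(matrix) {
  d <- as_dist_matrix(matrix)
  if (nrow(d) < 3) abort_argument("at least three taxa are required")
  if (any(!is.finite(d))) {
    abort_argument(paste("distance matrix contains non-finite entries;",
                         "build trees per cluster after removing saturated pairs"))
  }
  tree <- ape::nj(d)
  deficit <- -sum(tree$edge.length[tree$edge.length < 0])
  tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "negative_length_clamped") <- deficit
  tree
}
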