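# independent oracles and tiny fixture builders used across the suite

# connected components by breadth-first search over the d<=t (or d<t) graph;
# independent of the union-find in the package
bfs_components <- function(d, threshold, strict = FALSE) {
  n <- nrow(d)
  adj <- if (strict) d < threshold else d <= threshold
  diag(adj) <- FALSE
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# two component labelings describe the same partition?
same_partition <- function(a, b) {
  identical(match(a, unique(a)), match(b, unique(b)))
}

rand_dna <- function(len) paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                                collapse = "")

# a taxonomy row from a path of labels (phylum downwards)
tax_row <- function(...) {
  labs <- c(...)
  row <- stats::setNames(as.list(rep(NA_character_, 6)), TAX_RANKS)
  row[seq_along(labs)] <- labs
  as.data.frame(row, stringsAsFactors = FALSE)
}

tax_table <- function(...) do.call(rbind, list(...))

# a clean, stop-free coding sequence of the given length (>300 bp by default)
clean_coding_seq <- function(len = 321) {
  paste(rep("ATG", ceiling(len / 3)), collapse = "") |> substr(1, len)
}

# minimal valid record table
make_records <- function(n, species = sprintf("Genus%02d elegans", seq_len(n)),
                         bin = sprintf("BIN%03d", seq_len(n)),
                         seq_len_bp = 321) {
  if (n == 0) {
    return(make_records(1)[0, , drop = FALSE])
  }
  data.frame(
    record_id = sprintf("R%04d", seq_len(n)),
    species_name = species,
    phylum = "Annelida", class = "Polychaeta", order = "OrderA",
    family = "Famaidae", genus = "Genusa",
    bin_id = bin,
    sequence = vapply(seq_len(n), function(i) clean_coding_seq(seq_len_bp), character(1)),
    length_bp = seq_len_bp,
    flags = "",
    region = NA_character_,
    mined_from_genbank = FALSE,
    stringsAsFactors = FALSE
  )
}

# build a cluster/species record table from a named list cluster -> species names
records_from_clusters <- function(clusters) {
  do.call(rbind, lapply(names(clusters), function(cl) {
    data.frame(cluster = cl, species_name = clusters[[cl]], stringsAsFactors = FALSE)
  }))
}
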