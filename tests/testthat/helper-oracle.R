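# Naive reference implementations used as independent oracles. These are
# deliberately written with plain-R string primitives (substring loops,
# expand.grid enumeration, table-based reverse complements) so they share
# no code path with the package's Biostrings-based featurizer.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# all canonical k-mers for one k, by brute-force enumeration of all 4^k
oracle_canonical_set <- function(k) {
  grid <- do.call(expand.grid,
                  c(rep(list(c("A", "C", "G", "T")), k),
                    stringsAsFactors = FALSE))
  kmers <- apply(grid[, rev(seq_len(k)), drop = FALSE], 1, paste,
                 collapse = "")
  rc <- vapply(kmers, oracle_revcomp, character(1), USE.NAMES = FALSE)
  sort(unique(pmin(kmers, rc)))
}

# window-by-window canonical k-mer frequencies; counts kept as integers
# and divided only at the end, so the expected values are exact ratios
oracle_featurize <- function(seq, k_min, k_max) {
  seq <- toupper(seq)
  unlist(lapply(k_min:k_max, function(k) {
    levels <- oracle_canonical_set(k)
    counts <- stats::setNames(integer(length(levels)), levels)
    n_valid <- 0L
    if (nchar(seq) >= k) {
      for (i in seq_len(nchar(seq) - k + 1L)) {
        w <- substring(seq, i, i + k - 1L)
        if (grepl("[^ACGT]", w)) next
        canon <- min(w, oracle_revcomp(w))
        counts[canon] <- counts[canon] + 1L
        n_valid <- n_valid + 1L
      }
    }
    if (n_valid > 0L) counts / n_valid else counts * 0
  }))
}

random_dna <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# small two-class reference set for fast model-level tests
toy_refs <- function(seed = 1L) {
  set.seed(seed)
  list(
    plasmids = Biostrings::DNAStringSet(stats::setNames(
      vapply(1:6, function(i) random_dna(3000), character(1)),
      paste0("p", 1:6))),
    chromosomes = Biostrings::DNAStringSet(stats::setNames(
      vapply(1:6, function(i) random_dna(3000), character(1)),
      paste0("c", 1:6))))
}
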