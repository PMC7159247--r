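# Canonical k-mer featurization: the sole feature representation used by the
# classifiers. A k-mer and its reverse complement are collapsed onto the
# lexicographically smaller of the two ("canonical", A < C < G < T), making
# the features strand-independent.

.index_cache <- new.env(parent = emptyenv())

#' Reverse complement of a nucleotide string
#'
#' Thin character-level wrapper used when working with plain strings rather
#' than `DNAStringSet` objects.
#'
#' @param x Character vector of A/C/G/T strings.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' reverse_complement("ACGT")
reverse_complement <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Canonical form of a k-mer
#'
#' Returns the lexicographically smaller of a k-mer and its reverse
#' complement, the conventional strand-independent representative.
#'
#' @param kmer Character vector of k-mers over A/C/G/T.
#' @return Character vector of canonical k-mers.
#' @export
#' @examples
#' canonical_kmer(c("TTT", "ACG", "AT"))
canonical_kmer <- function(kmer) {
  if (any(grepl("[^ACGT]", kmer)))
    stop("canonical_kmer() requires k-mers over A/C/G/T only; ",
         "pre-filter ambiguous windows")
  pmin(kmer, reverse_complement(kmer))
}

# Distinct canonical k-mers for a single k: 4^k / 2 for odd k (no k-mer is
# its own reverse complement), (4^k + 4^(k/2)) / 2 for even k (palindromes
# are their own complement and are not paired).
.n_canonical <- function(k) {
  if (k %% 2 == 1) 4^k / 2 else (4^k + 4^(k / 2)) / 2
}

#' Number of canonical k-mer features over a k range
#'
#' Dimension of the feature space: the count of distinct canonical k-mers
#' for k in `[k_min, k_max]`. For the default range 3..7 this is 10952.
#'
#' @param k_min,k_max Integer k-mer size range, `1 <= k_min <= k_max`.
#' @return Integer feature-space dimension.
#' @export
#' @examples
#' index_size(3, 7)  # 10952
index_size <- function(k_min = 3L, k_max = 7L) {
  if (k_min < 1 || k_min > k_max)
    stop("require 1 <= k_min <= k_max (got ", k_min, ", ", k_max, ")")
  as.integer(sum(vapply(k_min:k_max, .n_canonical, numeric(1))))
}

#' Build the canonical k-mer feature index
#'
#' Fixes the feature layout shared by the featurizer and every trained
#' model: canonical k-mers sorted lexicographically within each k-block,
#' blocks ordered by increasing k. The layout is identified by a signature
#' string that is stored with trained models, so that a model is only ever
#' applied to feature vectors with the layout it was trained on.
#'
#' @param k_min,k_max Integer k range (defaults 3 and 7).
#' @return An object of class `kmer_index`: list with `k_min`, `k_max`,
#'   per-k canonical k-mer names and column maps, block `offsets`, total
#'   dimension `D`, and `signature`.
#' @export
#' @examples
#' idx <- kmer_index(3, 7)
#' idx$D  # 10952
kmer_index <- function(k_min = 3L, k_max = 7L) {
  if (k_min < 1 || k_min > k_max)
    stop("require 1 <= k_min <= k_max (got ", k_min, ", ", k_max, ")")
  key <- paste0(k_min, ":", k_max)
  if (!is.null(.index_cache[[key]])) return(.index_cache[[key]])
  ks <- k_min:k_max
  blocks <- lapply(ks, function(k) {
    kmers <- mkAllStrings(c("A", "C", "G", "T"), k)  # lexicographic order
    rc <- as.character(reverseComplement(DNAStringSet(kmers)))
    canon <- pmin(kmers, rc)
    levels <- sort(unique(canon))
    list(k = k, canon = levels,
         col_map = match(canon, levels))  # 4^k columns -> canonical slot
  })
  sizes <- vapply(blocks, function(b) length(b$canon), numeric(1))
  idx <- structure(list(
    k_min = as.integer(k_min), k_max = as.integer(k_max),
    blocks = blocks,
    offsets = c(0, cumsum(sizes))[seq_along(ks)],
    D = as.integer(sum(sizes)),
    signature = paste0("canonical-lex/k", k_min, "-", k_max, "/v1")
  ), class = "kmer_index")
  .index_cache[[key]] <- idx
  idx
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("kmer_index: k =", x$k_min, "..", x$k_max, "| D =", x$D,
      "|", x$signature, "\n")
  invisible(x)
}

# Core featurization of a DNAStringSet. For each k, every width-k window is
# counted under its canonical form; windows containing non-ACGT characters
# are skipped (oligonucleotideFrequency counts only exact A/C/G/T words).
# Each k-block is then normalized to sum to 1 over that k's counted windows;
# a block with no valid window (sequence shorter than k, or all windows
# ambiguous) is left all-zero.
.featurize_core <- function(seqs, index) {
  n <- length(seqs)
  out <- matrix(0, nrow = n, ncol = index$D)
  colnames(out) <- unlist(lapply(index$blocks, `[[`, "canon"))
  if (n == 0L) return(out)
  for (b in seq_along(index$blocks)) {
    blk <- index$blocks[[b]]
    cnt <- oligonucleotideFrequency(seqs, width = blk$k)
    # collapse the 4^k plain-k-mer columns onto canonical slots
    canon_cnt <- t(rowsum(t(cnt), group = blk$col_map))
    tot <- rowSums(canon_cnt)
    tot[tot == 0] <- 1  # all-zero block stays all-zero
    cols <- index$offsets[b] + seq_len(ncol(canon_cnt))
    out[, cols] <- canon_cnt / tot
  }
  out
}

.as_dna <- function(seqs) {
  if (is(seqs, "DNAStringSet")) return(seqs)
  if (is(seqs, "DNAString")) return(DNAStringSet(seqs))
  DNAStringSet(toupper(as.character(seqs)))
}

#' Canonical k-mer frequency vector of one sequence
#'
#' Slides a width-k window (step 1) over the sequence for every k in the
#' index range; each window over A/C/G/T increments the count of its
#' canonical form, windows containing any other character are skipped.
#' Each k-block of the returned vector is normalized to sum to 1 over that
#' k's counted windows; blocks with no valid window are all zero.
#'
#' @param seq A single sequence: character string, `DNAString`, or
#'   length-1 `DNAStringSet`.
#' @param index A [kmer_index()] (default: the 3..7 index).
#' @return Named numeric vector of length `index$D`.
#' @export
#' @examples
#' v <- featurize("ACGT", kmer_index(2, 2))
#' v[v > 0]  # AC: 2/3, CG: 1/3
featurize <- function(seq, index = kmer_index()) {
  x <- .as_dna(seq)
  if (length(x) != 1L) stop("featurize() takes a single sequence; ",
                            "use featurize_batch() for sets")
  drop(.featurize_core(x, index))
}

#' Featurize an ordered set of sequences
#'
#' @param seqs A `DNAStringSet` (or character vector) of sequences.
#' @param index A [kmer_index()].
#' @param workers Number of parallel workers (forked processes; 1 = serial).
#'   Output is identical for any worker count, in input order.
#' @return Numeric matrix, one row per input sequence, `index$D` columns.
#' @export
featurize_batch <- function(seqs, index = kmer_index(), workers = 1L) {
  x <- .as_dna(seqs)
  if (workers <= 1L || length(x) < 2L ||
      .Platform$OS.type == "windows") {
    return(.featurize_core(x, index))
  }
  chunks <- split(seq_along(x), cut(seq_along(x), workers, labels = FALSE))
  parts <- parallel::mclapply(chunks, function(i) .featurize_core(x[i], index),
                              mc.cores = workers)
  do.call(rbind, parts)
}
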