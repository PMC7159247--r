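# Fragment sampling from reference sequence sets. Fragments are returned as
# a DNAStringSet with provenance (source_id, 0-based start) in mcols(), so
# every fragment can be audited against its reference.

.frag_set <- function(seqs, source_id, start0) {
  names(seqs) <- sprintf("%s:%d-%d", source_id, start0, start0 + width(seqs))
  mcols(seqs) <- S4Vectors::DataFrame(source_id = source_id, start = start0)
  seqs
}

#' Sample fixed-length fragments from references, with replacement
#'
#' Draws `n` fragments i.i.d. uniformly over all possible length-`L`
#' windows of the reference set: a reference with length `len >= L` is
#' chosen with probability proportional to `len - L + 1` (its number of
#' windows), then a start offset is drawn uniformly. References shorter
#' than `L` are ineligible.
#'
#' @param refs `DNAStringSet` of reference sequences.
#' @param L Fragment length (bp).
#' @param n Number of fragments to draw.
#' @param seed Integer seed; sampling is reproducible given the seed.
#' @param per_reference_uniform If `TRUE`, choose the reference uniformly
#'   instead of window-weighted. Default `FALSE`.
#' @return `DNAStringSet` of `n` fragments, `mcols()` columns `source_id`
#'   and `start` (0-based).
#' @export
sample_fragments <- function(refs, L, n, seed = 1L,
                             per_reference_uniform = FALSE) {
  lens <- width(refs)
  elig <- which(lens >= L)
  if (length(elig) == 0L)
    stop("no reference of length >= ", L,
         " (longest available: ", if (length(lens)) max(lens) else 0, " bp)")
  if (n == 0L) return(.frag_set(refs[integer(0)], character(0), integer(0)))
  set.seed(seed)
  nwin <- lens[elig] - L + 1
  prob <- if (per_reference_uniform) rep(1, length(elig)) else nwin
  pick <- elig[sample.int(length(elig), n, replace = TRUE, prob = prob)]
  start0 <- floor(runif(n) * (lens[pick] - L + 1))
  frags <- subseq(refs[pick], start = start0 + 1, width = L)
  .frag_set(frags, seq_ids(refs)[pick], as.integer(start0))
}

#' Fragment count needed to cover eligible references to a depth
#'
#' `ceil(depth * sum(len_i) / L)` over references with `len_i >= L`;
#' 0 when none qualifies. Used for the 100 kb and 500 kb training bins,
#' where the plasmid database is too small for a fixed fragment count and
#' fragments are instead drawn to cover all sufficiently long plasmids to
#' a target depth (5 in the reference configuration).
#'
#' @inheritParams sample_fragments
#' @param depth Target coverage depth (> 0).
#' @return Integer fragment count.
#' @export
depth_fragment_count <- function(refs, L, depth) {
  if (depth <= 0) stop("depth must be > 0")
  lens <- width(refs)
  usable <- sum(as.numeric(lens[lens >= L]))
  if (usable == 0) return(0L)
  as.integer(ceiling(depth * usable / L))
}

#' Tile references with overlapping fixed-length fragments
#'
#' Emits length-`L` fragments at starts `0, L/2, L, ...` while the fragment
#' fits, with the last start moved to `len - L` when the final stride does
#' not land there, so every base of each eligible reference is covered
#' (at depth at most 2). References shorter than `L` are skipped (count
#' reported via a
#' message). This is the held-out evaluation fragmenter: overlapping
#' L-long fragments covering each reference with overlap L/2.
#'
#' @inheritParams sample_fragments
#' @return `DNAStringSet` of fragments with provenance in `mcols()`.
#' @export
tile_fragments <- function(refs, L) {
  lens <- width(refs)
  skipped <- sum(lens < L)
  if (skipped > 0L)
    message(skipped, " reference(s) shorter than ", L, " bp skipped")
  ids <- seq_ids(refs)
  step <- max(1L, as.integer(L / 2))
  src <- integer(0); start0 <- integer(0)
  for (i in which(lens >= L)) {
    s <- seq.int(0L, lens[i] - L, by = step)
    if (s[length(s)] != lens[i] - L) {
      # anchor the final fragment at the reference end; replacing the last
      # regular start (rather than appending) keeps coverage complete while
      # never covering any base more than twice
      if (length(s) >= 2L) s[length(s)] <- lens[i] - L
      else s <- c(s, lens[i] - L)
    }
    src <- c(src, rep.int(i, length(s)))
    start0 <- c(start0, s)
  }
  if (length(src) == 0L)
    return(.frag_set(refs[integer(0)], character(0), integer(0)))
  frags <- subseq(refs[src], start = start0 + 1, width = L)
  .frag_set(frags, ids[src], as.integer(start0))
}

#' Split references into training and held-out sets
#'
#' The split is by reference sequence, never by fragment, so no evaluation
#' fragment shares a source with any training fragment.
#'
#' @param refs `DNAStringSet`.
#' @param fraction Fraction of references held out (default 0.25).
#' @param seed Integer seed.
#' @return List with elements `train` and `heldout` (`DNAStringSet`s).
#' @export
split_references <- function(refs, fraction = 0.25, seed = 1L) {
  stopifnot(fraction >= 0, fraction < 1)
  set.seed(seed)
  n_hold <- round(length(refs) * fraction)
  hold <- sort(sample.int(length(refs), n_hold))
  list(train = refs[setdiff(seq_along(refs), hold)], heldout = refs[hold])
}
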