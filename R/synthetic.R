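# Synthetic reference sets and simulated communities. Real plasmid and
# chromosome databases are large downloads; for development, testing and
# benchmarking, this module generates compositionally distinct "plasmid"
# and "chromosome" sequence sets from Markov sources, and assembles them
# into simulated communities with log-normal genome abundances and
# geometric plasmid copy numbers.

#' Markov sequence source
#'
#' A base-composition model: order 0 draws i.i.d. bases with the target GC
#' fraction; order >= 1 additionally applies a same-base persistence bias,
#' giving the chain genuine short-range structure (the nominal GC then
#' holds approximately, not exactly). A full transition table may be
#' supplied instead of `gc`.
#'
#' @param gc Target GC fraction in (0, 1) (ignored when `transition` is
#'   given).
#' @param order Markov order (integer >= 0, default 1).
#' @param persistence Same-base bias for order >= 1: the probability of
#'   repeating the previous base is inflated by this factor (default 0.2).
#' @param transition Optional explicit transition matrix, `4^order` rows
#'   (contexts in lexicographic A/C/G/T order) by 4 columns (next base
#'   A,C,G,T); rows must sum to 1 (tolerance 1e-9).
#' @return Object of class `markov_source`.
#' @export
markov_source <- function(gc = 0.5, order = 1L, persistence = 0.2,
                          transition = NULL) {
  order <- as.integer(order)
  stopifnot(order >= 0)
  if (is.null(transition)) {
    stopifnot(gc >= 0, gc <= 1)
    base <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    if (order == 0L) {
      transition <- matrix(base, nrow = 1,
                           dimnames = list(NULL, names(base)))
    } else {
      ncontext <- 4L^order
      transition <- matrix(rep(base, each = ncontext), ncontext, 4,
                           dimnames = list(NULL, names(base)))
      last_base <- ((seq_len(ncontext) - 1L) %% 4L) + 1L  # last letter of context
      for (i in seq_len(ncontext))
        transition[i, last_base[i]] <- transition[i, last_base[i]] *
          (1 + persistence)
      transition <- transition / rowSums(transition)
    }
  } else {
    transition <- as.matrix(transition)
    if (nrow(transition) != 4^order || ncol(transition) != 4)
      stop("transition must be 4^order x 4")
    if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-9))
      stop("transition rows must be non-negative and sum to 1")
  }
  structure(list(order = order, transition = transition, gc = gc),
            class = "markov_source")
}

#' Generate a random sequence from a Markov source
#'
#' @param source A [markov_source()].
#' @param length Sequence length (bp, >= 1).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return A `DNAString`.
#' @export
generate_sequence <- function(source, length, seed = 1L) {
  stopifnot(inherits(source, "markov_source"), length >= 1)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  if (source$order == 0L) {
    idx <- sample.int(4L, length, replace = TRUE, prob = source$transition[1, ])
    return(DNAString(paste(bases[idx], collapse = "")))
  }
  trans <- source$transition
  ncontext <- nrow(trans)
  cum <- t(apply(trans, 1, cumsum))
  c1 <- cum[, 1]; c2 <- cum[, 2]; c3 <- cum[, 3]
  # seed the chain with an order-length prefix from the marginal composition
  marginal <- colMeans(trans)
  prefix <- sample.int(4L, source$order, replace = TRUE, prob = marginal)
  out <- integer(length)
  n_pre <- min(source$order, length)
  out[seq_len(n_pre)] <- prefix[seq_len(n_pre)]
  if (length > source$order) {
    # context index: base-4 encoding of the previous `order` bases
    ctx <- sum((prefix - 1L) * 4L^((source$order - 1L):0L)) + 1L
    u <- runif(length - source$order)
    pow <- 4L^(source$order - 1L)
    for (i in seq.int(source$order + 1L, length)) {
      ui <- u[i - source$order]
      b <- 1L + (ui > c1[ctx]) + (ui > c2[ctx]) + (ui > c3[ctx])
      out[i] <- b
      ctx <- ((ctx - 1L) %% pow) * 4L + b
    }
  }
  DNAString(paste(bases[out], collapse = ""))
}

.log_uniform <- function(n, range) {
  exp(runif(n, log(range[1]), log(range[2])))
}

#' Generate a synthetic plasmid/chromosome reference benchmark
#'
#' Two labeled reference sets drawn from Markov sources whose GC contents
#' are pulled apart by `divergence`: the plasmid source sits at
#' `0.5 + 0.15 * divergence`, the chromosome source at
#' `0.5 - 0.15 * divergence`, so divergence 0 gives identical sources
#' (no signal) and divergence 1 gives GC 0.65 vs 0.35. Reference lengths
#' are log-uniform in the given ranges; the defaults (plasmids 1-30 kb,
#' chromosomes 100 kb - 1 Mb) put the medians about one order of
#' magnitude below the real databases' medians (~54 kb plasmids, ~3.7 Mb
#' chromosomes), keeping generation and training desk-sized while
#' preserving the plasmid-much-shorter-than-chromosome structure.
#'
#' @param n_plasmid,n_chrom Number of references per class.
#' @param plasmid_len_range,chrom_len_range Length ranges (bp) for the
#'   log-uniform reference lengths.
#' @param divergence Compositional gap in `[0, 1]`.
#' @param order Markov order of both sources (default 1).
#' @param seed Integer seed.
#' @return List of class `benchmark_refs`: `plasmids` and `chromosomes`
#'   (`DNAStringSet`s) plus the two `markov_source` objects.
#' @export
make_benchmark_refs <- function(n_plasmid = 20L, n_chrom = 5L,
                                plasmid_len_range = c(1000, 30000),
                                chrom_len_range = c(1e5, 1e6),
                                divergence = 0.8, order = 1L, seed = 1L) {
  stopifnot(divergence >= 0, divergence <= 1,
            plasmid_len_range[1] <= plasmid_len_range[2],
            chrom_len_range[1] <= chrom_len_range[2])
  src_p <- markov_source(gc = 0.5 + 0.15 * divergence, order = order)
  src_c <- markov_source(gc = 0.5 - 0.15 * divergence, order = order)
  set.seed(seed)
  len_p <- round(.log_uniform(n_plasmid, plasmid_len_range))
  len_c <- round(.log_uniform(n_chrom, chrom_len_range))
  seeds <- sample.int(2147483646L, n_plasmid + n_chrom)
  gen <- function(src, lens, seeds, prefix) {
    if (length(lens) == 0L) {
      x <- DNAStringSet()
    } else {
      x <- DNAStringSet(lapply(seq_along(lens), function(i)
        generate_sequence(src, lens[i], seed = seeds[i])))
    }
    names(x) <- sprintf("%s_%03d", prefix, seq_along(x))
    x
  }
  list(plasmids = gen(src_p, len_p, seeds[seq_len(n_plasmid)], "plasmid"),
       chromosomes = gen(src_c, len_c,
                         seeds[n_plasmid + seq_len(n_chrom)], "chrom"),
       plasmid_source = src_p, chromosome_source = src_c) |>
    structure(class = "benchmark_refs")
}

#' Simulate a community over a reference benchmark
#'
#' Assigns each plasmid to a host genome (uniformly at random), draws
#' genome relative abundances from a log-normal distribution
#' (`exp(N(0, sigma^2))`, normalized to sum to 1), and draws each
#' plasmid's integer copy number from a geometric distribution on
#' `{1, 2, ...}` with success parameter `p = min(1, log10(L) / 7)`, `L`
#' the plasmid length in bp -- so a long plasmid almost surely has a
#' single copy while short plasmids can be multi-copy.
#'
#' @param chromosomes `DNAStringSet` of host genomes.
#' @param plasmids `DNAStringSet` of plasmids.
#' @param sigma Log-normal shape (sd of log-abundance), >= 0; default 1.
#' @param seed Integer seed.
#' @return Object of class `simulated_community`: the sequences plus
#'   `host` (plasmid -> genome index), `abundance` (per genome, sums to
#'   1) and `copy_number` (per plasmid).
#' @export
simulate_community <- function(chromosomes, plasmids, sigma = 1, seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0")
  stopifnot(length(chromosomes) >= 1)
  set.seed(seed)
  n_g <- length(chromosomes); n_p <- length(plasmids)
  ab <- rlnorm(n_g, meanlog = 0, sdlog = sigma)
  ab <- ab / sum(ab)
  host <- if (n_p) sample.int(n_g, n_p, replace = TRUE) else integer(0)
  cn <- if (n_p) rgeom(n_p, prob = plasmid_copy_p(width(plasmids))) + 1L
        else integer(0)
  structure(list(chromosomes = chromosomes, plasmids = plasmids,
                 host = host, abundance = ab, copy_number = cn,
                 sigma = sigma, seed = as.integer(seed)),
            class = "simulated_community")
}

#' Geometric copy-number parameter for a plasmid length
#'
#' `p = min(1, log10(L) / 7)`: the success parameter of the copy-number
#' geometric distribution on `{1, 2, ...}` (expected copy number `1/p`),
#' decreasing expectation with plasmid length.
#'
#' @param L Plasmid length(s), bp.
#' @return Numeric vector of probabilities in (0, 1].
#' @export
plasmid_copy_p <- function(L) pmin(1, log10(L) / 7)

#' Community manifest table
#'
#' @param community A [simulate_community()] object.
#' @return `data.frame` with one row per replicon: `genome_id`,
#'   `abundance`, `replicon_id`, `class`, `length`, `copy_number`.
#' @export
community_manifest <- function(community) {
  g <- data.frame(genome_id = seq_ids(community$chromosomes),
                  abundance = community$abundance,
                  replicon_id = seq_ids(community$chromosomes),
                  class = "chromosome",
                  length = width(community$chromosomes),
                  copy_number = 1L)
  if (length(community$plasmids) == 0L) return(g)
  p <- data.frame(genome_id = seq_ids(community$chromosomes)[community$host],
                  abundance = community$abundance[community$host],
                  replicon_id = seq_ids(community$plasmids),
                  class = "plasmid",
                  length = width(community$plasmids),
                  copy_number = community$copy_number)
  rbind(g, p)
}

#' Draw contig-like fragments from a simulated community
#'
#' Stands in for read simulation and metagenome assembly: emits fragments
#' whose expected counts are proportional to
#' `abundance x copy_number x source length` (copy number 1 for
#' chromosomes), with fragment lengths log-uniform in `len_range`
#' (skewed short, echoing real assemblies where most contigs are short)
#' and clipped to the source length. Labels carry the source class.
#'
#' @param community A [simulate_community()] object.
#' @param n Number of fragments to draw (default 2000).
#' @param len_range Fragment length range, bp (default 200 - 50000,
#'   log-uniform).
#' @param seed Integer seed.
#' @return `DNAStringSet` of fragments; `mcols()` columns `source_id`,
#'   `class`, `start` (0-based), `length`.
#' @export
fragment_community <- function(community, n = 2000L,
                               len_range = c(200, 50000), seed = 1L) {
  stopifnot(inherits(community, "simulated_community"), n >= 0)
  srcs <- c(community$chromosomes, community$plasmids)
  cls <- rep(c("chromosome", "plasmid"),
             c(length(community$chromosomes), length(community$plasmids)))
  ab <- c(community$abundance, community$abundance[community$host])
  cn <- c(rep(1L, length(community$chromosomes)), community$copy_number)
  wt <- ab * cn * width(srcs)
  set.seed(seed)
  pick <- sample.int(length(srcs), n, replace = TRUE, prob = wt)
  flen <- pmin(round(.log_uniform(n, len_range)), width(srcs)[pick])
  flen <- pmax(flen, 1L)
  start0 <- floor(runif(n) * (width(srcs)[pick] - flen + 1))
  frags <- subseq(srcs[pick], start = start0 + 1, width = flen)
  names(frags) <- sprintf("frag_%05d", seq_len(n))
  mcols(frags) <- S4Vectors::DataFrame(source_id = seq_ids(srcs)[pick],
                                       class = cls[pick],
                                       start = as.integer(start0),
                                       length = as.integer(flen))
  frags
}
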