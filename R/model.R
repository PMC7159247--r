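# Length-binned binary classification. Four ridge-penalized logistic
# regression models, one per training fragment length (1 kb, 10 kb, 100 kb,
# 500 kb); a query sequence is routed to the model of nearest training
# length. The dispatch boundaries are the midpoints between consecutive
# training lengths: 5.5 kb, 55 kb, 300 kb.

.TRAIN_LENGTHS <- c(1000L, 10000L, 100000L, 500000L)
.BIN_BOUNDARIES <- c(5500, 55000, 300000)
.MODEL_FORMAT_VERSION <- 1L

#' Training configuration
#'
#' Bundles the sampling and fitting parameters for
#' [train_length_binned()]. The reference configuration uses 90,000
#' fragments per class for the two short bins and covers the long
#' plasmids to depth 5 for the 100 kb / 500 kb bins; scale `n_short` down
#' for desk-size runs.
#'
#' @param n_short Fragments per class for the 1 kb and 10 kb bins.
#' @param depth_long Coverage depth defining the plasmid fragment count
#'   for the 100 kb and 500 kb bins (see [depth_fragment_count()]).
#' @param lengths Training fragment lengths; one model is fitted per
#'   length with at least one eligible reference in each class.
#' @param k_min,k_max Feature k-mer range.
#' @param reg_strength Inverse regularization strength C of the L2
#'   penalty (larger = weaker penalty), default 1.
#' @param seed Integer seed controlling fragment sampling.
#' @return A list of class `training_config`.
#' @export
training_config <- function(n_short = 90000L, depth_long = 5,
                            lengths = .TRAIN_LENGTHS,
                            k_min = 3L, k_max = 7L,
                            reg_strength = 1, seed = 1L) {
  stopifnot(n_short >= 2, depth_long > 0, reg_strength > 0)
  structure(list(n_short = as.integer(n_short), depth_long = depth_long,
                 lengths = as.integer(lengths),
                 k_min = as.integer(k_min), k_max = as.integer(k_max),
                 reg_strength = reg_strength, seed = as.integer(seed)),
            class = "training_config")
}

#' Assign a sequence length to its training-length bin
#'
#' Each sequence is assigned to the closest training length among 1 kb,
#' 10 kb, 100 kb and 500 kb, i.e. the four half-open ranges (0, 5.5kb],
#' (5.5kb, 55kb], (55kb, 300kb], (300kb, Inf). Boundary lengths fall in
#' the lower bin.
#'
#' @param L Integer vector of sequence lengths (bp), all >= 1.
#' @return Integer vector of training lengths.
#' @export
#' @examples
#' assign_length_bin(c(5500, 5501, 300001))
assign_length_bin <- function(L) {
  if (any(L < 1)) stop("sequence length must be >= 1")
  .TRAIN_LENGTHS[findInterval(L, .BIN_BOUNDARIES, left.open = TRUE) + 1L]
}

#' Fit one logistic regression classifier
#'
#' L2-regularized binary logistic regression on k-mer frequency vectors,
#' fitted with glmnet's deterministic coordinate-descent solver (ridge
#' penalty, single lambda). The penalty is parameterized by the
#' conventional inverse strength C: lambda = 1 / (C * n).
#'
#' @param x Feature matrix (rows = examples), from [featurize_batch()].
#' @param y Labels: 1/`"plasmid"` = positive, 0/`"chromosome"` = negative.
#' @param reg_strength Inverse regularization strength C (default 1).
#' @param index The [kmer_index()] the features were built with (records
#'   the layout signature in the model).
#' @param train_length Training fragment length tag (bp), or `NA`.
#' @return Object of class `logistic_model`: weights `w`, intercept `b`,
#'   `train_length`, `index_signature`.
#' @export
train_logistic <- function(x, y, reg_strength = 1, index = kmer_index(),
                           train_length = NA_integer_) {
  y <- .as_binary_label(y)
  if (all(y == 1L)) stop("training data contains no chromosome examples")
  if (all(y == 0L)) stop("training data contains no plasmid examples")
  n <- nrow(x)
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = 1 / (reg_strength * n),
                        standardize = FALSE, thresh = 1e-8, maxit = 1e6)
  structure(list(w = as.numeric(fit$beta), b = as.numeric(fit$a0),
                 train_length = as.integer(train_length),
                 index_signature = index$signature,
                 reg_strength = reg_strength, n_train = n),
            class = "logistic_model")
}

.as_binary_label <- function(y) {
  if (is.character(y) || is.factor(y)) {
    y <- as.character(y)
    bad <- setdiff(unique(y), c("plasmid", "chromosome"))
    if (length(bad)) stop("unknown class label(s): ",
                          paste(bad, collapse = ", "))
    as.integer(y == "plasmid")
  } else as.integer(y)
}

#' @export
predict.logistic_model <- function(object, x, ...) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  plogis(drop(x %*% object$w) + object$b)
}

#' @export
print.logistic_model <- function(x, ...) {
  cat("logistic_model: train_length =", x$train_length, "bp | D =",
      length(x$w), "| n_train =", x$n_train, "\n")
  invisible(x)
}

#' Train the length-binned classifier
#'
#' For each training length, samples labeled fragments from the plasmid
#' and chromosome reference sets ([sample_fragments()]), featurizes them,
#' and fits one logistic model. The 1 kb / 10 kb bins use `n_short`
#' fragments per class; the 100 kb / 500 kb bins use the depth rule on the
#' plasmid references ([depth_fragment_count()]) and sample the chromosome
#' class to the same count, keeping training balanced. A bin in which
#' either class has no sufficiently long reference is skipped with a
#' warning; at classification time such bins fall back to the nearest
#' available model of smaller training length.
#'
#' @param plasmid_refs,chrom_refs `DNAStringSet` reference sets.
#' @param config A [training_config()].
#' @return Object of class `length_binned_model`.
#' @export
train_length_binned <- function(plasmid_refs, chrom_refs,
                                config = training_config()) {
  if (length(plasmid_refs) == 0L) stop("plasmid reference set is empty")
  if (length(chrom_refs) == 0L) stop("chromosome reference set is empty")
  index <- kmer_index(config$k_min, config$k_max)
  models <- list()
  for (bi in seq_along(config$lengths)) {
    L <- config$lengths[bi]
    p_ok <- any(width(plasmid_refs) >= L)
    c_ok <- any(width(chrom_refs) >= L)
    if (!p_ok || !c_ok) {
      miss <- c("plasmid", "chromosome")[!c(p_ok, c_ok)]
      warning("no ", paste(miss, collapse = " or "),
              " reference of length >= ", L, "; skipping the ", L,
              " bp bin", call. = FALSE)
      next
    }
    if (L %in% c(1000L, 10000L)) {
      n_p <- n_c <- config$n_short
    } else {
      n_p <- depth_fragment_count(plasmid_refs, L, config$depth_long)
      n_c <- n_p
    }
    fp <- sample_fragments(plasmid_refs, L, n_p,
                           seed = .bin_seed(config$seed, bi, 1L))
    fc <- sample_fragments(chrom_refs, L, n_c,
                           seed = .bin_seed(config$seed, bi, 2L))
    x <- rbind(featurize_batch(fp, index), featurize_batch(fc, index))
    y <- rep(c(1L, 0L), c(length(fp), length(fc)))
    models[[as.character(L)]] <-
      train_logistic(x, y, reg_strength = config$reg_strength,
                     index = index, train_length = L)
  }
  if (length(models) == 0L)
    stop("no bin could be trained: every training length lacks ",
         "references in at least one class")
  structure(list(models = models, boundaries = .BIN_BOUNDARIES,
                 index_signature = index$signature,
                 k_min = config$k_min, k_max = config$k_max,
                 config = config),
            class = "length_binned_model")
}

# deterministic per-bin, per-class sampling seed derived from the run seed
.bin_seed <- function(seed, bin, class) {
  as.integer((as.numeric(seed) * 131 + bin * 7919 + class * 104729) %%
               2147483647)
}

#' @export
print.length_binned_model <- function(x, ...) {
  cat("length_binned_model:", length(x$models), "bin(s) [",
      paste(names(x$models), collapse = ", "), "bp ] |", x$index_signature,
      "\n")
  invisible(x)
}

# route a requested train length to an available bin (nearest smaller,
# else the smallest available)
.resolve_bin <- function(requested, available) {
  if (requested %in% available) return(requested)
  smaller <- available[available < requested]
  if (length(smaller)) max(smaller) else min(available)
}

#' Classify sequences with a length-binned model
#'
#' Each sequence is routed by [assign_length_bin()] to the model of
#' nearest training length, featurized, and scored; results are returned
#' in input order regardless of the worker count. A sequence is labeled
#' plasmid when its plasmid-class probability exceeds `threshold`
#' (strictly; a probability of exactly 0.5 is labeled chromosome under
#' the default).
#'
#' @param seqs `DNAStringSet` (or character vector) of query sequences.
#' @param model A [train_length_binned()] model (or one from
#'   [load_model()]).
#' @param workers Parallel workers for featurization (default 1).
#' @param threshold Plasmid probability threshold (default 0.5).
#' @return `data.frame` with columns `id`, `length`, `bin` (training
#'   length used), `probability`, `label`, one row per input sequence in
#'   input order.
#' @export
classify <- function(seqs, model, workers = 1L, threshold = 0.5) {
  stopifnot(inherits(model, "length_binned_model"))
  index <- kmer_index(model$k_min, model$k_max)
  if (!identical(index$signature, model$index_signature))
    stop("feature layout mismatch: featurizer '", index$signature,
         "' vs model '", model$index_signature, "'")
  x <- .as_dna(seqs)
  n <- length(x)
  if (n == 0L)
    return(data.frame(id = character(0), length = integer(0),
                      bin = integer(0), probability = numeric(0),
                      label = character(0), stringsAsFactors = FALSE))
  lens <- width(x)
  avail <- as.integer(names(model$models))
  bins <- vapply(assign_length_bin(lens), .resolve_bin, integer(1),
                 available = avail)
  prob <- numeric(n)
  for (b in unique(bins)) {
    sel <- which(bins == b)
    feats <- featurize_batch(x[sel], index, workers = workers)
    prob[sel] <- predict(model$models[[as.character(b)]], feats)
  }
  data.frame(id = seq_ids(x), length = lens, bin = bins,
             probability = prob,
             label = ifelse(prob > threshold, "plasmid", "chromosome"),
             stringsAsFactors = FALSE)
}

#' Save / load a length-binned model
#'
#' The model file stores the per-bin weight vectors, intercepts, the k
#' range and feature-layout signature, the dispatch boundaries, and a
#' format version; loading validates all of them and fails loudly on a
#' truncated or incompatible file. Round-tripping preserves the model
#' exactly.
#'
#' @param model A `length_binned_model`.
#' @param path File path.
#' @return `load_model` returns the `length_binned_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "length_binned_model"))
  saveRDS(list(format_version = .MODEL_FORMAT_VERSION,
               package = "repliclass", model = model),
          path, version = 3L)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("cannot read model file '", path,
                                           "': ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$package, "repliclass") ||
      is.null(obj$format_version))
    stop("'", path, "' is not a repliclass model file")
  if (!identical(obj$format_version, .MODEL_FORMAT_VERSION))
    stop("model format version ", obj$format_version,
         " not supported (expected ", .MODEL_FORMAT_VERSION, ")")
  model <- obj$model
  expected <- kmer_index(model$k_min, model$k_max)$signature
  if (!identical(model$index_signature, expected))
    stop("model feature layout '", model$index_signature,
         "' does not match this package's layout '", expected, "'")
  model
}
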