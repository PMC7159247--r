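# Small k ranges (3..4, D = 168) keep these unit tests fast; the full
# 3..7 feature space is exercised in the pipeline-level tests.

test_that("assign_length_bin implements the four half-open ranges", {
  cases <- rbind(
    c(1, 1000), c(999, 1000), c(5500, 1000),
    c(5501, 10000), c(30000, 10000), c(55000, 10000),
    c(55001, 100000), c(300000, 100000),
    c(300001, 500000), c(5e6, 500000))
  expect_identical(assign_length_bin(cases[, 1]), as.integer(cases[, 2]))
  # vectorized dispatch partitions: exactly one bin per length
  set.seed(201)
  L <- sample.int(1e6, 500)
  expect_true(all(assign_length_bin(L) %in% c(1000, 10000, 100000, 500000)))
  expect_error(assign_length_bin(0), ">= 1")
})

test_that("train_logistic separates a trivially separable toy problem", {
  idx <- kmer_index(3, 4)
  seqs <- c(replicate(20, paste0(random_dna(200, c("A")), random_dna(50))),
            replicate(20, paste0(random_dna(200, c("C")), random_dna(50))))
  x <- featurize_batch(seqs, idx)
  y <- rep(c(1L, 0L), each = 20)
  fit <- train_logistic(x, y, index = idx)
  expect_identical(length(fit$w), idx$D)
  p <- predict(fit, x)
  expect_true(all(p > 0 & p < 1))
  expect_identical(as.integer(p > 0.5), y)
})

test_that("train_logistic rejects single-class input, naming the class", {
  idx <- kmer_index(3, 3)
  x <- featurize_batch(c("ACGTACGT", "GGGTTTAA"), idx)
  expect_error(train_logistic(x, c(1L, 1L), index = idx), "no chromosome")
  expect_error(train_logistic(x, c(0L, 0L), index = idx), "no plasmid")
  expect_error(train_logistic(x, c("plasmid", "weird"), index = idx),
               "unknown class")
})

test_that("two well-separated Markov sources give high held-out F1", {
  src_p <- markov_source(gc = 0.65, order = 1)
  src_c <- markov_source(gc = 0.35, order = 1)
  idx <- kmer_index(3, 4)
  gen <- function(src, n, seed) {
    set.seed(seed)
    seeds <- sample.int(1e6, n)
    Biostrings::DNAStringSet(lapply(seeds, function(s)
      generate_sequence(src, 1000, seed = s)))
  }
  x_tr <- featurize_batch(c(gen(src_p, 150, 1), gen(src_c, 150, 2)), idx)
  y_tr <- rep(c(1L, 0L), each = 150)
  fit <- train_logistic(x_tr, y_tr, index = idx)
  x_te <- featurize_batch(c(gen(src_p, 60, 3), gen(src_c, 60, 4)), idx)
  pred <- predict(fit, x_te) > 0.5
  truth <- rep(c(TRUE, FALSE), each = 60)
  tp <- sum(pred & truth); fp <- sum(pred & !truth); fn <- sum(!pred & truth)
  f1 <- 2 * tp / (2 * tp + fp + fn)
  expect_gte(f1, 0.95)
})

test_that("length-binned training skips bins without long references", {
  refs <- toy_refs(11)  # 3 kb references: only the 1 kb bin is trainable
  cfg <- training_config(n_short = 60, k_min = 3, k_max = 4, seed = 5)
  expect_warning(expect_warning(expect_warning(
    m <- train_length_binned(refs$plasmids, refs$chromosomes, cfg),
    "10000"), "100000"), "500000")
  expect_identical(names(m$models), "1000")
  expect_s3_class(m, "length_binned_model")
  expect_error(
    suppressWarnings(train_length_binned(
      refs$plasmids,
      Biostrings::DNAStringSet(c(c1 = random_dna(50))), cfg)),
    "no bin could be trained")
})

test_that("missing bins dispatch to the nearest available smaller bin", {
  refs <- toy_refs(12)
  cfg <- training_config(n_short = 60, k_min = 3, k_max = 4, seed = 6)
  m <- suppressWarnings(
    train_length_binned(refs$plasmids, refs$chromosomes, cfg))
  long_query <- Biostrings::DNAStringSet(c(q = random_dna(80000)))
  res <- classify(long_query, m)
  expect_identical(res$bin, 1000L)  # 100 kb bin absent -> fall back
  expect_identical(res$id, "q")
})

test_that("classification is order-preserving, worker-invariant, empty-safe", {
  refs <- toy_refs(13)
  cfg <- training_config(n_short = 60, k_min = 3, k_max = 4, seed = 7)
  m <- suppressWarnings(
    train_length_binned(refs$plasmids, refs$chromosomes, cfg))
  set.seed(202)
  qs <- Biostrings::DNAStringSet(stats::setNames(
    vapply(1:40, function(i) random_dna(sample(c(300, 2000, 8000), 1)),
           character(1)), paste0("q", 1:40)))
  r1 <- classify(qs, m, workers = 1)
  r8 <- classify(qs, m, workers = 8)
  expect_identical(r1, r8)
  expect_identical(r1$id, paste0("q", 1:40))
  r0 <- classify(Biostrings::DNAStringSet(), m)
  expect_identical(nrow(r0), 0L)
})

test_that("probability exactly at the threshold is labeled chromosome", {
  idx <- kmer_index(3, 3)
  null_model <- structure(list(
    models = list(`1000` = structure(
      list(w = rep(0, idx$D), b = 0, train_length = 1000L,
           index_signature = idx$signature, reg_strength = 1, n_train = 0L),
      class = "logistic_model")),
    boundaries = c(5500, 55000, 300000),
    index_signature = idx$signature, k_min = 3L, k_max = 3L,
    config = NULL), class = "length_binned_model")
  res <- classify(Biostrings::DNAStringSet(c(q = "ACGTACGT")), null_model)
  expect_equal(res$probability, 0.5)
  expect_identical(res$label, "chromosome")
})

test_that("model save/load round-trips exactly and rejects bad files", {
  refs <- toy_refs(14)
  cfg <- training_config(n_short = 60, k_min = 3, k_max = 4, seed = 8)
  m <- suppressWarnings(
    train_length_binned(refs$plasmids, refs$chromosomes, cfg))
  tf <- withr::local_tempfile(fileext = ".rds")
  save_model(m, tf)
  m2 <- load_model(tf)
  expect_identical(m2$models, m$models)
  qs <- Biostrings::DNAStringSet(c(a = random_dna(500), b = random_dna(6000)))
  expect_identical(classify(qs, m), classify(qs, m2))

  # identical training run -> bit-identical model file
  m_again <- suppressWarnings(
    train_length_binned(refs$plasmids, refs$chromosomes, cfg))
  tf2 <- withr::local_tempfile(fileext = ".rds")
  save_model(m_again, tf2)
  expect_identical(readBin(tf, "raw", file.size(tf)),
                   readBin(tf2, "raw", file.size(tf2)))

  # tampered signature
  obj <- readRDS(tf)
  obj$model$index_signature <- "canonical-lex/k9-9/v0"
  tf3 <- withr::local_tempfile(fileext = ".rds")
  saveRDS(obj, tf3)
  expect_error(load_model(tf3), "layout")

  # truncated file errors rather than misreading
  raw <- readBin(tf, "raw", file.size(tf))
  tf4 <- withr::local_tempfile(fileext = ".rds")
  writeBin(raw[seq_len(floor(length(raw) / 3))], tf4)
  expect_error(load_model(tf4), "cannot read model file")

  # not a model file at all
  tf5 <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), tf5)
  expect_error(load_model(tf5), "not a repliclass model")
  expect_error(load_model("/nonexistent/model.rds"), "not found")
})

test_that("null training data yields near-0.5 probabilities (calibration)", {
  # both classes drawn from one identical generator: no signal
  src <- markov_source(gc = 0.5, order = 0)
  idx <- kmer_index(3, 4)
  gen <- function(n, seed) {
    set.seed(seed)
    seeds <- sample.int(1e6, n)
    Biostrings::DNAStringSet(lapply(seeds, function(s)
      generate_sequence(src, 500, seed = s)))
  }
  x <- featurize_batch(c(gen(150, 21), gen(150, 22)), idx)
  fit <- train_logistic(x, rep(c(1L, 0L), each = 150), index = idx)
  p_held <- predict(fit, featurize_batch(gen(400, 23), idx))
  expect_gt(mean(p_held), 0.4)
  expect_lt(mean(p_held), 0.6)
  # held-out accuracy consistent with coin flipping (3 sigma binomial)
  acc <- mean((p_held > 0.5) == rep(c(TRUE, FALSE), 200))
  expect_lt(abs(acc - 0.5), 3 * 0.5 / sqrt(400))
})
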