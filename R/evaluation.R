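# Count-based binary-classification metrics with length stratification, and
# precision-recall curves. The plasmid class is the positive class
# throughout. Metrics count sequences, not bases: every contig contributes
# equally regardless of its length. (A length-weighted variant is provided
# for comparison; on realistic assemblies, where most contigs are short,
# the two can diverge dramatically.)

.truth_vector <- function(truth) {
  if (is.data.frame(truth)) truth <- stats::setNames(as.character(truth$label),
                                                     truth$id)
  bad <- setdiff(unique(truth), c("plasmid", "chromosome"))
  if (length(bad)) stop("unknown truth label(s): ", paste(bad, collapse = ", "))
  truth
}

#' Score classifications against truth labels
#'
#' Computes tp/fp/fn/tn counts and precision, recall, F1 with plasmid as
#' the positive class. Sequences with length not exceeding `min_length`
#' are excluded before counting (strict `>` cutoff). Zero-denominator
#' metrics are reported as 0.
#'
#' @param results `data.frame` from [classify()] (columns `id`, `length`,
#'   `label`; `label` is the predicted class).
#' @param truth Truth labels: named character vector (`id` ->
#'   `"plasmid"`/`"chromosome"`) or data frame with columns `id`, `label`.
#'   Every result id must be present.
#' @param min_length Exclude sequences of length `<= min_length`
#'   (default 0 = keep all).
#' @param weight_by_length If `TRUE`, each sequence contributes its length
#'   in bp to the counts instead of 1. Off by default: the headline
#'   metrics are count-based.
#' @return One-row `data.frame`: `min_length`, `n`, `tp`, `fp`, `fn`,
#'   `tn`, `precision`, `recall`, `f1`.
#' @export
score_classification <- function(results, truth, min_length = 0,
                                 weight_by_length = FALSE) {
  truth <- .truth_vector(truth)
  missing <- setdiff(results$id, names(truth))
  if (length(missing))
    stop("id(s) missing from truth (first: ", missing[1], "; ",
         length(missing), " total)")
  keep <- results$length > min_length
  res <- results[keep, , drop = FALSE]
  pos <- truth[res$id] == "plasmid"
  pred <- res$label == "plasmid"
  w <- if (weight_by_length) as.numeric(res$length) else rep(1, nrow(res))
  tp <- sum(w[pred & pos]); fp <- sum(w[pred & !pos])
  fn <- sum(w[!pred & pos]); tn <- sum(w[!pred & !pos])
  safe_div <- function(num, den) if (den > 0) num / den else 0
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  if (tp + fp == 0 || tp + fn == 0)
    message("degenerate stratum (no predicted or no true plasmids); ",
            "affected metrics reported as 0")
  data.frame(min_length = min_length, n = nrow(res),
             tp = tp, fp = fp, fn = fn, tn = tn,
             precision = precision, recall = recall, f1 = f1)
}

#' Length-stratified metric report
#'
#' One [score_classification()] row per minimum-length cutoff, mirroring
#' the usual All / >500 / >1000 / >5000 presentation.
#'
#' @inheritParams score_classification
#' @param cutoffs Ascending vector of minimum-length cutoffs (bp); 0
#'   means no filter.
#' @return `data.frame`, one row per cutoff.
#' @export
length_stratified_report <- function(results, truth, cutoffs = c(0, 500,
                                                                 1000, 5000)) {
  if (is.unsorted(cutoffs)) stop("cutoffs must be sorted ascending")
  do.call(rbind, lapply(cutoffs, function(co)
    score_classification(results, truth, min_length = co)))
}

#' Precision-recall curve and area under it
#'
#' Sweeps the decision threshold over the distinct scores in descending
#' order; at each threshold all sequences scoring at least that value are
#' called plasmid. The area is the step-wise (average-precision) sum
#' `sum((R_i - R_{i-1}) * P_i)`, which avoids the optimistic linear
#' interpolation of trapezoidal PR areas. The no-skill baseline is the
#' positive fraction.
#'
#' @param probability Numeric vector of plasmid-class scores.
#' @param truth Parallel truth labels (`"plasmid"`/`"chromosome"`,
#'   logical, or 0/1). Both classes must be present.
#' @return List with `points` (`data.frame`: `threshold`, `recall`,
#'   `precision`), `auc`, and `baseline`.
#' @export
pr_curve <- function(probability, truth) {
  y <- if (is.character(truth) || is.factor(truth))
    as.character(truth) == "plasmid" else as.logical(truth)
  stopifnot(length(probability) == length(y))
  if (all(y) || !any(y))
    stop("pr_curve() needs at least one example of each class")
  o <- order(probability, decreasing = TRUE)
  p <- probability[o]; y <- y[o]
  tp <- cumsum(y); fp <- cumsum(!y)
  # one curve point per distinct score: the last index of each tied block
  last <- which(c(p[-length(p)] != p[-1], TRUE))
  P <- sum(y)
  recall <- tp[last] / P
  precision <- tp[last] / (tp[last] + fp[last])
  auc <- sum(diff(c(0, recall)) * precision)
  list(points = data.frame(threshold = p[last], recall = recall,
                           precision = precision),
       auc = auc, baseline = P / length(y))
}

#' Write a metric report as TSV
#'
#' Columns `min_length`, `n`, `tp`, `fp`, `fn`, `tn`, `precision`,
#' `recall`, `f1`, with the three rates printed as percentages to two
#' decimals.
#'
#' @param report Data frame from [length_stratified_report()] or
#'   [score_classification()].
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  out <- report
  for (col in c("precision", "recall", "f1"))
    out[[col]] <- sprintf("%.2f", 100 * report[[col]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
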