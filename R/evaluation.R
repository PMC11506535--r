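#' BayesiaLab-style confusion report
#'
#' Builds the occurrence / reliability / precision block for binary
#' predictions: `occurrences` is the 2x2 count table with rows = predicted
#' state and columns = true state; `reliability` normalizes each row to
#' percent (how trustworthy each emitted prediction is) and `precision`
#' each column (how well each true state is recovered). Summary statistics:
#' `overall_precision = 100 * trace / N`, `mean_precision` = mean of the
#' diagonal precision entries, `overall_reliability` = diagonal reliability
#' entries weighted by the true-class proportions, `mean_reliability` =
#' their unweighted mean, and the misclassified count. Row totals are
#' always derived from the counts themselves, never from labels.
#'
#' @param predicted,truth equal-length vectors of labels in `{0, 1}`.
#' @return An object of class `"confusion_report"`.
#' @examples
#' r <- confusion_report_from_counts(matrix(c(178, 33, 25, 128), 2))
#' r$overall_precision
#' @export
confusion_report <- function(predicted, truth) {
  predicted <- as.integer(predicted); truth <- as.integer(truth)
  if (length(predicted) != length(truth))
    stop("'predicted' and 'truth' must have equal length", call. = FALSE)
  if (!length(truth)) stop("empty input", call. = FALSE)
  stopifnot(all(predicted %in% 0:1), all(truth %in% 0:1))
  occ <- matrix(0, 2, 2, dimnames = list(predicted = c("0", "1"),
                                         truth = c("0", "1")))
  for (p in 0:1) for (t in 0:1)
    occ[p + 1, t + 1] <- sum(predicted == p & truth == t)
  confusion_report_from_counts(occ)
}

#' Confusion report from a printed occurrence table
#'
#' Recomputes every reliability/precision percentage and summary statistic
#' from the raw counts alone (rows = predicted state, columns = true
#' state), which is how published confusion tables are audited.
#'
#' @param occurrences 2x2 numeric matrix of counts, rows = predicted,
#'   columns = true.
#' @return An object of class `"confusion_report"` with elements
#'   `occurrences`, `reliability`, `precision` (percent matrices),
#'   `overall_precision`, `mean_precision`, `overall_reliability`,
#'   `mean_reliability`, `misclassified`, `n`.
#' @export
confusion_report_from_counts <- function(occurrences) {
  occ <- as.matrix(occurrences)
  stopifnot(nrow(occ) == 2, ncol(occ) == 2, all(occ >= 0))
  dimnames(occ) <- list(predicted = c("0", "1"), truth = c("0", "1"))
  n <- sum(occ)
  row_tot <- rowSums(occ); col_tot <- colSums(occ)
  reliability <- 100 * occ / ifelse(row_tot > 0, row_tot, NA)[row(occ)]
  precision <- 100 * sweep(occ, 2, ifelse(col_tot > 0, col_tot, NA), "/")
  diag_rel <- diag(reliability); diag_prec <- diag(precision)
  structure(list(
    occurrences = occ, reliability = reliability, precision = precision,
    overall_precision = 100 * sum(diag(occ)) / n,
    mean_precision = mean(diag_prec),
    overall_reliability = sum(col_tot / n * diag_rel),
    mean_reliability = mean(diag_rel),
    misclassified = n - sum(diag(occ)), n = n),
    class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, digits = 4, ...) {
  fmt <- function(m) formatC(m, format = "f", digits = digits)
  lab <- sprintf("%s (%d)", c("0", "1"), colSums(x$occurrences))
  show <- function(m, title, pct = TRUE) {
    cat(title, "\n")
    body <- if (pct) matrix(paste0(fmt(m), "%"), 2) else
      matrix(formatC(m, format = "d"), 2)
    tab <- rbind(c("Value", lab),
                 cbind(sprintf("%s (%d)", c("0", "1"), rowSums(x$occurrences)),
                       body))
    for (r in seq_len(nrow(tab)))
      cat("  ", formatC(tab[r, ], width = 14), "\n", sep = "")
  }
  show(x$occurrences, "Occurrences", pct = FALSE)
  show(x$reliability, "Reliability")
  show(x$precision, "Precision")
  cat("Classification Statistics\n")
  cat(sprintf("  Overall Precision   %s%%\n", fmt(x$overall_precision)))
  cat(sprintf("  Mean Precision      %s%%\n", fmt(x$mean_precision)))
  cat(sprintf("  Overall Reliability %s%%\n", fmt(x$overall_reliability)))
  cat(sprintf("  Mean Reliability    %s%%\n", fmt(x$mean_reliability)))
  cat(sprintf("  Misclassified       %d / %d\n", x$misclassified, x$n))
  invisible(x)
}

auc_midrank <- function(scores, truth) {
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: only one class present", call. = FALSE)
  r <- rank(scores)                       # midranks for ties
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Ranking and calibration summary of probabilistic predictions
#'
#' Computes the BayesiaLab-style index block from scores and true labels:
#' `roc_index` is the AUC in percent (midrank tie handling);
#' `gini_index = roc_index - 50` and `relative_gini = 2 * gini_index` hold
#' by definition. `lift_index` is the area under the cumulative-gains curve
#' (fraction of positives captured vs fraction of population, descending
#' score) divided by the 0.5 area of a random ranking, and `relative_lift`
#' expresses the same area as a percentage of the way from random to the
#' ideal ranking; these two follow documented definitions and are not
#' claimed to match any proprietary normalization. `calibration_index` is
#' `100 * (1 - mean |predicted - empirical|)` over 10 equal-count score
#' bins.
#'
#' @param prob_sick numeric scores in `[0, 1]`.
#' @param truth labels in `{0, 1}`, both classes present.
#' @param bins number of calibration bins.
#' @return An object of class `"performance_summary"`.
#' @export
performance_summary <- function(prob_sick, truth, bins = 10L) {
  truth <- as.integer(truth)
  stopifnot(length(prob_sick) == length(truth),
            all(prob_sick >= -1e-9 & prob_sick <= 1 + 1e-9))
  auc <- auc_midrank(prob_sick, truth)
  roc_index <- 100 * auc
  gini_index <- roc_index - 50
  n <- length(truth); npos <- sum(truth == 1)
  ord <- order(-prob_sick)
  gains <- cumsum(truth[ord] == 1) / npos
  area <- mean(gains)                      # right-endpoint area, step 1/n
  ideal <- mean(pmin(seq_len(n) / (npos / n * n), 1))
  lift_index <- area / 0.5
  relative_lift <- 100 * (area - 0.5) / (ideal - 0.5)
  qs <- stats::quantile(prob_sick, probs = seq(0, 1, length.out = bins + 1))
  bin <- findInterval(prob_sick, unique(qs), rightmost.closed = TRUE)
  gaps <- vapply(split(seq_len(n), bin), function(i)
    abs(mean(prob_sick[i]) - mean(truth[i])), numeric(1))
  calibration_index <- 100 * (1 - mean(gaps))
  structure(list(roc_index = roc_index, gini_index = gini_index,
                 relative_gini = 2 * gini_index, lift_index = lift_index,
                 relative_lift = relative_lift,
                 calibration_index = calibration_index, n = n),
            class = "performance_summary")
}

#' @export
print.performance_summary <- function(x, ...) {
  cat("Performance Summary\n")
  cat(sprintf("  Gini Index           %.5f%%\n", x$gini_index))
  cat(sprintf("  Relative Gini Index  %.5f%%\n", x$relative_gini))
  cat(sprintf("  Lift Index           %.5f\n", x$lift_index))
  cat(sprintf("  Relative Lift Index  %.5f%%\n", x$relative_lift))
  cat(sprintf("  ROC Index            %.5f%%\n", x$roc_index))
  cat(sprintf("  Calibration Index    %.5f%%\n", x$calibration_index))
  invisible(x)
}

#' The eight standard binary-classification metrics
#'
#' Accuracy, precision (positive predictive value), recall/sensitivity,
#' specificity, F1, AUC, balanced accuracy and Matthews correlation,
#' computed from hard labels plus scores. Metrics with a degenerate
#' denominator are reported as `NA` (undefined), not 0.
#'
#' @param predicted hard labels in `{0, 1}`.
#' @param prob scores in `[0, 1]` (used for AUC; may be `NULL`).
#' @param truth true labels in `{0, 1}`.
#' @return Named numeric vector of the eight metrics.
#' @export
eight_metrics <- function(predicted, prob, truth) {
  predicted <- as.integer(predicted); truth <- as.integer(truth)
  tp <- sum(predicted == 1 & truth == 1)
  tn <- sum(predicted == 0 & truth == 0)
  fp <- sum(predicted == 1 & truth == 0)
  fn <- sum(predicted == 0 & truth == 1)
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  prec <- safe(tp, tp + fp)
  rec <- safe(tp, tp + fn)
  spec <- safe(tn, tn + fp)
  f1 <- if (!is.na(prec) && !is.na(rec) && (prec + rec) > 0)
    2 * prec * rec / (prec + rec) else NA_real_
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else NA_real_
  auc <- if (!is.null(prob) && length(unique(truth)) == 2)
    auc_midrank(prob, truth) else NA_real_
  c(accuracy = (tp + tn) / length(truth),
    precision = prec, recall = rec, specificity = spec, f1 = f1,
    auc = auc,
    balanced_accuracy = if (!is.na(rec) && !is.na(spec)) (rec + spec) / 2
    else NA_real_,
    mcc = mcc)
}

#' Stratified fold assignment
#'
#' @param y class labels.
#' @param K number of folds, `2 <= K <= length(y)`.
#' @param seed integer seed.
#' @return Integer vector of fold ids in `1..K`; within each class the
#'   counts per fold differ by at most 1.
#' @export
stratified_folds <- function(y, K, seed = 1L) {
  if (K < 2 || K > length(y)) stop("need 2 <= K <= N", call. = FALSE)
  set.seed(as.integer(seed))
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(K), length(idx))
  }
  fold
}

#' Pooled K-fold cross-validation
#'
#' Splits the data into stratified folds, trains the supplied learner on
#' the K-1 complement of each fold, predicts the held-out fold, and
#' evaluates the pooled out-of-fold predictions. The learner sees nothing
#' from its test fold (any preprocessing it performs, e.g. discretization,
#' happens inside `fit`).
#'
#' @param data data.frame with the target column.
#' @param target name of the class column (values in `{0, 1}`).
#' @param K number of folds.
#' @param learner list with `fit(train_data)` returning a model and
#'   `predict(model, test_data)` returning positive-class probabilities.
#' @param seed integer seed for the fold assignment.
#' @return A list with `confusion` ([confusion_report]), `performance`
#'   ([performance_summary]), `prob`, `predicted`, `truth`, `folds`.
#' @export
kfold <- function(data, target, K, learner, seed = 1L) {
  y <- as.integer(data[[target]])
  folds <- stratified_folds(y, K, seed)
  prob <- numeric(length(y))
  for (k in seq_len(K)) {
    tr <- data[folds != k, , drop = FALSE]
    te <- data[folds == k, , drop = FALSE]
    if (length(unique(tr[[target]])) < 2L)
      stop(sprintf("fold %d: a class is absent from the training split", k),
           call. = FALSE)
    model <- learner$fit(tr)
    prob[folds == k] <- learner$predict(model, te)
  }
  predicted <- as.integer(prob >= 0.5)
  list(confusion = confusion_report(predicted, y),
       performance = performance_summary(prob, y),
       prob = prob, predicted = predicted, truth = y, folds = folds)
}
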