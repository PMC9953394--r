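# Evaluation battery for extremely skewed binary classification:
# confusion-derived metrics at a threshold, AUROC (rank form, ties
# grouped), step-sum average precision, and mean +/- SE aggregation over
# repeated seeded runs.

#' Binary calls from scores at a threshold
#'
#' Ties go to the positive class: `call = 1` iff `score >= threshold`.
#'
#' @param scores Numeric vector of probabilities in `[0, 1]`.
#' @param threshold Single number in `[0, 1]`.
#' @return Integer 0/1 vector.
#' @export
threshold_calls <- function(scores, threshold = 0.5) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 1)
  as.integer(scores >= threshold)
}

#' Confusion-derived and ranking metrics for binary predictions
#'
#' At `threshold`: accuracy, precision, recall and F1, with precision,
#' recall or F1 reported as `NaN` when their denominator is zero (e.g. no
#' positive calls), never silently 0. Ranking metrics: AUROC as the
#' tie-aware rank statistic (equal to the trapezoidal area under the ROC
#' with tied scores grouped) and AP as the step sum
#' `sum((R_n - R_{n-1}) * P_n)` over distinct score cutoffs in decreasing
#' order, anchored at recall 0 — not the PR trapezoid, which differs.
#'
#' @param labels Binary 0/1 vector.
#' @param scores Numeric score vector of the same length.
#' @param threshold Call threshold (default 0.5).
#' @return A `metrics_report` list: `accuracy`, `precision`, `recall`,
#'   `f1`, `auroc`, `ap`, `confusion` (TP/FP/TN/FN), `roc` and `prc`
#'   data frames, and `threshold`.
#' @examples
#' compute_metrics(c(1, 0, 1), c(0.9, 0.8, 0.3))
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores)) {
    stop("labels and scores differ in length")
  }
  if (length(labels) == 0L) stop("need at least one sample")
  stopifnot(all(labels %in% c(0L, 1L)))
  calls <- threshold_calls(scores, threshold)
  tp <- sum(calls == 1L & labels == 1L)
  fp <- sum(calls == 1L & labels == 0L)
  tn <- sum(calls == 0L & labels == 0L)
  fn <- sum(calls == 0L & labels == 1L)
  accuracy <- (tp + tn) / (tp + tn + fp + fn)
  precision <- if (tp + fp > 0L) tp / (tp + fp) else NaN
  recall <- if (tp + fn > 0L) tp / (tp + fn) else NaN
  f1 <- if (!is.nan(precision) && !is.nan(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NaN
  rk <- ranking_curves(labels, scores)
  structure(list(accuracy = accuracy, precision = precision,
                 recall = recall, f1 = f1,
                 auroc = rk$auroc, ap = rk$ap,
                 confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
                 roc = rk$roc, prc = rk$prc, threshold = threshold),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(v) ifelse(is.nan(v), "NaN", sprintf("%.4f", v))
  cat(sprintf(
    "metrics @ %.2f: acc=%s prec=%s rec=%s F1=%s | AUROC=%s AP=%s\n",
    x$threshold, fmt(x$accuracy), fmt(x$precision), fmt(x$recall),
    fmt(x$f1), fmt(x$auroc), fmt(x$ap)))
  invisible(x)
}

# ROC/PRC points over distinct score cutoffs (decreasing), plus AUROC and AP.
ranking_curves <- function(labels, scores) {
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # group tied scores: cumulative TP/FP at the last index of each tie block
  last_of_block <- which(!duplicated(s, fromLast = TRUE))
  ctp <- cumsum(y)[last_of_block]
  cfp <- cumsum(1L - y)[last_of_block]
  tpr <- if (n_pos > 0L) ctp / n_pos else rep(NaN, length(ctp))
  fpr <- if (n_neg > 0L) cfp / n_neg else rep(NaN, length(cfp))
  prec <- ctp / (ctp + cfp)
  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  prc <- data.frame(recall = c(0, tpr), precision = c(1, prec))
  auroc <- if (n_pos > 0L && n_neg > 0L) {
    # rank form: P(random positive outscores random negative), ties = 1/2
    r <- rank(scores)
    (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  } else NaN
  ap <- if (n_pos > 0L) sum(diff(c(0, tpr)) * prec) else NaN
  list(roc = roc, prc = prc, auroc = auroc, ap = ap)
}

#' Repeat a seeded evaluation and aggregate mean and standard error
#'
#' Runs `protocol(seed)` for `seeds = base_seed .. base_seed + k - 1` and
#' aggregates every scalar metric as mean +/- standard error
#' (`sd / sqrt(k)`). Runs where a metric is `NaN` propagate `NaN` for that
#' metric's aggregate.
#'
#' @param protocol Function of one argument (the seed) returning a
#'   `metrics_report`.
#' @param base_seed First seed.
#' @param k Number of repeats (default 5).
#' @return A `repeated_report`: data frame `summary` with `metric`, `mean`,
#'   `se`, plus the list of per-run reports.
#' @export
repeated_evaluation <- function(protocol, base_seed = 1L, k = 5L) {
  stopifnot(k >= 2L)
  runs <- lapply(seq_len(k) - 1L, function(i) {
    rep_i <- protocol(as.integer(base_seed) + i)
    stopifnot(inherits(rep_i, "metrics_report"))
    rep_i
  })
  metrics <- c("accuracy", "precision", "recall", "f1", "auroc", "ap")
  vals <- vapply(runs, function(r) unlist(r[metrics]), numeric(length(metrics)))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = length(metrics))
  summary <- data.frame(
    metric = metrics,
    mean = rowMeans(vals),
    se = apply(vals, 1L, stats::sd) / sqrt(k))
  structure(list(summary = summary, runs = runs, k = k,
                 base_seed = base_seed),
            class = "repeated_report")
}

#' @export
print.repeated_report <- function(x, ...) {
  cat("repeated_report over", x$k, "seeds (base", x$base_seed, "):\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-9s %.4f +/- %.4f\n", s$metric[i], s$mean[i], s$se[i]))
  }
  invisible(x)
}
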