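# Experiment drivers: within-cell-line (stratified half-split, oversampled
# training half, untouched test half) and cross-cell-line (oversample one
# full dataset, evaluate on another).

#' Restrict a labeled dataset to a feature subset
#'
#' From a dataset built in `"both"` mode, selects the accessibility block
#' (`"atac"`), the sequence block (`"seq"`), or everything (`"both"`), for
#' feature-ablation experiments.
#'
#' @param ds A `labeled_dataset`.
#' @param mode `"both"`, `"atac"` or `"seq"`.
#' @return A `labeled_dataset` with the selected columns.
#' @export
select_features <- function(ds, mode = c("both", "atac", "seq")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ds, "labeled_dataset"))
  fm <- ds$features
  if (mode == "both" || identical(fm$mode, mode)) return(ds)
  if (!identical(fm$mode, "both")) {
    stop("cannot select '", mode, "' from a '", fm$mode, "' feature matrix")
  }
  keep <- if (mode == "atac") !fm$categorical else fm$categorical
  fm$x <- fm$x[, keep, drop = FALSE]
  fm$categorical <- fm$categorical[keep]
  fm$mode <- mode
  structure(list(features = fm, labels = ds$labels, ids = ds$ids),
            class = "labeled_dataset")
}

#' One-cell-line experiment
#'
#' The full protocol for a single cell line: stratified half-split, then
#' oversampling of the training half only (the test half keeps the raw
#' skewed class ratio), training, scoring the test half, and metrics at
#' the given threshold. The split, the oversampling draw and the trainer
#' are all reseeded from `seed`.
#'
#' @param ds A `labeled_dataset` for one cell line.
#' @param hp A [gbdt_params()].
#' @param mode Feature subset, see [select_features()].
#' @param seed Integer seed.
#' @param threshold Call threshold for the confusion metrics (default 0.5).
#' @return A `metrics_report` on the untouched test half.
#' @export
one_cell_line_experiment <- function(ds, hp = gbdt_params(),
                                     mode = c("both", "atac", "seq"),
                                     seed = 1L, threshold = 0.5) {
  mode <- match.arg(mode)
  ds <- select_features(ds, mode)
  seed <- as.integer(seed)
  halves <- stratified_half_split(ds, train_fraction = 0.5, seed = seed)
  train <- oversample_positives(halves$train, seed = seed + 1L)
  model <- train_gbdt(train, hp, seed = seed + 2L)
  scores <- predict_scores(model, halves$test$features)
  compute_metrics(halves$test$labels, scores, threshold)
}

#' Cross-cell-line experiment
#'
#' Trains on one cell line's full dataset (oversampled, no split) and
#' evaluates on another cell line's full, untouched dataset. Feature
#' schemas must match.
#'
#' @param train_ds,test_ds `labeled_dataset`s with identical feature
#'   schemas.
#' @param hp A [gbdt_params()].
#' @param seed Integer seed.
#' @param threshold Call threshold (default 0.5).
#' @return A `metrics_report` on `test_ds`.
#' @export
cross_cell_line_experiment <- function(train_ds, test_ds,
                                       hp = gbdt_params(), seed = 1L,
                                       threshold = 0.5) {
  sa <- feature_schema(train_ds$features)
  sb <- feature_schema(test_ds$features)
  if (!schema_compatible(sa, sb)) {
    stop("train and test feature schemas differ (columns ", sa$n_col,
         " vs ", sb$n_col, ", mode ", sa$mode, " vs ", sb$mode, ")")
  }
  seed <- as.integer(seed)
  train <- oversample_positives(train_ds, seed = seed + 1L)
  model <- train_gbdt(train, hp, seed = seed + 2L)
  scores <- predict_scores(model, test_ds$features)
  compute_metrics(test_ds$labels, scores, threshold)
}
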