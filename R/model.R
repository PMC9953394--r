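# Gradient-boosted decision tree classifier (xgboost backend) with the
# sequence columns declared as unordered categorical features, so splits
# partition base identities rather than thresholding their ordinal codes.

#' Gradient-boosting hyperparameters
#'
#' @param n_estimators Number of boosting rounds (default 500).
#' @param learning_rate Shrinkage in (0, 1] (default 0.1).
#' @param num_leaves Maximum leaves per tree (default 31; trees are grown
#'   leaf-wise).
#' @param min_child_samples Approximate minimum samples per leaf
#'   (default 20), enforced through the hessian weight (one sample
#'   contributes ~1/4 under binary log-loss).
#' @param subsample Row fraction drawn per boosting round (default 0.8).
#' @param colsample_bytree Column fraction drawn per tree (default 0.8).
#'   Together with `subsample` this decorrelates the trees; with fully
#'   deterministic trees, a training set whose minority class is mostly
#'   duplicated rows yields an ensemble of identical trees whose split
#'   thresholds sit at the training positives' margin and generalize
#'   poorly.
#' @param extra Named list of additional backend parameters passed through
#'   verbatim (overrides the derived ones).
#' @return A `gbdt_params` list.
#' @export
gbdt_params <- function(n_estimators = 500L, learning_rate = 0.1,
                        num_leaves = 31L, min_child_samples = 20L,
                        subsample = 0.8, colsample_bytree = 0.8,
                        extra = list()) {
  stopifnot(n_estimators >= 1L, learning_rate > 0, learning_rate <= 1,
            num_leaves >= 2L, min_child_samples >= 0L,
            subsample > 0, subsample <= 1,
            colsample_bytree > 0, colsample_bytree <= 1)
  structure(list(n_estimators = as.integer(n_estimators),
                 learning_rate = learning_rate,
                 num_leaves = as.integer(num_leaves),
                 min_child_samples = as.integer(min_child_samples),
                 subsample = subsample,
                 colsample_bytree = colsample_bytree,
                 extra = extra),
            class = "gbdt_params")
}

feature_schema <- function(fm) {
  list(n_col = ncol(fm$x),
       categorical = as.logical(fm$categorical),
       mode = fm$mode,
       strand_orient = if (is.null(fm$config)) NA else
         fm$config$strand_orient)
}

schema_compatible <- function(a, b) {
  identical(a$n_col, b$n_col) && identical(a$categorical, b$categorical) &&
    identical(a$mode, b$mode)
}

make_dmatrix <- function(fm, labels = NULL) {
  ft <- ifelse(fm$categorical, "c", "float")
  x <- fm$x
  if (is.null(labels)) {
    xgboost::xgb.DMatrix(x, feature_types = ft, nthread = 1)
  } else {
    xgboost::xgb.DMatrix(x, label = labels, feature_types = ft, nthread = 1)
  }
}

#' Train the gradient-boosted tree classifier
#'
#' Binary log-loss objective; histogram tree method with leaf-wise growth.
#' Columns flagged categorical in the feature schema are consumed as
#' unordered categories (the backend orders category groups by gradient
#' statistics at each split). Training is deterministic given the data,
#' hyperparameters, seed and a single thread.
#'
#' @param train A `labeled_dataset` containing both classes. Whether it has
#'   been balanced is the caller's protocol decision; no check is made.
#' @param hp A [gbdt_params()].
#' @param seed Integer seed.
#' @param nthread Threads (default 1 for bit-reproducibility; more threads
#'   trade that away).
#' @return A `trained_model`: the booster, the feature schema it was
#'   trained on, and training provenance (seed, hyperparameters).
#' @export
train_gbdt <- function(train, hp = gbdt_params(), seed = 1L, nthread = 1L) {
  stopifnot(inherits(train, "labeled_dataset"), inherits(hp, "gbdt_params"))
  if (length(unique(train$labels)) < 2L) {
    stop("training data must contain both classes")
  }
  if (nthread > 1L) {
    message("nthread > 1: bit-level reproducibility is relinquished")
  }
  params <- utils::modifyList(list(
    objective = "binary:logistic",
    tree_method = "hist",
    grow_policy = "lossguide",
    max_leaves = hp$num_leaves,
    max_depth = 0L,
    eta = hp$learning_rate,
    # logistic hessian at p = 0.5 is 1/4 per sample, so this enforces a
    # minimum of ~min_child_samples samples per leaf
    min_child_weight = hp$min_child_samples / 4,
    subsample = hp$subsample,
    colsample_bytree = hp$colsample_bytree,
    max_cat_to_onehot = 1L,   # partition splits on categories, never one-hot
    seed = as.integer(seed),
    nthread = as.integer(nthread)),
    hp$extra)
  dtrain <- make_dmatrix(train$features, train$labels)
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = hp$n_estimators, verbose = 0)
  structure(list(booster = booster,
                 schema = feature_schema(train$features),
                 seed = as.integer(seed),
                 hp = hp),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat("trained_model:", x$hp$n_estimators, "rounds,",
      x$schema$n_col, "features (", sum(x$schema$categorical),
      "categorical ), mode =", x$schema$mode, "\n")
  invisible(x)
}

#' Predict folding probabilities for a feature matrix
#'
#' @param model A `trained_model`.
#' @param features A `feature_matrix` whose schema (column count,
#'   categorical flags, feature mode) matches the one the model was
#'   trained on; a mismatch is an error.
#' @return Numeric vector of probabilities in `[0, 1]`, one per row.
#' @export
predict_scores <- function(model, features) {
  stopifnot(inherits(model, "trained_model"),
            inherits(features, "feature_matrix"))
  sc <- feature_schema(features)
  if (!schema_compatible(model$schema, sc)) {
    stop(sprintf(
      "feature schema mismatch: model expects %d columns (mode %s, %d categorical), got %d (mode %s, %d categorical)",
      model$schema$n_col, model$schema$mode, sum(model$schema$categorical),
      sc$n_col, sc$mode, sum(sc$categorical)))
  }
  if (nrow(features$x) == 0L) return(numeric(0))
  as.numeric(predict(model$booster, make_dmatrix(features)))
}

#' Persist a trained model to disk
#'
#' Writes the booster in the backend's UBJSON format plus a JSON sidecar
#' (`<path>.schema.json`) holding the feature schema and provenance.
#'
#' @param model A `trained_model`.
#' @param path Output path (conventionally `.ubj`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  xgboost::xgb.save(model$booster, path)
  meta <- list(schema = model$schema, seed = model$seed,
               hp = model$hp[c("n_estimators", "learning_rate",
                               "num_leaves", "min_child_samples",
                               "subsample", "colsample_bytree")])
  jsonlite::write_json(meta, paste0(path, ".schema.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a trained model saved with [save_model()]
#'
#' @param path Path given to [save_model()].
#' @return A `trained_model`; predictions equal those of the model before
#'   saving.
#' @export
load_model <- function(path) {
  booster <- xgboost::xgb.load(path)
  meta <- jsonlite::read_json(paste0(path, ".schema.json"),
                              simplifyVector = TRUE)
  so <- meta$schema$strand_orient
  schema <- list(n_col = as.integer(meta$schema$n_col),
                 categorical = as.logical(meta$schema$categorical),
                 mode = meta$schema$mode,
                 strand_orient = if (length(so) == 0L) NA else
                   as.logical(so))
  hp <- gbdt_params(n_estimators = meta$hp$n_estimators,
                    learning_rate = meta$hp$learning_rate,
                    num_leaves = meta$hp$num_leaves,
                    min_child_samples = meta$hp$min_child_samples,
                    subsample = meta$hp$subsample,
                    colsample_bytree = meta$hp$colsample_bytree)
  structure(list(booster = booster, schema = schema,
                 seed = as.integer(meta$seed), hp = hp),
            class = "trained_model")
}
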