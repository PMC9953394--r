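# Stratified half-splitting and minority-class oversampling: the dataset
# protocol for training on extremely skewed whole-genome candidate sets.

#' Bundle features, labels and ids into a labeled dataset
#'
#' @param features A `feature_matrix` (or plain numeric matrix, wrapped
#'   with no categorical flags).
#' @param labels Binary integer vector (0/1), one per row.
#' @param ids Unique candidate identifiers; default `"cand<row>"`.
#' @return A `labeled_dataset`.
#' @export
labeled_dataset <- function(features, labels, ids = NULL) {
  if (is.matrix(features)) {
    features <- structure(list(x = features,
                               categorical = rep(FALSE, ncol(features)),
                               mode = "custom", config = NULL),
                          class = "feature_matrix")
  }
  stopifnot(inherits(features, "feature_matrix"))
  labels <- as.integer(labels)
  n <- nrow(features$x)
  if (length(labels) != n) stop("labels length != feature rows")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (is.null(ids)) ids <- paste0("cand", seq_len(n))
  ids <- as.character(ids)
  if (length(ids) != n || anyDuplicated(ids)) {
    stop("ids must be unique and match the number of rows")
  }
  structure(list(features = features, labels = labels, ids = ids),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("labeled_dataset:", length(x$labels), "samples (",
      sum(x$labels == 1L), "positive /", sum(x$labels == 0L),
      "negative ),", ncol(x$features$x), "features\n")
  invisible(x)
}

subset_dataset <- function(ds, idx) {
  f <- ds$features
  f$x <- f$x[idx, , drop = FALSE]
  structure(list(features = f, labels = ds$labels[idx], ids = ds$ids[idx]),
            class = "labeled_dataset")
}

#' Stratified random split preserving the class ratio
#'
#' Within each class, `floor(train_fraction * n_class)` members are drawn
#' uniformly without replacement into the training half; the remainder
#' forms the test half. With the default `train_fraction = 0.5` this
#' reproduces the equal-size random halves used in whole-genome
#' evaluation, including the one-off asymmetry for odd class counts (e.g.
#' 2491 positives split 1245 train / 1246 test).
#'
#' @param ds A `labeled_dataset` with both classes present.
#' @param train_fraction Fraction in (0, 1); default 0.5.
#' @param seed Integer seed; the split is deterministic given it.
#' @return List with elements `train` and `test`, both `labeled_dataset`s,
#'   forming a disjoint partition of `ds`.
#' @export
stratified_half_split <- function(ds, train_fraction = 0.5, seed = 1L) {
  stopifnot(inherits(ds, "labeled_dataset"),
            train_fraction > 0, train_fraction < 1)
  pos <- which(ds$labels == 1L)
  neg <- which(ds$labels == 0L)
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("both classes must be non-empty for a stratified split")
  }
  rng <- local_rng(seed)
  train_idx <- sort(c(
    sample_without_replacement(pos, floor(train_fraction * length(pos)), rng),
    sample_without_replacement(neg, floor(train_fraction * length(neg)), rng)))
  test_idx <- setdiff(seq_along(ds$labels), train_idx)
  list(train = subset_dataset(ds, train_idx),
       test = subset_dataset(ds, test_idx))
}

#' Oversample positives to match the negative count
#'
#' Adds uniform-with-replacement duplicates of original positive rows until
#' the class counts are exactly equal. Every original row remains present;
#' no synthetic feature values are created (pure duplication — this is not
#' SMOTE). Duplicate ids get a `.dup<k>` suffix to remain unique.
#'
#' @param ds A `labeled_dataset` with `n_pos >= 1` and `n_pos <= n_neg`.
#' @param seed Integer seed.
#' @return A balanced `labeled_dataset` of `2 * n_neg` rows.
#' @export
oversample_positives <- function(ds, seed = 1L) {
  stopifnot(inherits(ds, "labeled_dataset"))
  pos <- which(ds$labels == 1L)
  neg <- which(ds$labels == 0L)
  if (length(pos) < 1L) stop("no positive samples to oversample")
  if (length(pos) > length(neg)) {
    stop("more positives than negatives: oversampling direction undefined")
  }
  n_extra <- length(neg) - length(pos)
  if (n_extra == 0L) return(ds)
  rng <- local_rng(seed)
  extra <- pos[sample_with_replacement(length(pos), n_extra, rng)]
  f <- ds$features
  f$x <- rbind(f$x, f$x[extra, , drop = FALSE])
  new_ids <- c(ds$ids, paste0(ds$ids[extra], ".dup", seq_len(n_extra)))
  structure(list(features = f,
                 labels = c(ds$labels, rep(1L, n_extra)),
                 ids = new_ids),
            class = "labeled_dataset")
}

# ---- seeded RNG helpers ----------------------------------------------------
# All sampling flows through one explicitly seeded generator; the caller's
# global RNG state is untouched.

local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    set.seed(as.integer(seed))
    new <- get(".Random.seed", globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, globalenv())
    }
    new
  })
  env
}

with_rng <- function(rng, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  assign(".Random.seed", rng$state, globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, globalenv())
    }
  })
  eval.parent(substitute(expr))
}

sample_without_replacement <- function(x, k, rng) {
  with_rng(rng, x[sample.int(length(x), k)])
}

sample_with_replacement <- function(n, k, rng) {
  with_rng(rng, sample.int(n, k, replace = TRUE))
}
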