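# Flat-file serialization of labeled datasets: a TSV (id, label, features)
# plus a JSON sidecar carrying the feature schema, so a dataset survives a
# trip through the command line without losing its categorical flags.

#' Write a labeled dataset to TSV (+ JSON schema sidecar)
#'
#' @param ds A `labeled_dataset`.
#' @param path Output TSV path; the schema goes to `<path>.schema.json`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "labeled_dataset"))
  df <- data.frame(id = ds$ids, label = ds$labels, ds$features$x,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- ds$features$config
  jsonlite::write_json(
    list(mode = ds$features$mode,
         categorical = as.logical(ds$features$categorical),
         flank = if (!is.null(cfg)) cfg$flank,
         window = if (!is.null(cfg)) cfg$window,
         strand_orient = if (!is.null(cfg)) cfg$strand_orient),
    paste0(path, ".schema.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a labeled dataset written by [write_dataset()]
#'
#' @param path TSV path (expects `<path>.schema.json` alongside).
#' @return A `labeled_dataset`.
#' @export
read_dataset <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".schema.json"),
                              simplifyVector = TRUE)
  x <- as.matrix(df[, -(1:2), drop = FALSE])
  cfg <- if (!is.null(meta$flank)) {
    feature_config(flank = meta$flank, window = meta$window,
                   strand_orient = isTRUE(meta$strand_orient))
  }
  fm <- structure(list(x = x, categorical = as.logical(meta$categorical),
                       mode = meta$mode, config = cfg),
                  class = "feature_matrix")
  labeled_dataset(fm, df$label, df$id)
}
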