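# Feature-table file I/O, model persistence and run manifests.
#
# The on-disk feature table is delimited text (comma by default, tab
# accepted) with a header row, a `sample_id` column, a `label` column with
# exactly two distinct values, and non-negative numeric feature columns.

MKLFS_FORMAT_VERSION <- "1.0.0"

#' Read a labeled feature table
#'
#' Parses a CSV/TSV feature table into a non-negative feature matrix plus
#' labels and sample ids. Labels are mapped to -1/+1 deterministically: the
#' lexicographically smaller label becomes -1 unless `positive_label`
#' overrides the mapping.
#'
#' @param path file path.
#' @param sep field separator; `","` (default) or `"\t"`.
#' @param positive_label optional label value to map to +1.
#' @return list with `X` (numeric matrix), `y` (-1/+1), `labels` (original
#'   label values), `sample_ids`, `class_names` (names are "-1"/"1").
#' @export
read_feature_table <- function(path, sep = ",", positive_label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"label" %in% names(df))
    stop("missing required column 'label'", call. = FALSE)
  if (!"sample_id" %in% names(df))
    stop("missing required column 'sample_id'", call. = FALSE)
  feat_cols <- setdiff(names(df), c("sample_id", "label"))
  if (length(feat_cols) < 1L)
    stop("no feature columns found", call. = FALSE)
  labs <- as.character(df$label)
  if (length(unique(labs)) != 2L)
    stop("label column must take exactly 2 values, found ",
         length(unique(labs)), call. = FALSE)
  X <- as.matrix(df[feat_cols])
  if (!is.numeric(X))
    stop("non-numeric feature cell in columns: ",
         paste(feat_cols[!vapply(df[feat_cols], is.numeric, logical(1))],
               collapse = ", "), call. = FALSE)
  if (any(!is.finite(X)))
    stop("non-finite feature value", call. = FALSE)
  if (any(X < 0)) {
    bad <- which(X < 0, arr.ind = TRUE)[1, ]
    stop("negative feature value at row ", bad[1], ", column '",
         feat_cols[bad[2]], "'", call. = FALSE)
  }
  map <- .encode_labels(labs, positive_label)
  list(X = X, y = map$y, labels = labs,
       sample_ids = as.character(df$sample_id),
       class_names = map$class_names)
}

#' Write a labeled feature table
#'
#' @param X numeric samples x features matrix.
#' @param y labels (one per row).
#' @param path output file path.
#' @param sample_ids optional ids (default `s1, s2, ...`).
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(X, y, path, sample_ids = NULL, sep = ",") {
  X <- as.matrix(X)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  df <- data.frame(sample_id = sample_ids, label = y,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(X, check.names = FALSE))
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Save / load a fitted model
#'
#' The model archive is a single RDS file holding the training arrays, the
#' kernel spec and training configuration, and a semantic format version;
#' loading refuses archives with a different major version.
#'
#' @param model a fitted `mklfs_model`.
#' @param path archive path.
#' @return `path` (save) or the restored `mklfs_model` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "mklfs_model"))
  saveRDS(list(format_version = MKLFS_FORMAT_VERSION, model = model),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$format_version))
    stop("not a model archive", call. = FALSE)
  major <- function(v) strsplit(v, ".", fixed = TRUE)[[1]][1]
  if (major(obj$format_version) != major(MKLFS_FORMAT_VERSION))
    stop("incompatible model archive version: ", obj$format_version,
         call. = FALSE)
  obj$model
}

#' Write a run manifest
#'
#' Records the configuration, seed, package version and input checksums of
#' a run as JSON next to its outputs, so any result can be reproduced from
#' the manifest alone.
#'
#' @param path manifest output path.
#' @param config named list of configuration values.
#' @param seed integer seed of the run.
#' @param inputs character vector of input file paths (checksummed if they
#'   exist).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seed, inputs = character(0)) {
  checksums <- vapply(inputs, function(p) {
    if (file.exists(p)) as.character(tools::md5sum(p)) else NA_character_
  }, character(1))
  manifest <- list(
    package = "mklfs",
    version = as.character(utils::packageVersion("mklfs")),
    seed = seed,
    config = config,
    inputs = as.list(checksums)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
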