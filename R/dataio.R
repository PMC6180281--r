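# Readers and writers for the package's interchange formats. CSV is the
# canonical format; readers validate and reject rather than repair.

METADATA_COLS <- c("subject_id", "session_id", "group")

#' Validate and tag a feature table
#'
#' A feature table holds one row per recording session: the metadata
#' columns `subject_id`, `session_id`, `group` followed by the named
#' entropy features (380 columns for the default 19-channel, 20-scale
#' configuration).
#'
#' @param df A data.frame with metadata columns first.
#' @return The data.frame with class `feature_table` prepended.
#' @export
as_feature_table <- function(df) {
  if (!all(METADATA_COLS %in% names(df)))
    stop_format(paste("feature table must have columns",
                      paste(METADATA_COLS, collapse = ", ")))
  feats <- setdiff(names(df), METADATA_COLS)
  if (anyDuplicated(feats))
    stop_format("duplicate feature column names")
  if (anyDuplicated(df[, c("subject_id", "session_id")]))
    stop_format("duplicate (subject_id, session_id) rows")
  class(df) <- unique(c("feature_table", class(df)))
  df
}

#' Feature column names of a feature table
#' @param table A `feature_table`.
#' @return Character vector of feature column names.
#' @export
feature_cols <- function(table) setdiff(names(table), METADATA_COLS)

#' Write one recording as CSV
#'
#' Rows are channels; the first column holds the channel label, the
#' remaining columns the samples.
#'
#' @param rec An `eeg_recording`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_recording_csv <- function(rec, path) {
  df <- data.frame(channel = rownames(rec$data), rec$data,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("channel", sprintf("t%d", seq_len(ncol(rec$data))))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read one recording from CSV
#'
#' @param path CSV file: first column channel labels, remaining columns
#'   samples; all rows equal length.
#' @param fs Sampling rate in Hz.
#' @param subject_id,session_id,group Metadata attached to the recording.
#' @param strict Require exactly the 19 labels of [MONTAGE_10_20].
#' @return An `eeg_recording`.
#' @export
read_recording_csv <- function(path, fs, subject_id = NA_character_,
                               session_id = NA_character_,
                               group = NA_character_, strict = FALSE) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop_format("recording CSV needs a label column plus samples")
  labels <- df[[1]]
  mat <- suppressWarnings(
    vapply(seq_len(nrow(df)),
           function(i) as.numeric(unlist(df[i, -1])),
           numeric(ncol(df) - 1)))
  mat <- t(mat)
  bad <- which(apply(mat, 1, function(r) any(is.na(r))))
  if (length(bad))
    stop_format(sprintf("non-numeric sample in channel row '%s'",
                        labels[bad[1]]))
  if (strict) {
    if (nrow(mat) != 19 || !setequal(labels, MONTAGE_10_20))
      stop_format(sprintf(
        "strict montage check failed: %d channels, expected the 19-label 10-20 montage",
        nrow(mat)))
  }
  rownames(mat) <- labels
  new_recording(subject_id, session_id, group, fs, mat)
}

#' Write a feature table as CSV
#'
#' Metadata columns first, then the feature columns in channel-major,
#' scale-minor order as constructed; writes are deterministic.
#'
#' @param table A `feature_table`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(table, path) {
  table <- as_feature_table(as.data.frame(table))
  ord <- c(METADATA_COLS, feature_cols(table))
  write.csv(table[, ord], path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' Exact inverse of [write_feature_table()].
#'
#' @param path CSV file.
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  as_feature_table(df)
}

#' Read a symptom-score table from CSV
#'
#' @param path CSV with columns `subject_id` and the 12 symptom scores
#'   named as in [NPI_SYMPTOMS].
#' @return data.frame with validated, non-negative scores.
#' @export
read_npi_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(c("subject_id", NPI_SYMPTOMS), names(df))
  if (length(missing))
    stop_format(paste("NPI table lacks columns:",
                      paste(missing, collapse = ", ")))
  sc <- as.matrix(df[, NPI_SYMPTOMS])
  if (!is.numeric(sc) || any(is.na(sc)) || any(sc < 0))
    stop_format("NPI scores must be non-negative numbers")
  df[, c("subject_id", NPI_SYMPTOMS)]
}

#' Analysis configuration
#'
#' Bundles the tunable parameters of the pipeline: entropy settings,
#' classifier settings, the group contrast and the scale bins.
#'
#' @param mse A [sampen_params()].
#' @param method One of `"lasso"`, `"enet"`, `"lr"`.
#' @param alpha Elastic-net trade-off in \[0,1\]; 1 = LASSO. Default 0.7
#'   for `method = "enet"` per the usual empirical choice.
#' @param lambda_grid_size Points on the penalty path (default 50).
#' @param inner_folds Subject-grouped folds of the nested CV (default 5).
#' @param contrast Ordered pair `c(negative, positive)`; the positive
#'   class is the more severe group.
#' @param bins List of integer vectors partitioning `1..max_scale`
#'   (default the five 4-scale bins).
#' @param seed Integer seed for fold shuffling.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(mse = sampen_params(),
                            method = c("lasso", "enet", "lr"),
                            alpha = NULL,
                            lambda_grid_size = 50,
                            inner_folds = 5,
                            contrast = c("HC", "AD3"),
                            bins = default_scale_bins(mse$max_scale),
                            seed = 1L) {
  method <- match.arg(method)
  if (is.null(alpha))
    alpha <- switch(method, lasso = 1, enet = 0.7, lr = 1)
  if (alpha < 0 || alpha > 1) stop_invalid("'alpha' must lie in [0, 1]")
  if (length(contrast) != 2 || contrast[1] == contrast[2])
    stop_invalid("'contrast' must name two distinct groups (negative, positive)")
  if (!setequal(unlist(bins), seq_len(mse$max_scale)))
    stop_invalid("'bins' must partition 1..max_scale")
  structure(list(mse = mse, method = method, alpha = alpha,
                 lambda_grid_size = as.integer(lambda_grid_size),
                 inner_folds = as.integer(inner_folds),
                 contrast = contrast, bins = bins, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read a flat key=value configuration file
#'
#' Recognized keys: `m`, `r_frac`, `max_scale`, `method`, `alpha`,
#' `lambda_grid_size`, `inner_folds`, `contrast` (as `NEG:POS`), `seed`.
#' Unknown keys raise an error; missing keys keep their defaults.
#'
#' @param path Text file with one `key = value` per line; `#` comments.
#' @return An [analysis_config()].
#' @export
read_analysis_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- which(lengths(kv) != 2)
  if (length(bad)) stop_format(sprintf("cannot parse config line: '%s'",
                                       lines[bad[1]]))
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  known <- c("m", "r_frac", "max_scale", "method", "alpha",
             "lambda_grid_size", "inner_folds", "contrast", "seed")
  unk <- setdiff(keys, known)
  if (length(unk)) stop_format(paste("unknown config keys:",
                                     paste(unk, collapse = ", ")))
  g <- function(key, default) if (key %in% keys) vals[keys == key][1] else default
  num <- function(key, default) as.numeric(g(key, default))
  analysis_config(
    mse = sampen_params(m = num("m", 2), r_frac = num("r_frac", 0.15),
                        max_scale = num("max_scale", 20)),
    method = g("method", "lasso"),
    alpha = if ("alpha" %in% keys) num("alpha", NA) else NULL,
    lambda_grid_size = num("lambda_grid_size", 50),
    inner_folds = num("inner_folds", 5),
    contrast = strsplit(g("contrast", "HC:AD3"), ":")[[1]],
    seed = as.integer(num("seed", 1)))
}
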