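# Selection-frequency biomarker maps: how often each feature receives a
# non-zero coefficient across the LOSO folds, aggregated over channels
# into five scale-factor bins (1-4, 5-8, 9-12, 13-16, 17-20) by taking
# the maximum frequency within each bin.

#' Schematic 2-D scalp coordinates of the 19-channel 10-20 montage
#'
#' Conventional top-view layout (nose up): outer-ring electrodes on the
#' unit circle, midline and parasagittal electrodes inside. Coordinates
#' are for display and export only.
#'
#' @return data.frame: channel, x, y.
#' @export
montage_coordinates <- function() {
  ring <- function(deg) c(cos(deg * pi / 180), sin(deg * pi / 180))
  coords <- rbind(
    Fp1 = ring(108), Fp2 = ring(72),
    F7 = ring(144), F8 = ring(36),
    T3 = ring(180), T4 = ring(0),
    T5 = ring(216), T6 = ring(324),
    O1 = ring(252), O2 = ring(288),
    F3 = c(-0.40, 0.48), Fz = c(0, 0.48), F4 = c(0.40, 0.48),
    C3 = c(-0.50, 0), Cz = c(0, 0), C4 = c(0.50, 0),
    P3 = c(-0.40, -0.48), Pz = c(0, -0.48), P4 = c(0.40, -0.48))
  df <- data.frame(channel = rownames(coords),
                   x = round(coords[, 1], 4), y = round(coords[, 2], 4),
                   stringsAsFactors = FALSE)
  df[match(MONTAGE_10_20, df$channel), ]
}

#' Default scale-factor bins
#'
#' @param max_scale Largest scale (default 20).
#' @param width Bin width (default 4).
#' @return Named list of integer vectors partitioning `1..max_scale`.
#' @export
default_scale_bins <- function(max_scale = 20, width = 4) {
  starts <- seq(1, max_scale, by = width)
  out <- lapply(starts, function(s) seq(s, min(s + width - 1, max_scale)))
  names(out) <- vapply(out, function(b) sprintf("%d-%d", b[1], b[length(b)]),
                       "")
  out
}

#' Per-feature selection frequency across CV folds
#'
#' Fraction of folds whose fitted model gave the feature a coefficient
#' with absolute value above 1e-8 (soft-thresholding produces exact
#' zeros; the threshold only guards float dust).
#'
#' @param cv A `loso_cv`, or a list of character vectors of selected
#'   feature names (one per fold).
#' @param feature_names Feature names for the output; defaults to the
#'   names recorded in `cv`.
#' @return Named numeric vector of frequencies in \[0, 1\].
#' @export
selection_frequency <- function(cv, feature_names = NULL) {
  sel <- if (inherits(cv, "loso_cv")) lapply(cv$folds, `[[`, "selected")
         else cv
  if (length(sel) < 1) stop_invalid("need at least one fold")
  if (is.null(feature_names)) {
    feature_names <- if (inherits(cv, "loso_cv")) cv$feature_names
                     else sort(unique(unlist(sel)))
  }
  counts <- table(factor(unlist(sel), levels = feature_names))
  stats::setNames(as.numeric(counts) / length(sel), feature_names)
}

.parse_feature_names <- function(nm) {
  ok <- grepl("^.+_s[0-9]+$", nm)
  if (!all(ok))
    stop_format(paste("feature names not of the form <channel>_s<scale>:",
                      paste(utils::head(nm[!ok], 3), collapse = ", ")))
  list(channel = sub("_s[0-9]+$", "", nm),
       scale = as.integer(sub("^.+_s", "", nm)))
}

#' Aggregate selection frequencies into a channel x bin map
#'
#' The value of a (channel, bin) cell is the maximum selection frequency
#' among that channel's scale factors inside the bin. E.g. frequencies
#' 0.3/0.5/0.7/0.9 on scales 1-4 of one channel give that channel a
#' first-bin value of 0.9.
#'
#' @param freqs Named per-feature frequencies (names
#'   `<channel>_s<scale>`), as returned by [selection_frequency()].
#' @param bins Scale bins, a partition of the scales present (default
#'   [default_scale_bins()]).
#' @return Object of class `selection_map`: `values` (channels x bins
#'   matrix in \[0, 1\]), `bins`, `coordinates`.
#' @export
bin_frequencies <- function(freqs, bins = default_scale_bins()) {
  parsed <- .parse_feature_names(names(freqs))
  channels <- unique(parsed$channel)
  vals <- matrix(0, length(channels), length(bins),
                 dimnames = list(channels, names(bins)))
  for (b in seq_along(bins)) {
    in_bin <- parsed$scale %in% bins[[b]]
    if (!any(in_bin)) next
    agg <- tapply(freqs[in_bin], parsed$channel[in_bin], max)
    vals[names(agg), b] <- agg
  }
  coords <- montage_coordinates()
  structure(list(values = vals, bins = bins,
                 coordinates = coords[coords$channel %in% channels, ]),
            class = "selection_map")
}

#' @export
print.selection_map <- function(x, ...) {
  cat(sprintf("<selection_map> %d channels x %d bins\n",
              nrow(x$values), ncol(x$values)))
  print(round(x$values, 2))
  invisible(x)
}

#' Export a selection-frequency map as long-format CSV
#'
#' One row per (channel, bin): channel, bin, value, x, y with the
#' schematic 10-20 coordinates.
#'
#' @param map A `selection_map`.
#' @param path Output CSV file.
#' @return Invisibly, the exported data.frame.
#' @export
topomap_export <- function(map, path) {
  coords <- montage_coordinates()
  df <- expand.grid(channel = rownames(map$values),
                    bin = colnames(map$values),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$value <- map$values[cbind(df$channel, df$bin)]
  i <- match(df$channel, coords$channel)
  df$x <- coords$x[i]
  df$y <- coords$y[i]
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Read back a map exported by [topomap_export()]
#'
#' @param path CSV file.
#' @return A `selection_map` (bins restored from the bin labels).
#' @export
topomap_read <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("channel", "bin", "value")
  if (!all(need %in% names(df))) stop_format("not a topomap CSV")
  channels <- unique(df$channel)
  bin_names <- unique(df$bin)
  vals <- matrix(0, length(channels), length(bin_names),
                 dimnames = list(channels, bin_names))
  vals[cbind(df$channel, df$bin)] <- df$value
  bins <- lapply(strsplit(bin_names, "-"), function(p)
    seq(as.integer(p[1]), as.integer(p[2])))
  names(bins) <- bin_names
  coords <- montage_coordinates()
  structure(list(values = vals, bins = bins,
                 coordinates = coords[coords$channel %in% channels, ]),
            class = "selection_map")
}
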