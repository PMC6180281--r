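# Multiscale entropy: coarse-graining + sample entropy per scale factor.
# Conventions (Richman-Moorman / Costa): Chebyshev distance, strict
# matching (< r), self-matches excluded, both template counts taken over
# start indices 1..M-m, and the tolerance fixed once from the SD of the
# original (scale-1) series and reused at every scale.

#' Sample-entropy parameters
#'
#' @param m Pattern (template) length; default 2.
#' @param r_frac Similarity criterion as a fraction of the SD of the
#'   original series; default 0.15.
#' @param max_scale Largest coarse-graining scale factor; default 20.
#' @return Object of class `sampen_params`.
#' @export
sampen_params <- function(m = 2, r_frac = 0.15, max_scale = 20) {
  if (m < 1) stop_invalid("'m' must be >= 1")
  if (r_frac <= 0) stop_invalid("'r_frac' must be positive")
  if (max_scale < 1) stop_invalid("'max_scale' must be >= 1")
  structure(list(m = as.integer(m), r_frac = r_frac,
                 max_scale = as.integer(max_scale)),
            class = "sampen_params")
}

#' Coarse-grain a series at scale factor tau
#'
#' Averages the series inside consecutive non-overlapping windows of
#' length `tau`; trailing samples that do not fill a window are dropped,
#' so the result has `floor(length(x) / tau)` elements.
#'
#' @param x Numeric vector.
#' @param tau Scale factor, `1 <= tau <= length(x)`.
#' @return Numeric vector of length `floor(length(x) / tau)`.
#' @examples
#' coarse_grain(1:6, 2)  # 1.5 3.5 5.5
#' @export
coarse_grain <- function(x, tau) {
  n <- length(x)
  if (tau < 1 || tau > n)
    stop_invalid(sprintf("'tau' must lie in [1, %d]", n))
  tau <- as.integer(tau)
  if (tau == 1L) return(x)
  m <- n %/% tau
  colMeans(matrix(x[seq_len(m * tau)], nrow = tau))
}

#' Sample entropy of a series
#'
#' Counts pairs of m-length templates (start indices 1..M-m, k < l) whose
#' Chebyshev distance is strictly below `r_abs`, and pairs of
#' (m+1)-length templates over the same index range, and returns
#' `-log(N_m1 / N_m)`. When either count is zero the entropy is
#' undefined and `NA` is returned (with attribute `undefined = TRUE`).
#'
#' @param y Numeric vector of length M > m + 1.
#' @param m Template length.
#' @param r_abs Absolute similarity tolerance (> 0).
#' @return Non-negative scalar, or `NA` when no matches exist.
#' @examples
#' sample_entropy(rnorm(500), m = 2, r_abs = 0.15)
#' @export
sample_entropy <- function(y, m, r_abs) {
  M <- length(y)
  if (M <= m + 1) stop_invalid("series too short: need length > m + 1")
  if (r_abs <= 0) stop_invalid("'r_abs' must be positive")
  cnt <- sampen_counts(as.numeric(y), as.integer(m), r_abs)
  if (cnt$n_m == 0 || cnt$n_m1 == 0)
    return(structure(NA_real_, undefined = TRUE))
  -log(cnt$n_m1 / cnt$n_m)
}

#' Multiscale entropy curve of one channel
#'
#' Computes `sample_entropy(coarse_grain(x, tau), m, r_abs)` for
#' `tau = 1..max_scale`, with `r_abs = r_frac * sd(x)` fixed from the
#' original series and reused at every scale, which makes the curve
#' invariant under rescaling of the input.
#'
#' @param x Numeric vector; must satisfy
#'   `length(x) >= (m + 2) * max_scale`.
#' @param params A [sampen_params()].
#' @param channel Optional channel label stored on the result.
#' @return Object of class `mse_curve`: list with `channel`, `scales`,
#'   `entropy` (NA at undefined scales), `r_abs`, `undefined_scales`.
#' @export
mse_curve <- function(x, params = sampen_params(), channel = NA_character_) {
  n <- length(x)
  need <- (params$m + 2L) * params$max_scale
  if (n < need) {
    feasible <- n %/% (params$m + 2L)
    stop_invalid(sprintf(
      "series of length %d too short for max_scale %d; largest feasible scale is %d",
      n, params$max_scale, feasible))
  }
  r_abs <- params$r_frac * stats::sd(x)
  if (!is.finite(r_abs) || r_abs <= 0)
    stop_invalid("input series has zero variance; tolerance undefined")
  ent <- vapply(seq_len(params$max_scale), function(tau) {
    as.numeric(sample_entropy(coarse_grain(x, tau), params$m, r_abs))
  }, numeric(1))
  structure(list(channel = channel, scales = seq_len(params$max_scale),
                 entropy = ent, r_abs = r_abs,
                 undefined_scales = which(is.na(ent))),
            class = "mse_curve")
}

#' @export
print.mse_curve <- function(x, ...) {
  cat(sprintf("<mse_curve> channel %s, scales 1..%d, r_abs = %.4g\n",
              x$channel, length(x$scales), x$r_abs))
  print(round(x$entropy, 3))
  invisible(x)
}

#' Feature names in channel-major, scale-minor order
#'
#' @param channels Channel labels.
#' @param max_scale Number of scales.
#' @return Character vector `"<channel>_s<scale>"`, channels varying
#'   slowest.
#' @export
feature_names <- function(channels = MONTAGE_10_20, max_scale = 20) {
  as.vector(t(outer(channels, seq_len(max_scale),
                    function(ch, s) paste0(ch, "_s", s))))
}

#' Extract the multiscale-entropy feature row of one recording
#'
#' Removes the linear trend from each channel, computes its MSE curve,
#' and concatenates the curves in montage order into `channels x scales`
#' named features. Undefined entropies propagate as `NA`.
#'
#' @param rec An `eeg_recording`.
#' @param params A [sampen_params()].
#' @param detrend Remove a per-channel linear trend before analysis
#'   (default TRUE; the tolerance SD is computed after detrending).
#' @return Named numeric vector of `nrow(rec$data) * max_scale` features,
#'   with attributes `subject_id`, `session_id`, `group`.
#' @export
extract_features <- function(rec, params = sampen_params(), detrend = TRUE) {
  if (!inherits(rec, "eeg_recording"))
    stop_invalid("'rec' must be an eeg_recording")
  channels <- rownames(rec$data)
  vals <- lapply(seq_along(channels), function(ci) {
    x <- rec$data[ci, ]
    if (detrend) {
      t_idx <- seq_along(x)
      x <- stats::residuals(stats::lm.fit(cbind(1, t_idx), x))
    }
    curve <- tryCatch(
      mse_curve(x, params, channel = channels[ci]),
      error = function(e) stop_invalid(sprintf(
        "channel %s: %s", channels[ci], conditionMessage(e))))
    curve$entropy
  })
  out <- unlist(vals)
  names(out) <- feature_names(channels, params$max_scale)
  attr(out, "subject_id") <- rec$subject_id
  attr(out, "session_id") <- rec$session_id
  attr(out, "group") <- rec$group
  out
}

#' Build the cohort feature table
#'
#' Applies [extract_features()] to every recording and assembles the
#' session-by-feature table with metadata columns first.
#'
#' @param recordings List of `eeg_recording` objects (e.g.
#'   `cohort$recordings`).
#' @param params A [sampen_params()].
#' @param detrend Passed to [extract_features()].
#' @return A `feature_table` data.frame: columns `subject_id`,
#'   `session_id`, `group`, then one column per feature.
#' @export
extract_feature_table <- function(recordings, params = sampen_params(),
                                  detrend = TRUE) {
  rows <- lapply(recordings, function(rec) {
    f <- extract_features(rec, params, detrend)
    cbind(data.frame(subject_id = attr(f, "subject_id"),
                     session_id = attr(f, "session_id"),
                     group = attr(f, "group"),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(f), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  as_feature_table(out)
}
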