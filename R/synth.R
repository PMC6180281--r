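# Synthetic cohort generator: white/pink noise mixtures with a planted
# severity gradient on a subset of posterior channels, plus a
# linear-Gaussian symptom model. The mixture is the minimal signal model
# with the multiscale-entropy geometry the analysis assumes: white noise
# loses sample entropy as it is coarse-grained while 1/f noise does not,
# so increasing the pink weight lowers short-scale entropy and flattens
# the curve, producing the characteristic crossover between groups.

# deterministic sub-seed derivation; stays below 2^31
.sub_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483647 + i * 1046527) %% 2147483647)
}

# spectrally shape a white vector into 1/f noise, standardized
.pink_filter <- function(z) {
  n <- length(z)
  zf <- stats::fft(z)
  k <- 0:(n - 1)
  f <- pmin(k, n - k)               # symmetric frequency index
  amp <- ifelse(f >= 1, 1 / sqrt(f), 0)
  x <- Re(stats::fft(zf * amp, inverse = TRUE)) / n
  (x - mean(x)) / stats::sd(x)
}

#' Seeded 1/f (pink) noise
#'
#' Generates a zero-mean, unit-variance sequence whose power spectral
#' density decays approximately as 1/f, by spectral shaping of white
#' Gaussian noise with amplitude weight f^(-1/2) (DC removed).
#'
#' @param n Number of samples (>= 2).
#' @param seed Integer seed; the output is fully determined by it.
#' @return Numeric vector of length `n` with sample mean 0 and sample SD 1.
#' @examples
#' x <- pink_noise(1024, seed = 1)
#' @export
pink_noise <- function(n, seed) {
  if (!is.numeric(n) || length(n) != 1 || n < 2)
    stop_invalid("'n' must be a single integer >= 2")
  set.seed(seed)
  .pink_filter(stats::rnorm(n))
}

#' White/pink noise mixture channel signal
#'
#' Returns a standardized mixture sqrt(1-w) * white + sqrt(w) * pink of
#' independent white and 1/f Gaussian noise. Higher pink weight `w` lowers
#' scale-1 sample entropy (the series becomes more predictable) and keeps
#' entropy high at long scales, flattening the multiscale-entropy curve.
#'
#' @param n Number of samples (>= 2).
#' @param w Pink-noise weight in \[0, 1\]; 0 gives pure white noise, 1 pure
#'   pink noise.
#' @param seed Integer seed.
#' @return Numeric vector of length `n`, standardized to mean 0, SD 1.
#' @export
generate_channel_signal <- function(n, w, seed) {
  if (!is.numeric(w) || length(w) != 1 || is.na(w) || w < 0 || w > 1)
    stop_invalid("'w' must be a single value in [0, 1]")
  if (!is.numeric(n) || length(n) != 1 || n < 2)
    stop_invalid("'n' must be a single integer >= 2")
  set.seed(seed)
  white <- stats::rnorm(n)
  pink <- .pink_filter(stats::rnorm(n))
  white <- (white - mean(white)) / stats::sd(white)
  x <- sqrt(1 - w) * white + sqrt(w) * pink
  (x - mean(x)) / stats::sd(x)
}

#' Default symptom loadings for the synthetic cohort
#'
#' A 12 x 1 loading matrix mapping the latent severity factor to mean
#' symptom scores. Mood/behaviour symptoms that track dementia severity
#' (apathy, dysphoria, anxiety, agitation, night-time disturbance) carry
#' the largest loadings; psychotic and euphoric symptoms carry small ones.
#'
#' @return Numeric matrix, 12 rows named by [NPI_SYMPTOMS], one column.
#' @export
default_npi_loadings <- function() {
  matrix(c(DEL = 1, HAL = 0.5, AG = 2, DEP = 2.5, ANX = 2, APA = 3,
           IRR = 2, EUP = 0.3, DIS = 1.5, ABE = 1, NIG = 2, APP = 1),
         ncol = 1, dimnames = list(NPI_SYMPTOMS, "severity"))
}

#' Specification of a synthetic cohort
#'
#' Collects the geometry and effect parameters of a synthetic EEG cohort:
#' group sizes, sessions per subject, recording length and rate, montage,
#' per-group pink-noise weights on the effect channels, and the symptom
#' model. Defaults reproduce the reference cohort geometry (15/15/69/24
#' subjects in groups HC/AD1/AD2/AD3, 3 sessions of 10 s at 256 Hz).
#'
#' @param group_sizes Named integer vector, group label -> subject count.
#' @param sessions_per_subject Sessions recorded per subject.
#' @param duration_s Session length in seconds.
#' @param fs Sampling rate in Hz; `fs * duration_s` must be a positive
#'   integer.
#' @param channels Ordered character vector of exactly 19 unique labels.
#' @param mix_weights Named numeric vector, group -> pink weight in \[0,1\]
#'   applied on the effect channels. The default gradient 0.2/0.35/0.5/0.8
#'   makes the extreme contrast easily separable and the mildest one hard.
#' @param baseline_weight Pink weight on non-effect channels (all groups).
#' @param effect_channels Channels where group differences are planted.
#' @param w_jitter SD of the per-subject jitter on the effect weight; the
#'   jittered weight is the subject's latent severity.
#' @param npi_loadings 12 x k numeric matrix linking latent severity to
#'   mean symptom scores.
#' @param noise_sd SD of the Gaussian symptom noise (scores truncated
#'   at 0).
#' @param seed Integer seed determining the whole cohort.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(group_sizes = c(HC = 15, AD1 = 15, AD2 = 69, AD3 = 24),
                        sessions_per_subject = 3,
                        duration_s = 10,
                        fs = 256,
                        channels = MONTAGE_10_20,
                        mix_weights = c(HC = 0.2, AD1 = 0.35,
                                        AD2 = 0.5, AD3 = 0.8),
                        baseline_weight = 0.3,
                        effect_channels = c("T5", "T6", "O1", "O2"),
                        w_jitter = 0.05,
                        npi_loadings = default_npi_loadings(),
                        noise_sd = 0.5,
                        seed = 1L) {
  if (is.null(names(group_sizes)) || any(names(group_sizes) == ""))
    stop_invalid("'group_sizes' must be a named vector")
  if (any(group_sizes < 1))
    stop_invalid("'group_sizes': every group needs at least 1 subject")
  n_samp <- fs * duration_s
  if (n_samp <= 0 || abs(n_samp - round(n_samp)) > 1e-9)
    stop_invalid("'fs * duration_s' must be a positive integer")
  if (length(channels) != 19 || anyDuplicated(channels))
    stop_invalid("'channels' must hold exactly 19 unique labels")
  if (!all(names(group_sizes) %in% names(mix_weights)))
    stop_invalid("'mix_weights' must cover every group in 'group_sizes'")
  if (any(mix_weights < 0 | mix_weights > 1) ||
      baseline_weight < 0 || baseline_weight > 1)
    stop_invalid("'mix_weights' and 'baseline_weight' must lie in [0, 1]")
  if (!all(effect_channels %in% channels))
    stop_invalid("'effect_channels' must be a subset of 'channels'")
  npi_loadings <- as.matrix(npi_loadings)
  if (nrow(npi_loadings) != 12)
    stop_invalid("'npi_loadings' must have 12 rows (one per symptom)")
  if (noise_sd <= 0) stop_invalid("'noise_sd' must be positive")
  structure(list(group_sizes = group_sizes,
                 sessions_per_subject = as.integer(sessions_per_subject),
                 duration_s = duration_s, fs = fs, channels = channels,
                 mix_weights = mix_weights,
                 baseline_weight = baseline_weight,
                 effect_channels = effect_channels,
                 w_jitter = w_jitter, npi_loadings = npi_loadings,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

new_recording <- function(subject_id, session_id, group, fs, data) {
  stopifnot(is.matrix(data))
  structure(list(subject_id = subject_id, session_id = session_id,
                 group = group, fs = fs, data = data),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s session %s group %s: %d ch x %d samples @ %g Hz\n",
              x$subject_id, x$session_id, x$group,
              nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

#' Generate a synthetic cohort of EEG recordings and symptom scores
#'
#' Produces one recording per subject and session. Effect channels receive
#' the subject's jittered group pink weight (the latent severity); all
#' other channels share the baseline weight. Symptom scores are drawn from
#' the linear-Gaussian model `loadings %*% severity + noise`, truncated at
#' zero. Everything is a deterministic function of `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return Object of class `eeg_cohort`: list with `recordings` (list of
#'   `eeg_recording`), `npi` (data.frame: subject_id + 12 symptom columns),
#'   and `subjects` (data.frame: subject_id, group, severity = the
#'   subject's planted latent severity).
#' @examples
#' spec <- cohort_spec(group_sizes = c(HC = 2, AD3 = 2), duration_s = 2)
#' coh <- generate_cohort(spec)
#' length(coh$recordings)  # 4 subjects x 3 sessions
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec"))
    stop_invalid("'spec' must be a cohort_spec")
  n <- as.integer(round(spec$fs * spec$duration_s))
  groups <- names(spec$group_sizes)
  recordings <- list()
  subj_rows <- list()
  npi_rows <- list()
  counter <- 0L
  subj_idx <- 0L
  for (g in groups) {
    for (s in seq_len(spec$group_sizes[[g]])) {
      subj_idx <- subj_idx + 1L
      subject_id <- sprintf("%s%02d", g, s)
      set.seed(.sub_seed(spec$seed, 7000000 + subj_idx))
      w_subj <- spec$mix_weights[[g]] + stats::rnorm(1, 0, spec$w_jitter)
      w_subj <- min(max(w_subj, 0), 1)
      for (sess in seq_len(spec$sessions_per_subject)) {
        session_id <- sprintf("s%d", sess)
        dat <- matrix(NA_real_, nrow = 19, ncol = n,
                      dimnames = list(spec$channels, NULL))
        for (ci in seq_along(spec$channels)) {
          counter <- counter + 1L
          ch <- spec$channels[ci]
          w <- if (ch %in% spec$effect_channels) w_subj
               else spec$baseline_weight
          dat[ci, ] <- generate_channel_signal(
            n, w, .sub_seed(spec$seed, counter))
        }
        recordings[[length(recordings) + 1L]] <-
          new_recording(subject_id, session_id, g, spec$fs, dat)
      }
      # symptom scores from the latent severity
      set.seed(.sub_seed(spec$seed, 9000000 + subj_idx))
      mu <- drop(spec$npi_loadings %*% rep(w_subj, ncol(spec$npi_loadings)))
      scores <- pmax(0, mu + stats::rnorm(12, 0, spec$noise_sd))
      npi_rows[[subj_idx]] <- c(list(subject_id = subject_id),
                                as.list(stats::setNames(scores, NPI_SYMPTOMS)))
      subj_rows[[subj_idx]] <- data.frame(subject_id = subject_id,
                                          group = g, severity = w_subj,
                                          stringsAsFactors = FALSE)
    }
  }
  structure(list(recordings = recordings,
                 npi = do.call(rbind, lapply(npi_rows, as.data.frame)),
                 subjects = do.call(rbind, subj_rows),
                 spec = spec),
            class = "eeg_cohort")
}

#' @export
print.eeg_cohort <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat(sprintf("<eeg_cohort> %d subjects (%s), %d recordings\n",
              nrow(x$subjects),
              paste(sprintf("%s:%d", names(tab), tab), collapse = ", "),
              length(x$recordings)))
  invisible(x)
}

#' Write a cohort to per-session CSV files
#'
#' Writes each recording with [write_recording_csv()], a manifest table
#' (subject_id, session_id, group, fs, path) and the symptom table as
#' `npi.csv`.
#'
#' @param cohort An `eeg_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest data.frame.
#' @export
write_cohort_csv <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- do.call(rbind, lapply(cohort$recordings, function(rec) {
    fn <- sprintf("%s_%s.csv", rec$subject_id, rec$session_id)
    write_recording_csv(rec, file.path(dir, fn))
    data.frame(subject_id = rec$subject_id, session_id = rec$session_id,
               group = rec$group, fs = rec$fs, path = fn,
               stringsAsFactors = FALSE)
  }))
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  write.csv(cohort$npi, file.path(dir, "npi.csv"), row.names = FALSE)
  invisible(manifest)
}
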