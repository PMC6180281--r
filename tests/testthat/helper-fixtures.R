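# Shared fixtures. Cohorts and feature tables are generated in code and
# memoized so several test files can reuse one extraction.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# small two-group cohort with the default planted contrast
small_cohort <- function(seed = 11, n_per_group = 6) {
  memo(sprintf("coh_%d_%d", seed, n_per_group),
       generate_cohort(cohort_spec(
         group_sizes = c(HC = n_per_group, AD3 = n_per_group),
         seed = seed)))
}

small_features <- function(seed = 11, n_per_group = 6) {
  memo(sprintf("ft_%d_%d", seed, n_per_group),
       extract_feature_table(small_cohort(seed, n_per_group)$recordings))
}

# feature table with synthetic Gaussian entries (IO/classifier tests that
# do not need real entropy values)
gaussian_feature_table <- function(n_subj = 10, sessions = 3, p = 20,
                                   groups = c("HC", "AD3"), seed = 1,
                                   channels = MONTAGE_10_20[1:(p %/% 2)],
                                   effect = 0) {
  set.seed(seed)
  fn <- feature_names(channels, max_scale = ceiling(p / length(channels)))[1:p]
  rows <- list()
  for (s in seq_len(n_subj)) {
    g <- groups[1 + (s - 1) %% length(groups)]
    shift <- if (g == groups[2]) effect else 0
    for (k in seq_len(sessions)) {
      f <- rnorm(p) + shift * c(rep(1, ceiling(p / 4)),
                                rep(0, p - ceiling(p / 4)))
      rows[[length(rows) + 1]] <- cbind(
        data.frame(subject_id = sprintf("S%02d", s),
                   session_id = sprintf("s%d", k), group = g,
                   stringsAsFactors = FALSE),
        as.data.frame(as.list(setNames(f, fn)), check.names = FALSE))
    }
  }
  as_feature_table(do.call(rbind, rows))
}

# independent minimal EDF writer (round-trip oracle for read_edf); the
# produced file is a synthetic stand-in for an acquisition-system export
write_edf_fixture <- function(rec, path, n_per_rec = NULL) {
  dat <- rec$data
  ns <- nrow(dat)
  n <- ncol(dat)
  if (is.null(n_per_rec)) n_per_rec <- rec$fs
  n_rec <- n / n_per_rec
  stopifnot(n_rec == round(n_rec))
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  pmin_ <- signif(apply(dat, 1, min), 6)
  pmax_ <- signif(apply(dat, 1, max), 6)
  pmax_[pmax_ == pmin_] <- pmin_[pmax_ == pmin_] + 1
  dmin <- -32768
  dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad("synthetic patient", 80), pad("synthetic rec", 80),
    pad("01.01.20", 8), pad("00.00.00", 8), pad(256 * (1 + ns), 8),
    pad("", 44), pad(n_rec, 8), pad(format(n_per_rec / rec$fs), 8),
    pad(ns, 4),
    paste(pad(rownames(dat), 16), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(rep(pad("uV", 8), ns), collapse = ""),
    paste(pad(pmin_, 8), collapse = ""),
    paste(pad(pmax_, 8), collapse = ""),
    paste(rep(pad(dmin, 8), ns), collapse = ""),
    paste(rep(pad(dmax, 8), ns), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(rep(pad(n_per_rec, 8), ns), collapse = ""),
    paste(rep(pad("", 32), ns), collapse = ""))
  writeChar(hdr, con, eos = NULL)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      seg <- dat[s, ((r - 1) * n_per_rec + 1):(r * n_per_rec)]
      dig <- round((seg - pmin_[s]) / (pmax_[s] - pmin_[s]) *
                     (dmax - dmin) + dmin)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
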