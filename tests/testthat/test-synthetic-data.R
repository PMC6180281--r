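test_that("pink_noise is seeded, standardized, with ~1/f spectrum", {
  expect_identical(pink_noise(2560, 7), pink_noise(2560, 7))
  expect_false(identical(pink_noise(2560, 7), pink_noise(2560, 8)))
  expect_error(pink_noise(1, 1), class = "eegmse_invalid_argument")

  x <- pink_noise(2^16, 1)
  expect_lt(abs(mean(x)), 0.02)
  expect_lt(abs(sd(x) - 1), 0.02)
  # least-squares slope of the log-log periodogram
  n <- length(x)
  spec <- Mod(fft(x)[2:(n / 2)])^2 / n
  f <- (1:(n / 2 - 1)) / n
  slope <- coef(lm(log(spec) ~ log(f)))[2]
  expect_gt(slope, -1.3)
  expect_lt(slope, -0.7)
})

test_that("generate_channel_signal validates w and is reproducible", {
  expect_error(generate_channel_signal(100, -0.1, 1),
               class = "eegmse_invalid_argument")
  expect_error(generate_channel_signal(100, 1.1, 1),
               class = "eegmse_invalid_argument")
  expect_identical(generate_channel_signal(512, 0.5, 3),
                   generate_channel_signal(512, 0.5, 3))
})

test_that("mixture weight shapes the MSE curve as designed", {
  # Monte-Carlo over 50 seeds: white noise entropy falls with scale;
  # pink noise keeps a much flatter curve
  p <- sampen_params()
  mc <- function(w) rowMeans(vapply(1:50, function(s)
    mse_curve(generate_channel_signal(2560, w, s + 300 * w), p)$entropy,
    numeric(20)))
  white <- mc(0)
  pink <- mc(1)
  expect_true(all(diff(white) < 0.02))   # non-increasing in expectation
  expect_lt(white[20] - white[1], pink[20] - pink[1])
  expect_gt(white[1], pink[1])           # pink starts lower at scale 1
})

test_that("generate_cohort has the declared geometry and determinism", {
  spec <- cohort_spec(group_sizes = c(HC = 2, AD2 = 1), duration_s = 2,
                      seed = 5)
  coh <- generate_cohort(spec)
  expect_length(coh$recordings, 9)  # 3 subjects x 3 sessions
  for (r in coh$recordings) {
    expect_identical(dim(r$data), c(19L, 512L))
    expect_true(all(is.finite(r$data)))
  }
  expect_identical(coh$npi[, NPI_SYMPTOMS],
                   generate_cohort(spec)$npi[, NPI_SYMPTOMS])
  coh2 <- generate_cohort(cohort_spec(group_sizes = c(HC = 2, AD2 = 1),
                                      duration_s = 2, seed = 6))
  expect_false(identical(coh$recordings[[1]]$data, coh2$recordings[[1]]$data))
})

test_that("default spec gives the reference cohort geometry", {
  # 123 subjects x 3 sessions, 19 x 2560 matrices; checked without
  # generating the signals by validating the spec arithmetic, then
  # generating one subject's worth of data
  spec <- cohort_spec()
  expect_equal(sum(spec$group_sizes), 123)
  expect_equal(spec$fs * spec$duration_s, 2560)
  coh1 <- generate_cohort(cohort_spec(group_sizes = c(HC = 1)))
  expect_length(coh1$recordings, 3)
  expect_identical(dim(coh1$recordings[[1]]$data), c(19L, 2560L))
})

test_that("cohort_spec rejects inconsistent fields", {
  expect_error(cohort_spec(group_sizes = c(1, 2)),
               class = "eegmse_invalid_argument")
  expect_error(cohort_spec(group_sizes = c(HC = 0)),
               class = "eegmse_invalid_argument")
  expect_error(cohort_spec(fs = 256, duration_s = 0.0003),
               class = "eegmse_invalid_argument")
  expect_error(cohort_spec(channels = c("A", "B")),
               class = "eegmse_invalid_argument")
  expect_error(cohort_spec(mix_weights = c(HC = 2, AD1 = 0.3,
                                           AD2 = 0.5, AD3 = 0.8)),
               class = "eegmse_invalid_argument")
  expect_error(cohort_spec(effect_channels = "XX"),
               class = "eegmse_invalid_argument")
  expect_error(cohort_spec(noise_sd = 0),
               class = "eegmse_invalid_argument")
})

test_that("planted ordering: scale-1 entropy decreases HC -> AD3", {
  # Monte-Carlo over 20 cohort draws, scale-1 sample entropy on the
  # effect channels only (1 session per subject to keep this fast)
  groups <- c("HC", "AD1", "AD2", "AD3")
  means <- matrix(NA_real_, 20, 4, dimnames = list(NULL, groups))
  for (d in 1:20) {
    spec <- cohort_spec(group_sizes = c(HC = 3, AD1 = 3, AD2 = 3, AD3 = 3),
                        sessions_per_subject = 1, seed = 100 + d)
    coh <- generate_cohort(spec)
    e <- vapply(coh$recordings, function(r) {
      mean(vapply(spec$effect_channels, function(ch) {
        x <- r$data[ch, ]
        sample_entropy(x, 2, 0.15 * sd(x))
      }, numeric(1)))
    }, numeric(1))
    g <- vapply(coh$recordings, `[[`, "", "group")
    means[d, ] <- tapply(e, g, mean)[groups]
  }
  mu <- colMeans(means)
  se <- apply(means, 2, sd) / sqrt(nrow(means))
  expect_true(all(diff(mu) < 0))
  # separations exceed Monte-Carlo uncertainty
  expect_true(all(-diff(mu) > 2 * sqrt(se[-1]^2 + se[-4]^2)))
})

test_that("HC vs AD3 group-mean MSE curves cross at short scales", {
  # The mean-difference curve (HC minus AD3) starts positive and turns
  # negative; a 200-seed Monte-Carlo run of the stated oracle locates the
  # sign change at scale 4 (+/- 1 for cohort-level noise), so the frozen
  # expectation is a single sign change inside scales 3..5.
  spec <- cohort_spec(group_sizes = c(HC = 8, AD3 = 8), seed = 41)
  coh <- generate_cohort(spec)
  p <- sampen_params(max_scale = 8)
  curves <- vapply(coh$recordings, function(r) {
    rowMeans(vapply(spec$effect_channels, function(ch)
      mse_curve(r$data[ch, ], p)$entropy, numeric(8)))
  }, numeric(8))
  g <- vapply(coh$recordings, `[[`, "", "group")
  d <- rowMeans(curves[, g == "HC"]) - rowMeans(curves[, g == "AD3"])
  flips <- which(diff(sign(d)) != 0) + 1
  expect_length(flips, 1)
  expect_gte(flips, 3)
  expect_lte(flips, 5)
})

test_that("NPI scores are non-negative and track latent severity", {
  coh <- generate_cohort(cohort_spec(
    group_sizes = c(HC = 10, AD1 = 10, AD2 = 10, AD3 = 10), seed = 5,
    duration_s = 1))  # short signals; only the NPI block is used
  sc <- as.matrix(coh$npi[, NPI_SYMPTOMS])
  expect_true(all(sc >= 0))
  cors <- apply(sc, 2, cor, y = coh$subjects$severity)
  expect_gt(max(cors), 0.5)
})

test_that("write_cohort_csv produces manifest, sessions, and npi", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(cohort_spec(group_sizes = c(HC = 2),
                                     duration_s = 1, seed = 2))
  man <- write_cohort_csv(coh, dir)
  expect_identical(nrow(man), 6L)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "npi.csv")))
  rec <- read_recording_csv(file.path(dir, man$path[1]), fs = man$fs[1])
  expect_equal(unname(rec$data), unname(coh$recordings[[1]]$data),
               tolerance = 1e-12)
})
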