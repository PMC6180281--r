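test_that("recording CSV round-trips exactly", {
  rec <- generate_cohort(cohort_spec(group_sizes = c(HC = 1),
                                     duration_s = 1, seed = 3))$recordings[[1]]
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(rec, path)
  back <- read_recording_csv(path, fs = 256, subject_id = "HC01",
                             session_id = "s1", group = "HC", strict = TRUE)
  expect_equal(back$data, rec$data, tolerance = 1e-12)
  expect_identical(rownames(back$data), MONTAGE_10_20)
})

test_that("strict mode rejects an 18-channel file", {
  rec <- generate_cohort(cohort_spec(group_sizes = c(HC = 1),
                                     duration_s = 1, seed = 3))$recordings[[1]]
  rec$data <- rec$data[1:18, ]
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(rec, path)
  expect_error(read_recording_csv(path, 256, strict = TRUE),
               class = "eegmse_format_error")
  expect_s3_class(read_recording_csv(path, 256, strict = FALSE)$data,
                  NA)  # non-strict read succeeds
})

test_that("non-numeric cells are rejected naming the channel", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("channel,t1,t2", "Fp1,0.1,0.2", "Fp2,0.3,oops"), path)
  err <- tryCatch(read_recording_csv(path, 256), error = identity)
  expect_s3_class(err, "eegmse_format_error")
  expect_match(conditionMessage(err), "Fp2")
})

test_that("feature tables round-trip with stable column order", {
  ft <- gaussian_feature_table(n_subj = 4, p = 12, seed = 5)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ft, p1)
  back <- read_feature_table(p1)
  expect_equal(as.data.frame(back), as.data.frame(ft), tolerance = 1e-12)
  write_feature_table(back, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("duplicate (subject, session) rows are an integrity error", {
  ft <- gaussian_feature_table(n_subj = 3, p = 6)
  dup <- rbind(as.data.frame(ft), as.data.frame(ft)[1, ])
  expect_error(as_feature_table(dup), class = "eegmse_format_error")
})

test_that("full extraction pipeline yields the 380-column table", {
  ft <- small_features()
  expect_length(feature_cols(ft), 380)
  expect_identical(names(ft)[1:3], c("subject_id", "session_id", "group"))
  # one row per subject x session of the cohort
  expect_identical(nrow(ft),
                   length(small_cohort()$recordings))
})

test_that("npi reader validates the 12-symptom schema", {
  coh <- generate_cohort(cohort_spec(group_sizes = c(HC = 2),
                                     duration_s = 1, seed = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(coh$npi, path, row.names = FALSE)
  npi <- read_npi_csv(path)
  expect_identical(names(npi), c("subject_id", NPI_SYMPTOMS))
  bad <- coh$npi
  names(bad)[2] <- "WRONG"
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_npi_csv(path), class = "eegmse_format_error")
})

test_that("analysis_config validates and parses flat config files", {
  cfg <- analysis_config(method = "enet")
  expect_equal(cfg$alpha, 0.7)
  expect_error(analysis_config(alpha = 2), class = "eegmse_invalid_argument")
  expect_error(analysis_config(contrast = c("HC", "HC")),
               class = "eegmse_invalid_argument")
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# pipeline settings", "method = enet", "alpha = 0.5",
               "max_scale = 10", "contrast = AD1:AD3", "seed = 9"), path)
  cfg2 <- read_analysis_config(path)
  expect_identical(cfg2$method, "enet")
  expect_equal(cfg2$alpha, 0.5)
  expect_identical(cfg2$mse$max_scale, 10L)
  expect_identical(cfg2$contrast, c("AD1", "AD3"))
  writeLines("nonsense_key = 1", path)
  expect_error(read_analysis_config(path), class = "eegmse_format_error")
})

test_that("EDF round-trip agrees within 16-bit quantization", {
  rec <- generate_cohort(cohort_spec(group_sizes = c(HC = 1),
                                     duration_s = 2, seed = 9))$recordings[[1]]
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf_fixture(rec, path)
  back <- read_edf(path)
  expect_identical(rownames(back$data), rownames(rec$data))
  expect_equal(back$fs, 256)
  qstep <- apply(rec$data, 1, function(v) diff(range(v))) / 65535
  expect_true(all(abs(back$data - rec$data) <= qstep + 1e-9))
})

test_that("truncated and malformed EDF files are rejected", {
  rec <- generate_cohort(cohort_spec(group_sizes = c(HC = 1),
                                     duration_s = 1, seed = 9))$recordings[[1]]
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf_fixture(rec, path)
  full <- readBin(path, "raw", file.info(path)$size)
  cut <- withr::local_tempfile(fileext = ".edf")
  writeBin(full[1:(length(full) - 100)], cut)
  expect_error(read_edf(cut), class = "eegmse_format_error")
  writeBin(full[1:100], cut)
  expect_error(read_edf(cut), class = "eegmse_format_error")
})

test_that("EDF with mismatched per-channel rates is unsupported", {
  rec <- generate_cohort(cohort_spec(group_sizes = c(HC = 1),
                                     duration_s = 1, seed = 9))$recordings[[1]]
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf_fixture(rec, path)
  raw <- readBin(path, "raw", file.info(path)$size)
  # samples-per-record field of signal 2: offset inside the signal headers
  ns <- 19
  off <- 256 + ns * (16 + 80 + 8 + 8 + 8 + 8 + 8 + 80) + 8
  raw[(off + 1):(off + 8)] <- charToRaw(formatC("128", width = 8, flag = "-"))
  writeBin(raw, path)
  err <- tryCatch(read_edf(path), error = identity)
  expect_s3_class(err, "eegmse_format_error")
  expect_match(conditionMessage(err), "rates differ")
})
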