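# Minimal reader for the European Data Format (EDF), the export format
# of most clinical EEG systems: a 256-byte ASCII header, 256 ASCII bytes
# per signal, then data records of little-endian 16-bit integers that
# are mapped to physical units linearly via the per-signal calibration
# fields. Read-only and optional: the rest of the pipeline only uses
# CSV.

.edf_field <- function(raw, off, len) {
  trimws(rawToChar(raw[(off + 1):(off + len)]))
}

.edf_num <- function(raw, off, len, what) {
  v <- suppressWarnings(as.numeric(.edf_field(raw, off, len)))
  if (any(is.na(v))) stop_format(sprintf("malformed EDF header field: %s", what))
  v
}

#' Read an EDF recording
#'
#' Parses the EDF header, checks that every signal shares one sampling
#' rate, and returns the calibrated signal matrix. Annotation channels
#' and per-signal rates are not supported.
#'
#' @param path EDF file.
#' @param subject_id,session_id,group Optional metadata (the EDF patient
#'   field is not parsed into structured metadata).
#' @return An `eeg_recording` with labels and sampling rate from the
#'   header.
#' @export
read_edf <- function(path, subject_id = NA_character_,
                     session_id = NA_character_, group = NA_character_) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  sz <- file.info(path)$size
  if (sz < 256) stop_format("truncated EDF file: header incomplete")
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", 256)
  n_rec <- .edf_num(head, 236, 8, "number of data records")
  rec_dur <- .edf_num(head, 244, 8, "record duration")
  ns <- as.integer(.edf_num(head, 252, 4, "signal count"))
  if (ns < 1) stop_format("EDF header reports no signals")
  if (n_rec < 0) stop_format("EDF files with unknown record count are unsupported")
  if (rec_dur <= 0) stop_format("malformed EDF header: record duration <= 0")
  if (sz < 256 + 256 * ns) stop_format("truncated EDF file: signal headers incomplete")
  sig <- readBin(con, "raw", 256 * ns)
  fld <- function(width, base) vapply(seq_len(ns) - 1L, function(i)
    .edf_field(sig, base * ns + i * width, width), "")
  labels <- fld(16, 0)
  numfld <- function(width, base_bytes, what) {
    v <- suppressWarnings(as.numeric(vapply(seq_len(ns) - 1L, function(i)
      .edf_field(sig, base_bytes + i * width, width), "")))
    if (any(is.na(v))) stop_format(sprintf("malformed EDF header field: %s", what))
    v
  }
  pmin_ <- numfld(8, ns * (16 + 80 + 8), "physical minimum")
  pmax_ <- numfld(8, ns * (16 + 80 + 8 + 8), "physical maximum")
  dmin_ <- numfld(8, ns * (16 + 80 + 8 + 8 + 8), "digital minimum")
  dmax_ <- numfld(8, ns * (16 + 80 + 8 + 8 + 8 + 8), "digital maximum")
  spr <- numfld(8, ns * (16 + 80 + 8 + 8 + 8 + 8 + 8 + 80),
                "samples per record")
  if (length(unique(spr)) != 1)
    stop_format("unsupported EDF: per-channel sampling rates differ")
  if (any(dmax_ == dmin_)) stop_format("malformed EDF: digital min equals max")
  spr <- spr[1]
  fs <- spr / rec_dur
  expect <- n_rec * ns * spr * 2
  payload <- readBin(con, "raw", expect)
  if (length(payload) < expect)
    stop_format("truncated EDF file: data records incomplete")
  ints <- readBin(payload, "integer", n = expect / 2, size = 2,
                  signed = TRUE, endian = "little")
  # records are blocks of [spr samples of signal 1, spr of signal 2, ...]
  dat <- matrix(NA_real_, nrow = ns, ncol = n_rec * spr)
  arr <- array(ints, dim = c(spr, ns, n_rec))
  gain <- (pmax_ - pmin_) / (dmax_ - dmin_)
  for (s in seq_len(ns)) {
    dig <- as.vector(arr[, s, ])
    dat[s, ] <- (dig - dmin_[s]) * gain[s] + pmin_[s]
  }
  rownames(dat) <- labels
  new_recording(subject_id, session_id, group, fs, dat)
}
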