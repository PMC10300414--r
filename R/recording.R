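#' Construct a multichannel EEG recording
#'
#' A lightweight container for a continuous multichannel recording:
#' a channels-by-samples matrix in microvolts, the sampling rate, ordered
#' channel names and a subject identifier.
#'
#' @param signals Numeric matrix, `n_channels x n_samples`, microvolts.
#' @param fs Sampling rate in Hz (the clinical convention here is 200 Hz).
#' @param channel_names Character vector, one unique name per row.
#' @param subject_id Subject identifier string.
#' @return An object of class `eeg_recording`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(1200), 2), fs = 20, c("C3", "C4"), "s1")
#' rec
#' @export
eeg_recording <- function(signals, fs, channel_names, subject_id = "subject") {
  signals <- as.matrix(signals)
  if (!is.numeric(signals)) abort("signals must be numeric")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) abort("fs must be a positive scalar")
  if (nrow(signals) < 1) abort("recording needs at least one channel")
  if (length(channel_names) != nrow(signals))
    abort("one channel name per signal row is required")
  if (anyDuplicated(channel_names)) abort("channel names must be unique")
  rownames(signals) <- channel_names
  structure(
    list(signals = signals, fs = fs,
         channel_names = as.character(channel_names),
         subject_id = as.character(subject_id)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s: %d channel(s) [%s], %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, nrow(x$signals),
              paste(x$channel_names, collapse = ","),
              ncol(x$signals), x$fs, ncol(x$signals) / x$fs))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$signals)

#' Write / read a recording in the package's sidecar format
#'
#' Recordings are persisted as a pair of files: `<path>` is a JSON header
#' (sampling rate, channel names, subject id, sample count, data type and
#' byte order) and `<path>` with extension replaced by `.bin` holds the
#' samples as little-endian float64, channel-interleaved by sample block
#' (channel 1 samples, then channel 2, ...).  The round trip is exact.
#'
#' @param rec An [eeg_recording()].
#' @param path Path to the JSON header file (conventionally `.eeg.json`).
#' @param channels Optional channel subset/ordering to return; default all
#'   channels in file order.  A requested channel absent from the file is
#'   an error naming that channel.
#' @param target_fs Expected sampling rate; a file whose rate differs is
#'   rejected (`on_fs_mismatch = "error"`, default) or polyphase-resampled
#'   with a warning (`"resample"`).  Use `NULL` to accept any rate.
#' @param on_fs_mismatch Policy when the stored rate differs from
#'   `target_fs`.
#' @return `read_recording()` returns an [eeg_recording()];
#'   `write_recording()` returns `path` invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  bin_path <- sidecar_bin_path(path)
  header <- list(
    format = "sleepstager-recording", version = 1L,
    subject_id = rec$subject_id, fs = rec$fs,
    channel_names = rec$channel_names,
    n_channels = nrow(rec$signals), n_samples = ncol(rec$signals),
    dtype = "float64", endian = "little", data_file = basename(bin_path)
  )
  jsonlite::write_json(header, path, auto_unbox = TRUE, digits = NA)
  con <- file(bin_path, "wb")
  on.exit(close(con))
  # row-major: one channel's full sample vector at a time
  writeBin(as.vector(t(rec$signals)), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path, channels = NULL, target_fs = 200,
                           on_fs_mismatch = c("error", "resample")) {
  on_fs_mismatch <- match.arg(on_fs_mismatch)
  if (!file.exists(path)) abort(sprintf("recording header not found: %s", path))
  header <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                     error = function(e) abort(sprintf(
                       "not a readable recording header: %s (%s)", path, conditionMessage(e))))
  if (!identical(header$format, "sleepstager-recording"))
    abort(sprintf("not a sleepstager recording file: %s", path))
  bin_path <- file.path(dirname(path), header$data_file)
  if (!file.exists(bin_path)) abort(sprintf("data file missing: %s", bin_path))
  header$fs <- as.numeric(header$fs)
  n <- header$n_channels * header$n_samples
  con <- file(bin_path, "rb")
  samples <- readBin(con, "double", n = n, size = 8, endian = "little")
  close(con)
  if (length(samples) != n) abort("recording data file is truncated")
  signals <- matrix(samples, nrow = header$n_channels, byrow = TRUE)
  rec <- eeg_recording(signals, header$fs, header$channel_names, header$subject_id)
  if (!is.null(channels)) {
    missing <- setdiff(channels, rec$channel_names)
    if (length(missing) > 0)
      abort(sprintf("channel(s) not found in recording: %s",
                    paste(missing, collapse = ", ")))
    rec <- eeg_recording(rec$signals[channels, , drop = FALSE], rec$fs,
                         channels, rec$subject_id)
  }
  if (!is.null(target_fs) && rec$fs != target_fs) {
    if (on_fs_mismatch == "error")
      abort(sprintf(
        "recording sampled at %g Hz but %g Hz expected; set on_fs_mismatch = \"resample\" to convert",
        rec$fs, target_fs))
    warn(sprintf("resampling recording from %g Hz to %g Hz", rec$fs, target_fs))
    rat <- ratio_integers(target_fs, rec$fs)
    res <- t(apply(rec$signals, 1, function(x) signal::resample(x, rat[1], rat[2])))
    rec <- eeg_recording(res, target_fs, rec$channel_names, rec$subject_id)
  }
  rec
}

sidecar_bin_path <- function(path) sub("\\.[^.]*$", "", path) |> paste0(".bin")

ratio_integers <- function(p, q) {
  # smallest integer ratio p/q for rational rates
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  scale <- 1
  while (abs(p * scale - round(p * scale)) > 1e-9 ||
         abs(q * scale - round(q * scale)) > 1e-9) scale <- scale * 10
  pi_ <- round(p * scale); qi <- round(q * scale)
  d <- g(pi_, qi)
  c(pi_ / d, qi / d)
}
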