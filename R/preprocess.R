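#' Zero-phase Butterworth bandpass filtering
#'
#' Applies the standard sleep-EEG preprocessing: a 4th-order Butterworth
#' bandpass design (default 0.5-50 Hz) run forward and backward
#' (`signal::filtfilt`) so transient waveforms such as K-complexes are
#' not phase-distorted.  The forward-backward pass squares the magnitude
#' response (about 39 dB attenuation at 80 Hz for the default band at
#' 200 Hz) while passband frequencies keep unit gain.
#'
#' @param rec An [eeg_recording()].
#' @param low,high Band edges in Hz; require `0 < low < high < fs/2`.
#' @param order Butterworth design order per edge (default 4).
#' @return A filtered [eeg_recording()] of identical shape and rate.
#' @export
bandpass <- function(rec, low = 0.5, high = 50, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(low > 0 && low < high)) abort("require 0 < low < high")
  if (high >= rec$fs / 2)
    abort(sprintf("high edge %g Hz must be below the Nyquist rate %g Hz", high, rec$fs / 2))
  bf <- signal::butter(order, c(low, high) / (rec$fs / 2), type = "pass")
  filtered <- t(apply(rec$signals, 1, function(x) signal::filtfilt(bf, x)))
  eeg_recording(filtered, rec$fs, rec$channel_names, rec$subject_id)
}

#' Segment a recording into labelled 30-s epochs
#'
#' Cuts the recording into consecutive non-overlapping epochs of
#' `epoch_seconds` and pairs them in order with the hypnogram labels.
#' Trailing samples that do not fill an epoch are dropped; if the number
#' of full epochs and the number of labels differ, both are truncated to
#' the shorter with a warning (clinical exports commonly differ by a
#' trailing epoch).
#'
#' @param rec An [eeg_recording()].
#' @param hyp Optional [hypnogram()]; when `NULL`, epochs are returned
#'   unlabelled (`stage = NA`), e.g. for prediction on new recordings.
#' @param epoch_seconds Epoch duration (default 30 s); `fs * epoch_seconds`
#'   must be an integer.
#' @param mismatch Policy when epoch and label counts differ: `"warn"`
#'   (truncate with warning, default) or `"error"`.
#' @return A tibble with columns `epoch` (0-based), `stage` (factor, may
#'   be NA), and `block` (list of `n_channels x fs*epoch_seconds`
#'   matrices).
#' @export
segment_epochs <- function(rec, hyp = NULL, epoch_seconds = 30,
                           mismatch = c("warn", "error")) {
  stopifnot(inherits(rec, "eeg_recording"))
  mismatch <- match.arg(mismatch)
  spe <- rec$fs * epoch_seconds
  if (abs(spe - round(spe)) > 1e-9) abort("fs * epoch_seconds must be an integer")
  spe <- as.integer(round(spe))
  n_full <- floor(ncol(rec$signals) / spe)
  if (n_full < 1)
    abort(sprintf("recording too short: %d samples < one %g-s epoch",
                  ncol(rec$signals), epoch_seconds))
  n <- n_full
  stages <- rep(NA_character_, n_full)
  if (!is.null(hyp)) {
    stopifnot(inherits(hyp, "hypnogram"))
    if (nrow(hyp) != n_full) {
      msg <- sprintf("recording has %d full epochs but hypnogram has %d labels; truncating to %d",
                     n_full, nrow(hyp), min(n_full, nrow(hyp)))
      if (mismatch == "error") abort(msg)
      warn(msg)
    }
    n <- min(n_full, nrow(hyp))
    stages <- as.character(hyp$stage)[seq_len(n)]
  }
  blocks <- lapply(seq_len(n), function(i) {
    rec$signals[, ((i - 1L) * spe + 1L):(i * spe), drop = FALSE]
  })
  tibble::tibble(
    epoch = seq_len(n) - 1L,
    stage = factor(stages[seq_len(n)], levels = sleep_stages()),
    block = blocks
  )
}
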