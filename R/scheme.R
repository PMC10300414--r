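#' Canonical sleep-stage and channel conventions
#'
#' The five AASM sleep-stage labels in canonical order, and the six scalp
#' EEG channels (international 10-20 system) the pipeline expects.
#'
#' @format `sleep_stages()` returns a character vector of length 5;
#'   `eeg_channels()` a character vector of length 6.
#' @export
sleep_stages <- function() c("W", "N1", "N2", "N3", "R")

#' @rdname sleep_stages
#' @export
eeg_channels <- function() c("F3", "F4", "C3", "C4", "O1", "O2")

#' Frequency-band scheme for relative PSD features
#'
#' Defines the six analysis bands -- low delta (0.5-2 Hz), delta (1-4 Hz),
#' theta (4-8 Hz), alpha (8-12 Hz), sigma (12-15 Hz) and beta (15-30 Hz) --
#' plus the analysis range (0.5-50 Hz) whose total power is the
#' normalization denominator for relative PSD.  Low delta and delta overlap
#' deliberately: slow-wave activity and K-complex transients are scored on
#' partially overlapping ranges.
#'
#' Band membership of a frequency bin `f` uses the half-open convention
#' `low < f <= high`, so with 1 Hz bins delta covers bins \{2, 3, 4\} Hz.
#'
#' @param analysis_range Numeric length-2: normalization denominator range
#'   in Hz (default `c(0.5, 50)`, matching the preprocessing bandpass).
#' @return An object of class `band_scheme`: a list with elements `bands`
#'   (named list of `c(low, high)` pairs) and `analysis_range`.
#' @examples
#' sch <- band_scheme()
#' names(sch$bands)
#' @export
band_scheme <- function(analysis_range = c(0.5, 50)) {
  bands <- list(
    low_delta = c(0.5, 2),
    delta     = c(1, 4),
    theta     = c(4, 8),
    alpha     = c(8, 12),
    sigma     = c(12, 15),
    beta      = c(15, 30)
  )
  stopifnot(length(analysis_range) == 2, analysis_range[1] < analysis_range[2])
  for (b in bands) {
    if (b[1] >= b[2]) abort("band has low >= high")
    if (b[1] < analysis_range[1] || b[2] > analysis_range[2])
      abort("band lies outside the analysis range")
  }
  structure(list(bands = bands, analysis_range = analysis_range),
            class = "band_scheme")
}

# per-channel feature names, in extraction order
channel_feature_names <- function() {
  c("low_delta", "K_comp_1", "K_comp_2", "theta",
    "alpha", "spindle_1", "spindle_2", "beta")
}

#' Names of the 48 per-epoch features
#'
#' Channel-major ordering: all eight features of F3, then F4, C3, C4, O1,
#' O2.  Eight features per channel: mean relative power in low delta,
#' theta, alpha and beta; the max (`K_comp_1`) and argmax-excluded mean
#' (`K_comp_2`) of delta-band relative power over the 59 STFT windows;
#' the analogous `spindle_1`/`spindle_2` pair on the sigma band.
#'
#' @return Character vector of length 48, e.g. `"F3.low_delta"`.
#' @export
feature_names <- function() {
  as.vector(t(outer(eeg_channels(), channel_feature_names(), paste, sep = ".")))
}

assert_stage_labels <- function(x, what = "stage") {
  bad <- setdiff(unique(as.character(x)), sleep_stages())
  if (length(bad) > 0)
    abort(sprintf("unknown %s label(s): %s", what, paste(bad, collapse = ", ")))
  invisible(x)
}
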