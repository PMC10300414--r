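#' Short-time Fourier spectrogram of one 30-s epoch channel
#'
#' Computes the epoch's spectrogram with 1-s windows and 50% overlap: a
#' 30-s epoch yields 59 windows.  Each window is tapered with a periodic
#' Hann window and the power is the squared magnitude of its DFT, kept
#' for the non-negative frequencies 0..fs/2.  With 1-s windows and no
#' zero-padding the bins fall on integer frequencies (1 Hz resolution).
#'
#' @param x Numeric vector, one channel of one epoch
#'   (`fs * epoch_seconds` samples).
#' @param fs Sampling rate in Hz; `fs * window_seconds` must be an
#'   integer.
#' @param window_seconds STFT window length (default 1 s).
#' @param overlap Fractional window overlap (default 0.5).
#' @param epoch_seconds Expected epoch duration (default 30 s); the input
#'   length is validated against it.
#' @return An object of class `spectrogram`: list with `power`
#'   (`n_windows x n_bins`, nonnegative), `freqs` (bin centres in Hz),
#'   `window_seconds`, `overlap`.
#' @examples
#' sp <- compute_spectrogram(sin(2 * pi * 10 * (0:5999) / 200), fs = 200)
#' dim(sp$power)  # 59 windows x 101 bins
#' @export
compute_spectrogram <- function(x, fs, window_seconds = 1, overlap = 0.5,
                                epoch_seconds = 30) {
  n <- length(x)
  if (n != fs * epoch_seconds)
    abort(sprintf("epoch has %d samples but fs * epoch_seconds = %g", n, fs * epoch_seconds))
  win <- fs * window_seconds
  if (abs(win - round(win)) > 1e-9) abort("fs * window_seconds must be an integer")
  win <- as.integer(round(win))
  hop <- as.integer(round(win * (1 - overlap)))
  n_windows <- (n - win) %/% hop + 1L
  starts <- (seq_len(n_windows) - 1L) * hop
  taper <- hann_window(win)
  # win x n_windows matrix of tapered segments; mvfft transforms columns
  seg <- matrix(x[outer(seq_len(win), starts, "+")], win, n_windows) * taper
  ft <- stats::mvfft(seg)
  n_bins <- win %/% 2L + 1L
  power <- t(Mod(ft[seq_len(n_bins), , drop = FALSE])^2)
  structure(
    list(power = power, freqs = (seq_len(n_bins) - 1L) * fs / win,
         window_seconds = window_seconds, overlap = overlap),
    class = "spectrogram"
  )
}

# periodic Hann taper: 0.5 * (1 - cos(2*pi*k/N)), k = 0..N-1
hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))

#' Per-window relative PSD normalization
#'
#' Divides each STFT window's power values by that window's total power
#' over the analysis range (0.5-50 Hz by default), making features
#' invariant to signal amplitude.  Bins outside the analysis range are
#' set to 0.  A window with zero in-range power gets all-zero relative
#' values and is recorded in the `degenerate_windows` attribute.
#'
#' @param spec A [compute_spectrogram()] result.
#' @param scheme A [band_scheme()].
#' @return A `spectrogram` whose in-range values sum to 1 per window,
#'   with attribute `degenerate_windows` (integer indices, possibly
#'   empty) and `relative = TRUE`.
#' @export
normalize_psd <- function(spec, scheme = band_scheme()) {
  stopifnot(inherits(spec, "spectrogram"))
  rng <- scheme$analysis_range
  in_range <- spec$freqs > rng[1] & spec$freqs <= rng[2]
  p <- spec$power
  p[, !in_range] <- 0
  totals <- rowSums(p[, in_range, drop = FALSE])
  degenerate <- which(totals <= 0)
  scale <- ifelse(totals > 0, totals, 1)
  p <- p / scale
  p[degenerate, ] <- 0
  out <- spec
  out$power <- p
  attr(out, "relative") <- TRUE
  attr(out, "degenerate_windows") <- degenerate
  out
}

band_bins <- function(freqs, band) freqs > band[1] & freqs <= band[2]

#' Relative power in a frequency band
#'
#' Sums a normalized window's relative PSD over the bins belonging to a
#' band under the half-open convention `low < f <= high` (with 1 Hz bins,
#' band (0.5, 2] sums bins 1 and 2 Hz).
#'
#' @param relative_window Numeric vector of relative PSD values for one
#'   window.
#' @param freqs Bin centre frequencies (Hz), parallel to
#'   `relative_window`.
#' @param band Numeric `c(low, high)` in Hz.
#' @param scheme Scheme supplying the admissible analysis range.
#' @return Scalar band fraction in `[0, 1]`.
#' @export
band_fraction <- function(relative_window, freqs, band, scheme = band_scheme()) {
  if (band[1] < scheme$analysis_range[1] || band[2] > scheme$analysis_range[2])
    abort("band lies outside the analysis range")
  sum(relative_window[band_bins(freqs, band)])
}

# n_windows x n_bands matrix of band fractions for a relative spectrogram
band_fraction_matrix <- function(spec_rel, scheme) {
  vapply(scheme$bands,
         function(b) rowSums(spec_rel$power[, band_bins(spec_rel$freqs, b), drop = FALSE]),
         numeric(nrow(spec_rel$power)))
}

# max / mean-excluding-argmax / mean summaries of a band's window series;
# argmax ties break to the lowest window index
series_max <- function(v) v[which.max(v)]
series_mean_rest <- function(v) mean(v[-which.max(v)])

#' Eight spectral features of one epoch channel
#'
#' The per-channel feature vector: mean relative power over the 59 STFT
#' windows in the low delta, theta, alpha and beta bands; for the delta
#' band the maximum over windows (`K_comp_1`, sensitive to a K-complex
#' transient concentrated in one window) and the mean of the remaining 58
#' windows (`K_comp_2`); the same max/mean-of-rest pair on the sigma band
#' (`spindle_1`, `spindle_2`) targeting sleep spindles.
#'
#' @param x One channel of one epoch (`fs * 30` samples).
#' @param fs Sampling rate in Hz.
#' @param scheme A [band_scheme()].
#' @return Named numeric vector of length 8, all values in `[0, 1]`, with
#'   attribute `degenerate_windows`.  An all-zero epoch is an error: its
#'   relative PSD is undefined.
#' @export
extract_channel_features <- function(x, fs, scheme = band_scheme()) {
  spec <- compute_spectrogram(x, fs)
  rel <- normalize_psd(spec, scheme)
  degen <- attr(rel, "degenerate_windows")
  if (length(degen) == nrow(rel$power))
    abort("all-zero epoch: relative PSD undefined in every window")
  bf <- band_fraction_matrix(rel, scheme)
  out <- features_from_band_fractions(bf)
  attr(out, "degenerate_windows") <- degen
  out
}

features_from_band_fractions <- function(bf) {
  c(
    low_delta = mean(bf[, "low_delta"]),
    K_comp_1  = series_max(bf[, "delta"]),
    K_comp_2  = series_mean_rest(bf[, "delta"]),
    theta     = mean(bf[, "theta"]),
    alpha     = mean(bf[, "alpha"]),
    spindle_1 = series_max(bf[, "sigma"]),
    spindle_2 = series_mean_rest(bf[, "sigma"]),
    beta      = mean(bf[, "beta"])
  )
}

#' The 48-dimensional feature vector of a six-channel epoch
#'
#' Applies [extract_channel_features()] to each of the six channels in
#' canonical order (F3, F4, C3, C4, O1, O2) and concatenates
#' channel-major.
#'
#' @param block `6 x fs*30` numeric matrix, rows in canonical channel
#'   order.
#' @param fs Sampling rate in Hz.
#' @param scheme A [band_scheme()].
#' @return Named numeric vector of length 48 (names as
#'   [feature_names()]).
#' @export
extract_epoch_features <- function(block, fs, scheme = band_scheme()) {
  block <- as.matrix(block)
  n_ch <- length(eeg_channels())
  if (nrow(block) != n_ch)
    abort(sprintf("expected %d channels, got %d", n_ch, nrow(block)))
  # all channels' windows share one FFT call; identical numerics to the
  # per-channel path
  n <- ncol(block)
  if (n != fs * 30) abort(sprintf("epoch has %d samples but fs * 30 = %g", n, fs * 30))
  win <- as.integer(fs); hop <- win %/% 2L
  n_windows <- (n - win) %/% hop + 1L
  starts <- (seq_len(n_windows) - 1L) * hop
  taper <- hann_window(win)
  idx <- outer(seq_len(win), starts, "+")
  seg <- matrix(0, win, n_windows * n_ch)
  for (c in seq_len(n_ch))
    seg[, ((c - 1L) * n_windows + 1L):(c * n_windows)] <- matrix(block[c, ][idx], win) * taper
  ft <- stats::mvfft(seg)
  n_bins <- win %/% 2L + 1L
  freqs <- (seq_len(n_bins) - 1L) * fs / win
  pw <- Mod(ft[seq_len(n_bins), , drop = FALSE])^2
  vals <- unlist(lapply(seq_len(n_ch), function(c) {
    spec <- structure(
      list(power = t(pw[, ((c - 1L) * n_windows + 1L):(c * n_windows), drop = FALSE]),
           freqs = freqs, window_seconds = 1, overlap = 0.5),
      class = "spectrogram")
    rel <- normalize_psd(spec, scheme)
    if (length(attr(rel, "degenerate_windows")) == n_windows)
      abort("all-zero epoch: relative PSD undefined in every window")
    features_from_band_fractions(band_fraction_matrix(rel, scheme))
  }), use.names = FALSE)
  setNames(vals, feature_names())
}

#' Featurize a subject's segmented epochs
#'
#' Runs [extract_epoch_features()] over every row of a
#' [segment_epochs()] table, yielding the per-epoch feature matrix with
#' its stage labels: the training unit of the staging models.
#'
#' @param epochs Tibble from [segment_epochs()] (columns `epoch`,
#'   `stage`, `block`).
#' @param fs Sampling rate in Hz.
#' @param scheme A [band_scheme()].
#' @param subject_id Optional subject id column value.
#' @return A tibble: `subject_id`, `epoch`, `stage`, then the 48 named
#'   feature columns.
#' @export
featurize_subject <- function(epochs, fs, scheme = band_scheme(),
                              subject_id = "subject") {
  if (nrow(epochs) < 1) abort("no epochs to featurize")
  feats <- t(vapply(epochs$block, extract_epoch_features, numeric(48),
                    fs = fs, scheme = scheme))
  dplyr::bind_cols(
    tibble::tibble(subject_id = subject_id, epoch = epochs$epoch,
                   stage = epochs$stage),
    tibble::as_tibble(feats)
  )
}

#' Read/write a feature matrix CSV
#'
#' Dialect: `subject_id,epoch,stage,<48 named feature columns>` with the
#' names of [feature_names()].
#'
#' @param features Feature tibble as from [featurize_subject()].
#' @param path CSV path.
#' @return `read_features()` the tibble; `write_features()` `path`,
#'   invisibly.
#' @export
write_features <- function(features, path) {
  df <- features
  df$stage <- as.character(df$stage)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(feature_names(), names(df))
  if (length(missing) > 0)
    abort(sprintf("feature CSV lacks column(s): %s",
                  paste(head(missing, 3), collapse = ", ")))
  df$stage <- factor(df$stage, levels = sleep_stages())
  tibble::as_tibble(df)
}
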