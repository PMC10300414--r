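# direct-from-definition DFT oracle; shares only the documented Hann
# taper with the implementation
oracle_spectrogram <- function(x, fs) {
  win <- fs; hop <- fs / 2
  n_windows <- (length(x) - win) / hop + 1
  taper <- 0.5 * (1 - cos(2 * pi * (0:(win - 1)) / win))
  ks <- 0:(win / 2)
  basis <- exp(-2i * pi * outer(0:(win - 1), ks) / win)
  t(vapply(seq_len(n_windows), function(w) {
    seg <- x[((w - 1) * hop + 1):((w - 1) * hop + win)] * taper
    Mod(colSums(seg * basis))^2
  }, numeric(length(ks))))
}
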