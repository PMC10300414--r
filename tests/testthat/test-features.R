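test_that("spectrogram has 59 one-second windows and 1 Hz bins for a 30-s epoch", {
  x <- rnorm(6000)
  sp <- compute_spectrogram(x, 200)
  expect_equal(dim(sp$power), c(59, 101))
  expect_equal(sp$freqs, 0:100)
  expect_true(all(sp$power >= 0))
  expect_error(compute_spectrogram(x[-1], 200), "samples")
  expect_identical(compute_spectrogram(numeric(6000), 200)$power,
                   matrix(0, 59, 101))
})

test_that("spectrogram power matches the DFT definition on random epochs", {
  set.seed(11)
  for (i in 1:20) {
    x <- as.numeric(simulate_epoch(sample(sleep_stages(), 1), seed = 100 + i)[1, ])
    got <- compute_spectrogram(x, 200)$power
    want <- oracle_spectrogram(x, 200)
    keep <- want > max(want) * 1e-8
    expect_lt(max(abs(got[keep] - want[keep]) / want[keep]), 1e-9)
  }
  # pure tone: the 10 Hz bin in particular
  t <- (0:5999) / 200
  x <- sin(2 * pi * 10 * t)
  got <- compute_spectrogram(x, 200)$power
  want <- oracle_spectrogram(x, 200)
  expect_lt(max(abs(got[, 11] - want[, 11]) / want[, 11]), 1e-9)
})

test_that("relative PSD sums to one in-range and zeroes out-of-range bins", {
  set.seed(12)
  sp <- compute_spectrogram(rnorm(6000), 200)
  rel <- normalize_psd(sp)
  in_range <- rel$freqs > 0.5 & rel$freqs <= 50
  expect_equal(rowSums(rel$power[, in_range]), rep(1, 59), tolerance = 1e-12)
  expect_true(all(rel$power[, !in_range] == 0))
  expect_length(attr(rel, "degenerate_windows"), 0)

  # a window with power in exactly one in-range bin gets relative value 1
  fake <- sp
  fake$power[] <- 0
  fake$power[3, 11] <- 42
  rel2 <- normalize_psd(fake)
  expect_equal(rel2$power[3, 11], 1)
  expect_equal(length(attr(rel2, "degenerate_windows")), 58)
  expect_true(all(rel2$power[-3, ] == 0))
})

test_that("band fractions follow the half-open upper-inclusive bin convention", {
  freqs <- 0:100
  uniform <- rep(0, 101)
  uniform[freqs > 0.5 & freqs <= 50] <- 1 / 50
  expect_equal(band_fraction(uniform, freqs, c(0.5, 2)), 2 / 50)
  expect_equal(band_fraction(uniform, freqs, c(15, 30)), 15 / 50)
  expect_equal(band_fraction(uniform, freqs, c(1, 4)), 3 / 50)
  # delta (1,4] and theta (4,8] use disjoint bins {2,3,4} and {5,...,8}
  w <- rep(0, 101); w[5] <- 1   # the 4 Hz bin
  expect_equal(band_fraction(w, freqs, c(1, 4)), 1)
  expect_equal(band_fraction(w, freqs, c(4, 8)), 0)
  expect_error(band_fraction(uniform, freqs, c(40, 60)), "analysis range")
})

test_that("K-complex and spindle operators are max and mean-of-remaining-58", {
  set.seed(13)
  x <- as.numeric(simulate_epoch("N2", seed = 13)[1, ])
  rel <- normalize_psd(compute_spectrogram(x, 200))
  sch <- band_scheme()
  delta <- vapply(seq_len(59), function(w)
    band_fraction(rel$power[w, ], rel$freqs, sch$bands$delta), numeric(1))
  sigma <- vapply(seq_len(59), function(w)
    band_fraction(rel$power[w, ], rel$freqs, sch$bands$sigma), numeric(1))
  f <- extract_channel_features(x, 200)
  expect_equal(f[["K_comp_1"]], max(delta))
  rest <- delta[-which.max(delta)]
  expect_length(rest, 58)
  expect_equal(f[["K_comp_2"]], mean(rest))
  expect_equal(f[["spindle_1"]], max(sigma))
  expect_equal(f[["spindle_2"]], mean(sigma[-which.max(sigma)]))
  expect_equal(f[["theta"]], mean(vapply(seq_len(59), function(w)
    band_fraction(rel$power[w, ], rel$freqs, sch$bands$theta), numeric(1))))
})

test_that("a constant band series makes the max equal the mean of the rest", {
  # pure stationary tone in the delta band: every window has (almost)
  # identical delta fraction
  t <- (0:5999) / 200
  x <- sin(2 * pi * 3 * t)
  f <- extract_channel_features(x, 200)
  expect_equal(f[["K_comp_1"]], f[["K_comp_2"]], tolerance = 1e-6)
})

test_that("epoch features are 48-long, channel-major, and equivariant", {
  blk <- simulate_epoch("N2", seed = 21)
  f <- extract_epoch_features(blk, 200)
  expect_length(f, 48)
  expect_identical(names(f), feature_names())
  expect_true(all(f >= 0 & f <= 1))

  # identical channels give identical blocks of 8
  rep_blk <- blk[rep(1, 6), ]
  fr <- extract_epoch_features(rep_blk, 200)
  m <- matrix(fr, nrow = 8)
  for (c in 2:6) expect_equal(m[, c], m[, 1])

  # permuting channels permutes the feature blocks and nothing else
  perm <- c(3, 1, 2, 6, 4, 5)
  fp <- extract_epoch_features(blk[perm, ], 200)
  expect_equal(matrix(fp, nrow = 8), matrix(f, nrow = 8)[, perm],
               ignore_attr = TRUE)

  expect_error(extract_epoch_features(blk[1:5, ], 200), "channels")
  expect_error(extract_epoch_features(matrix(0, 6, 6000), 200), "all-zero")
})

test_that("features are invariant to signal amplitude", {
  set.seed(22)
  blk <- simulate_epoch("R", seed = 22)
  f1 <- extract_epoch_features(blk, 200)
  for (scale in c(1e-3, 7.3, 1e4)) {
    f2 <- extract_epoch_features(blk * scale, 200)
    expect_equal(unname(f2), unname(f1), tolerance = 1e-9)
  }
})

test_that("featurize_subject stacks per-epoch vectors with labels intact", {
  rec <- bandpass(eeg_recording(
    do.call(cbind, lapply(1:10, function(i) simulate_epoch("N1", seed = i))),
    200, eeg_channels(), "s1"))
  hyp <- hypnogram(rep(c("N1", "N2"), 5))
  ep <- segment_epochs(rec, hyp)
  ft <- featurize_subject(ep, 200, subject_id = "s1")
  expect_equal(nrow(ft), 10)
  expect_identical(as.character(ft$stage), as.character(hyp$stage))
  row3 <- unlist(ft[3, feature_names()])
  expect_equal(unname(row3),
               unname(extract_epoch_features(ep$block[[3]], 200)))
  expect_error(featurize_subject(ep[0, ], 200), "no epochs")

  path <- file.path(withr::local_tempdir(), "features.csv")
  write_features(ft, path)
  back <- read_features(path)
  expect_equal(back[[feature_names()[1]]], ft[[feature_names()[1]]])
  expect_identical(as.character(back$stage), as.character(ft$stage))
})
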