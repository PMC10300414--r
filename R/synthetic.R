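#' Stage templates for the synthetic EEG generator
#'
#' Each sleep stage is described by target relative band powers over
#' five disjoint generator bands -- low frequency (0.5-4 Hz), theta
#' (4-8), alpha (8-12), sigma (12-15), beta (15-30 Hz) -- plus transient
#' event statistics: K-complex and spindle rates (events per 30-s epoch;
#' the N2 default of 0.5/epoch encodes "roughly one every two epochs"),
#' event durations drawn uniformly from 0.5-1.5 s, and amplitude
#' multipliers relative to the background standard deviation.
#'
#' The templates emulate the AASM stage descriptions (alpha-dominant
#' wake, theta-dominant N1, K-complex/spindle N2, slow-wave N3, mixed
#' REM).  They are generator defaults, not claims about real EEG.
#'
#' @return Named list (one entry per stage) of template lists with
#'   elements `band_powers`, `k_rate`, `spindle_rate`, `k_amp`,
#'   `spindle_amp`, `event_duration`.
#' @export
stage_templates <- function() {
  tpl <- function(low, theta, alpha, sigma, beta, k_rate = 0, spindle_rate = 0) {
    list(band_powers = c(low = low, theta = theta, alpha = alpha,
                         sigma = sigma, beta = beta),
         k_rate = k_rate, spindle_rate = spindle_rate,
         k_amp = 4, spindle_amp = 3, event_duration = c(0.5, 1.5))
  }
  list(
    W  = tpl(0.12, 0.13, 0.50, 0.05, 0.20),
    N1 = tpl(0.22, 0.48, 0.10, 0.05, 0.15),
    # N2 background carries < 20% slow-wave activity (that is what
    # separates it from N3); its delta signature comes from K-complexes
    N2 = tpl(0.22, 0.30, 0.08, 0.17, 0.18, k_rate = 0.5, spindle_rate = 0.5),
    N3 = tpl(0.72, 0.13, 0.04, 0.04, 0.07, k_rate = 0.2),
    R  = tpl(0.18, 0.32, 0.12, 0.06, 0.32)
  )
}

generator_bands <- function() {
  list(low = c(0.5, 4), theta = c(4, 8), alpha = c(8, 12),
       sigma = c(12, 15), beta = c(15, 30))
}

#' Severity-dependent effect multipliers of the generator
#'
#' Multiplicative shifts applied to a subject's stage templates by
#' OSA class, encoding the reported qualitative directions: K-complex
#' amplitude and rate decrease with severity, slow-wave background
#' power decreases (fragmented sleep carries less slow-wave activity,
#' pulling the secondary delta means down too), and beta (and mildly
#' sigma) background power increases.  All multipliers are positive;
#' healthy is the identity.
#'
#' @return Named list (healthy, mtom, severe) of multiplier lists.
#' @export
osa_effects <- function() {
  eff <- function(k_amp, k_rate, low, beta, sigma) {
    list(k_amp = k_amp, k_rate = k_rate, low = low, beta = beta, sigma = sigma)
  }
  list(healthy = eff(1, 1, 1, 1, 1),
       mtom    = eff(0.80, 0.80, 0.90, 1.25, 1.10),
       severe  = eff(0.55, 0.55, 0.75, 1.60, 1.25))
}

#' Default stage-transition matrix
#'
#' First-order Markov dynamics over (W, N1, N2, N3, R) with strong
#' self-transition, giving a plausible hypnogram texture and non-trivial
#' occupancy of every stage.
#'
#' @return 5x5 row-stochastic matrix with stage dimnames.
#' @export
default_transitions <- function() {
  lv <- sleep_stages()
  m <- rbind(
    c(0.60, 0.30, 0.05, 0.00, 0.05),
    c(0.10, 0.40, 0.40, 0.02, 0.08),
    c(0.03, 0.05, 0.70, 0.12, 0.10),
    c(0.01, 0.02, 0.25, 0.65, 0.07),
    c(0.05, 0.08, 0.12, 0.00, 0.75))
  dimnames(m) <- list(lv, lv)
  m
}

#' Simulate a hypnogram as a first-order Markov chain
#'
#' @param n_epochs Number of 30-s epochs.
#' @param transition_matrix 5x5 row-stochastic matrix over the canonical
#'   stage order (rows must sum to 1 within 1e-9).
#' @param initial_stage Starting stage (default `"W"`).
#' @param seed Optional integer seed; when `NULL` the current RNG stream
#'   is used.
#' @param subject_id Subject id for the returned [hypnogram()].
#' @return A [hypnogram()] of length `n_epochs`.
#' @export
simulate_hypnogram <- function(n_epochs, transition_matrix = default_transitions(),
                               initial_stage = "W", seed = NULL,
                               subject_id = "subject") {
  lv <- sleep_stages()
  stopifnot(is.matrix(transition_matrix), all(dim(transition_matrix) == 5))
  if (any(abs(rowSums(transition_matrix) - 1) > 1e-9))
    abort("transition matrix rows must sum to 1")
  if (any(transition_matrix < 0)) abort("transition probabilities must be nonnegative")
  if (!initial_stage %in% lv) abort("unknown initial stage")
  if (!is.null(seed)) set.seed(seed)
  stages <- character(n_epochs)
  cur <- initial_stage
  for (i in seq_len(n_epochs)) {
    stages[i] <- cur
    cur <- sample(lv, 1, prob = transition_matrix[cur, ])
  }
  hypnogram(stages, subject_id = subject_id)
}

# real-valued noise with the requested relative power per generator band,
# synthesized in the frequency domain (one inverse FFT); unit total
# variance up to realization noise
colored_noise <- function(n, fs, band_powers, bands = generator_bands()) {
  amp <- numeric(n)
  freqs <- (0:(n - 1)) * fs / n
  half <- 2:(n %/% 2)  # skip DC and (for even n) Nyquist
  for (b in names(bands)) {
    if (!b %in% names(band_powers) || band_powers[[b]] <= 0) next
    sel <- half[freqs[half] > bands[[b]][1] & freqs[half] <= bands[[b]][2]]
    if (length(sel)) amp[sel] <- sqrt(band_powers[[b]] / length(sel))
  }
  z <- complex(real = rnorm(n), imaginary = rnorm(n)) * amp
  z[(n %/% 2 + 2):n] <- Conj(z[seq(n %/% 2, 2)])
  z[1] <- 0; z[n %/% 2 + 1] <- 0
  # scaled so the total variance equals sum(band_powers); transient
  # amplitudes are thus expressed in background-SD units
  Re(fft(z, inverse = TRUE)) / 2
}

# windowed biphasic slow transient (K-complex surrogate); the 2 Hz
# carrier puts its energy squarely inside the delta band (1-4 Hz) that
# the max operator scores
k_complex_wave <- function(duration, fs, amplitude) {
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  amplitude * hann_window(n) * sin(2 * pi * 2 * t)
}

# Hann-enveloped sigma-band burst (sleep spindle surrogate)
spindle_wave <- function(duration, fs, amplitude, freq = 13.5) {
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  amplitude * hann_window(n) * sin(2 * pi * freq * t)
}

add_events <- function(x, fs, rate, wave_fn, duration_range, amplitude) {
  if (rate <= 0 || amplitude <= 0) return(x)
  n_events <- stats::rpois(1, rate)
  for (e in seq_len(n_events)) {
    d <- runif(1, duration_range[1], duration_range[2])
    w <- wave_fn(d, fs, amplitude)
    start <- sample.int(length(x) - length(w) + 1L, 1)
    x[start:(start + length(w) - 1L)] <- x[start:(start + length(w) - 1L)] + w
  }
  x
}

#' Simulate one six-channel 30-s epoch of a given stage
#'
#' Background activity is band-limited Gaussian noise mixed to the
#' stage's relative band-power targets; the six channels share 80% of
#' their variance (a common stage process) with 20% independent
#' per-channel noise.  For stages configured with events, K-complex
#' and/or spindle transients of 0.5-1.5 s are superimposed on the shared
#' component at random positions.
#'
#' @param stage Stage label.
#' @param template Stage template (default from [stage_templates()]).
#' @param fs Sampling rate in Hz.
#' @param epoch_seconds Epoch duration.
#' @param channel_share Fraction of variance shared across channels.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return `6 x fs*epoch_seconds` numeric matrix (canonical channel
#'   order).
#' @export
simulate_epoch <- function(stage, template = stage_templates()[[stage]],
                           fs = 200, epoch_seconds = 30,
                           channel_share = 0.8, seed = NULL) {
  if (!stage %in% sleep_stages()) abort("unknown stage")
  if (!is.null(seed)) set.seed(seed)
  n <- fs * epoch_seconds
  shared <- colored_noise(n, fs, template$band_powers)
  shared <- add_events(shared, fs, template$k_rate, k_complex_wave,
                       template$event_duration, template$k_amp)
  shared <- add_events(shared, fs, template$spindle_rate, spindle_wave,
                       template$event_duration, template$spindle_amp)
  block <- matrix(0, length(eeg_channels()), n)
  for (c in seq_len(nrow(block))) {
    indep <- colored_noise(n, fs, template$band_powers)
    block[c, ] <- sqrt(channel_share) * shared + sqrt(1 - channel_share) * indep
  }
  rownames(block) <- eeg_channels()
  block
}

#' Cohort specification for the synthetic generator
#'
#' Bundles every knob of the simulated study: cell sizes over age group
#' x OSA class, epochs per subject, the stage-transition matrix, the
#' stage templates, the severity effect multipliers, per-subject
#' variability, and the oximetry distribution parameters by group cell
#' (means/SDs follow the clinical demographics table; saturation is
#' truncated to (0, 100]).
#'
#' @param n_per_cell Subjects per (age_group x osa_class) cell; a scalar
#'   or a named numeric with names like `"younger.healthy"`.
#' @param epochs_per_subject Epochs simulated per subject.
#' @param transitions Stage-transition matrix.
#' @param templates Stage templates.
#' @param effects Severity multipliers ([osa_effects()]).
#' @param subject_sd SD of the per-subject log-normal jitter applied to
#'   band powers and event amplitudes (inter-individual variability).
#' @param spo2_params Data frame of `age_group`, `osa_class`, `mean`,
#'   `sd` for the oximetry scalar.
#' @param fs Sampling rate.
#' @param seed Master seed; every subject's seed derives from it.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_cell = 5, epochs_per_subject = 120,
                        transitions = default_transitions(),
                        templates = stage_templates(),
                        effects = osa_effects(),
                        subject_sd = 0.15,
                        spo2_params = default_spo2_params(),
                        fs = 200, seed = 0L) {
  for (tpl in templates) {
    if (any(tpl$band_powers < 0) || sum(tpl$band_powers) > 1 + 1e-9)
      abort("template band powers must be nonnegative and sum to at most 1")
  }
  if (any(unlist(effects) <= 0)) abort("effect multipliers must be positive")
  structure(list(n_per_cell = n_per_cell,
                 epochs_per_subject = epochs_per_subject,
                 transitions = transitions, templates = templates,
                 effects = effects, subject_sd = subject_sd,
                 spo2_params = spo2_params, fs = fs, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_spo2_params <- function() {
  tibble::tribble(
    ~age_group, ~osa_class, ~mean, ~sd,
    "younger", "healthy", 89.40, 8.07,
    "younger", "mtom",    82.92, 4.39,
    "younger", "severe",  73.40, 10.95,
    "older",   "healthy", 88.40, 6.41,
    "older",   "mtom",    83.70, 5.84,
    "older",   "severe",  74.92, 7.90
  )
}

# apply class multipliers and per-subject jitter to the stage templates
subject_templates <- function(spec, osa_class, jitter) {
  eff <- spec$effects[[osa_class]]
  if (is.null(eff)) abort(sprintf("no effect entry for class '%s'", osa_class))
  lapply(spec$templates, function(tpl) {
    bp <- tpl$band_powers * jitter$band
    bp[["low"]] <- bp[["low"]] * eff$low
    bp[["beta"]] <- bp[["beta"]] * eff$beta
    bp[["sigma"]] <- bp[["sigma"]] * eff$sigma
    tpl$band_powers <- bp
    tpl$k_amp <- tpl$k_amp * eff$k_amp * jitter$k_amp
    tpl$k_rate <- tpl$k_rate * eff$k_rate
    tpl$spindle_amp <- tpl$spindle_amp * jitter$spindle_amp
    tpl
  })
}

rtruncnorm_spo2 <- function(mean, sd) {
  for (i in 1:1000) {
    v <- rnorm(1, mean, sd)
    if (v > 0 && v <= 100) return(v)
  }
  min(100, max(mean, 1))
}

#' Simulate one subject's night
#'
#' Draws the hypnogram from the Markov model, synthesizes each epoch
#' from the subject's severity- and jitter-adjusted stage templates,
#' concatenates them into a continuous recording, and draws the oximetry
#' scalar from the subject's group cell (truncated to (0, 100]).
#'
#' @param meta List or one-row data frame with `subject_id`,
#'   `age_group`, `osa_class`.
#' @param spec A [cohort_spec()].
#' @param seed Integer seed for this subject.
#' @return List with elements `recording` ([eeg_recording()]),
#'   `hypnogram` ([hypnogram()]) and `spo2` (scalar).
#' @export
simulate_subject <- function(meta, spec = cohort_spec(), seed = 0L) {
  set.seed(seed)
  jitter <- list(band = exp(rnorm(5, 0, spec$subject_sd)) |>
                   setNames(names(generator_bands())),
                 k_amp = exp(rnorm(1, 0, spec$subject_sd)),
                 spindle_amp = exp(rnorm(1, 0, spec$subject_sd)))
  tpls <- subject_templates(spec, meta$osa_class, jitter)
  hyp <- simulate_hypnogram(spec$epochs_per_subject, spec$transitions,
                            subject_id = meta$subject_id)
  blocks <- lapply(seq_len(nrow(hyp)), function(i) {
    st <- as.character(hyp$stage[i])
    simulate_epoch(st, tpls[[st]], spec$fs)
  })
  signals <- do.call(cbind, blocks)
  sp <- spec$spo2_params
  row <- sp[sp$age_group == meta$age_group & sp$osa_class == meta$osa_class, ]
  spo2 <- if (nrow(row) == 1) rtruncnorm_spo2(row$mean, row$sd) else NA_real_
  list(recording = eeg_recording(signals, spec$fs, eeg_channels(), meta$subject_id),
       hypnogram = hyp, spo2 = spo2)
}

#' Simulate a full cohort
#'
#' Generates every subject of the specification (balanced over the six
#' age x severity cells unless per-cell counts are given), with each
#' subject's seed derived deterministically from the master seed, and
#' optionally writes recordings (sidecar format), hypnogram CSVs and the
#' metadata CSV to a directory.
#'
#' @param spec A [cohort_spec()].
#' @param dir Optional output directory; created if missing.
#' @return List of class `cohort`: `recordings` (named list),
#'   `hypnograms` (named list), `spo2` (named numeric), `meta` (tibble).
#' @export
simulate_cohort <- function(spec = cohort_spec(), dir = NULL) {
  cells <- expand.grid(age_group = c("younger", "older"),
                       osa_class = c("healthy", "mtom", "severe"),
                       stringsAsFactors = FALSE)
  meta_rows <- list()
  for (i in seq_len(nrow(cells))) {
    key <- paste(cells$age_group[i], cells$osa_class[i], sep = ".")
    n <- if (length(spec$n_per_cell) == 1) spec$n_per_cell
         else spec$n_per_cell[[key]] %||% 0
    for (j in seq_len(n)) {
      meta_rows[[length(meta_rows) + 1]] <- tibble::tibble(
        subject_id = sprintf("S%s_%s_%02d",
                             substr(cells$age_group[i], 1, 1),
                             substr(cells$osa_class[i], 1, 2), j),
        age_group = cells$age_group[i], osa_class = cells$osa_class[i])
    }
  }
  meta <- dplyr::bind_rows(meta_rows)
  recordings <- list(); hypnograms <- list(); spo2 <- numeric(0)
  for (i in seq_len(nrow(meta))) {
    sub <- simulate_subject(meta[i, ], spec, seed = spec$seed + 7919L * i)
    recordings[[meta$subject_id[i]]] <- sub$recording
    hypnograms[[meta$subject_id[i]]] <- sub$hypnogram
    spo2[meta$subject_id[i]] <- sub$spo2
  }
  meta$spo2 <- unname(spo2[meta$subject_id])
  out <- structure(list(recordings = recordings, hypnograms = hypnograms,
                        spo2 = spo2, meta = meta, spec = spec),
                   class = "cohort")
  if (!is.null(dir)) write_cohort(out, dir)
  out
}

#' @rdname simulate_cohort
#' @param cohort A `cohort` object.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in names(cohort$recordings)) {
    write_recording(cohort$recordings[[sid]], file.path(dir, paste0(sid, ".eeg.json")))
    write_hypnogram(cohort$hypnograms[[sid]], file.path(dir, paste0(sid, "_hypnogram.csv")))
  }
  write_metadata(cohort$meta, file.path(dir, "metadata.csv"))
  invisible(dir)
}

#' Extract per-epoch features for every subject of a cohort
#'
#' Convenience wrapper chaining preprocessing ([bandpass()]),
#' segmentation and [featurize_subject()] over the cohort.
#'
#' @param cohort A [simulate_cohort()] result (or a compatible list).
#' @param filter Apply the 0.5-50 Hz bandpass first (default TRUE).
#' @return A feature tibble over all subjects and epochs.
#' @export
featurize_cohort <- function(cohort, filter = TRUE) {
  purrr::map_dfr(names(cohort$recordings), function(sid) {
    rec <- cohort$recordings[[sid]]
    if (filter) rec <- bandpass(rec)
    epochs <- segment_epochs(rec, cohort$hypnograms[[sid]])
    featurize_subject(epochs, rec$fs, subject_id = sid)
  })
}
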