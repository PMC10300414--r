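# Shared, lazily built fixtures.  The two cohort experiments are costly
# (minutes), so every test that needs them draws from this cache instead
# of re-simulating.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# 30-subject staging cohort (5 per age x severity cell, 200 epochs each,
# master seed 0) with a stratified one-subject-per-cell holdout
staging_fixture <- function() {
  fixture("staging", function() {
    spec <- cohort_spec(n_per_cell = 5, epochs_per_subject = 200, seed = 0)
    cohort <- simulate_cohort(spec)
    feats <- featurize_cohort(cohort)
    set.seed(0)
    strata <- paste(cohort$meta$age_group, cohort$meta$osa_class)
    holdout <- unlist(lapply(unique(strata), function(s)
      sample(cohort$meta$subject_id[strata == s], 1)))
    cohort$recordings <- NULL  # featurized; free ~350 MB
    gc()
    list(cohort = cohort, feats = feats, holdout = holdout,
         train = feats[!feats$subject_id %in% holdout, ],
         test = feats[feats$subject_id %in% holdout, ])
  })
}

staging_model_fixture <- function(algorithm) {
  fixture(paste0("staging_model_", algorithm), function() {
    fit_staging_model(staging_fixture()$train, algorithm, seed = 0)
  })
}

# healthy-vs-severe screening cohort: 60 subjects per class (30 per age
# cell), 40 epochs per subject, seed 0; 20 subjects held out
osa_fixture <- function() {
  fixture("osa", function() {
    spec <- cohort_spec(
      n_per_cell = c(younger.healthy = 30, older.healthy = 30,
                     younger.severe = 30, older.severe = 30,
                     younger.mtom = 0, older.mtom = 0),
      epochs_per_subject = 40, seed = 0)
    cohort <- simulate_cohort(spec)
    feats <- featurize_cohort(cohort)
    profiles <- purrr::map_dfr(cohort$meta$subject_id, function(sid)
      aggregate_profile(feats[feats$subject_id == sid, ],
                        meta = cohort$meta[cohort$meta$subject_id == sid, ]))
    set.seed(1)
    holdout <- c(sample(cohort$meta$subject_id[cohort$meta$osa_class == "healthy"], 10),
                 sample(cohort$meta$subject_id[cohort$meta$osa_class == "severe"], 10))
    # only the held-out recordings are needed again (integrated screening)
    cohort$recordings <- cohort$recordings[holdout]
    gc()
    list(cohort = cohort, feats = feats, profiles = profiles, holdout = holdout)
  })
}

# small epoch-level feature table with clearly separated stage classes,
# cheap enough for structural CV checks
toy_features <- function(n_per_stage = 20, sd = 0.05, seed = 42) {
  set.seed(seed)
  centers <- seq_along(sleep_stages())
  purrr::map_dfr(seq_along(sleep_stages()), function(i) {
    tibble::tibble(
      subject_id = sprintf("T%02d", rep(1:4, length.out = n_per_stage)),
      epoch = seq_len(n_per_stage) - 1L,
      stage = factor(sleep_stages()[i], levels = sleep_stages()),
      f1 = rnorm(n_per_stage, centers[i], sd),
      f2 = rnorm(n_per_stage, -centers[i], sd))
  })
}

tiny_knn_grid <- list(list(n_neighbors = 3, weights = "uniform", metric = "euclidean"))

# one deterministic sinusoidal recording for io tests
sine_recording <- function(freq = 10, fs = 200, seconds = 60, amp = 1,
                           subject_id = "sine") {
  t <- (seq_len(fs * seconds) - 1) / fs
  x <- amp * sin(2 * pi * freq * t)
  eeg_recording(matrix(rep(x, 6), nrow = 6, byrow = TRUE),
                fs, eeg_channels(), subject_id)
}
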