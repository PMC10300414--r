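fake_feats <- function(stages, values, subject_id = "s1") {
  n <- length(stages)
  fn <- feature_names()
  m <- matrix(rep(values, each = length(fn)), nrow = n, byrow = TRUE)
  colnames(m) <- fn
  dplyr::bind_cols(
    tibble::tibble(subject_id = subject_id, epoch = seq_len(n) - 1L,
                   stage = factor(stages, levels = sleep_stages())),
    tibble::as_tibble(m))
}

test_that("profiles average REM and pooled NREM epochs, excluding wake", {
  feats <- fake_feats(c("R", "R", "N1", "N2", "N3", "W"),
                      c(0.2, 0.4, 0.1, 0.2, 0.6, 0.99))
  p <- aggregate_profile(feats)
  expect_equal(p$rem.F3.low_delta, 0.3)
  expect_equal(p$nrem.O2.beta, 0.3)
  expect_equal(p$n_rem, 2)
  expect_equal(p$n_nrem, 3)

  # epoch order and wake insertion/removal do not matter
  shuffled <- feats[c(5, 6, 1, 3, 2, 4), ]
  no_wake <- feats[feats$stage != "W", ]
  expect_equal(aggregate_profile(shuffled)[, -(1:4)], p[, -(1:4)])
  expect_equal(aggregate_profile(no_wake)[, -(1:4)], p[, -(1:4)])

  # missing compartments flag as NA; all-wake errors
  rem_only <- fake_feats(c("R", "R"), c(0.2, 0.4))
  pr <- aggregate_profile(rem_only)
  expect_true(is.na(pr$nrem.F3.low_delta))
  expect_equal(pr$n_nrem, 0)
  expect_error(aggregate_profile(fake_feats("W", 0.5)), "no REM and no NREM")
})

test_that("profile tables have 96 feature columns (97 with oximetry)", {
  profiles <- purrr::map_dfr(1:10, function(i) {
    cls <- c("healthy", "mtom", "severe")[(i %% 3) + 1]
    aggregate_profile(
      fake_feats(c("R", "N2"), c(0.3, 0.5) + i / 100, sprintf("s%02d", i)),
      meta = list(subject_id = sprintf("s%02d", i), age_group = "younger",
                  osa_class = cls, spo2 = 80 + i))
  })
  t2 <- build_profile_table(profiles, c("healthy", "severe"))
  expect_equal(sum(grepl("^(rem|nrem)\\.", names(t2))), 96)
  expect_false("spo2" %in% names(t2))
  expect_false(any(t2$osa_class == "mtom"))
  t3 <- build_profile_table(profiles, c("healthy", "severe"), use_spo2 = TRUE)
  expect_equal(sum(grepl("^(rem|nrem)\\.|^spo2$", names(t3))), 97)
  t_all <- build_profile_table(profiles, c("healthy", "mtom", "severe"))
  expect_setequal(unique(t_all$osa_class), c("healthy", "mtom", "severe"))
  expect_error(build_profile_table(profiles, c("healthy", "osa")), "class_set")

  # subjects with a missing aggregate are dropped with a warning
  incomplete <- profiles
  incomplete[1, "rem.F3.low_delta"] <- NA
  expect_warning(td <- build_profile_table(incomplete, c("healthy", "mtom", "severe")),
                 "dropping")
  expect_equal(nrow(td), 9)
})

test_that("screening on a separable cohort is perfect and deterministic", {
  set.seed(41)
  profiles <- purrr::map_dfr(1:20, function(i) {
    cls <- if (i <= 10) "healthy" else "severe"
    base <- if (cls == "healthy") 0.3 else 0.6
    aggregate_profile(
      fake_feats(c("R", "N2"), base + rnorm(2, 0, 0.01), sprintf("s%02d", i)),
      meta = list(subject_id = sprintf("s%02d", i), age_group = "younger",
                  osa_class = cls, spo2 = NA))
  })
  table <- build_profile_table(profiles, c("healthy", "severe"))
  m1 <- fit_osa_model(table, "knn", seed = 2, grid = tiny_knn_grid)
  m2 <- fit_osa_model(table, "knn", seed = 2, grid = tiny_knn_grid)
  expect_identical(m1$hyperparams, m2$hyperparams)
  expect_equal(as.character(predict(m1, table)), table$osa_class)
})

test_that("integrated screening equals expert-stage screening under a perfect staging oracle", {
  osa <- osa_fixture()
  train_profiles <- osa$profiles[!osa$profiles$subject_id %in% osa$holdout, ]
  table <- build_profile_table(train_profiles, c("healthy", "severe"))
  osa_model <- fit_osa_model(table, "svm", seed = 0)
  sid <- osa$holdout[1]
  feats <- osa$feats[osa$feats$subject_id == sid, ]
  expert_hyp <- osa$cohort$hypnograms[[sid]]
  via_oracle <- sleepstager:::screen_from_features(osa_model, feats, expert_hyp, sid)
  expert_profile <- aggregate_profile(feats, meta = list(subject_id = sid,
                                                         age_group = NA,
                                                         osa_class = NA, spo2 = NA))
  direct <- as.character(predict(osa_model, expert_profile[, osa_model$feature_names]))
  expect_identical(via_oracle$predicted_class, direct)
})

test_that("an all-wake prediction is reported unscreenable, missing REM is imputed", {
  osa <- osa_fixture()
  train_profiles <- osa$profiles[!osa$profiles$subject_id %in% osa$holdout, ]
  table <- build_profile_table(train_profiles, c("healthy", "severe"))
  osa_model <- fit_osa_model(table, "knn", seed = 0, grid = tiny_knn_grid)

  feats <- fake_feats(rep("W", 4), rep(0.4, 4), "awake")
  res <- sleepstager:::screen_from_features(osa_model, feats,
                                            hypnogram(rep("W", 4)), "awake")
  expect_equal(res$outcome, "unscreenable")
  expect_true(is.na(res$predicted_class))

  nrem_only <- fake_feats(c("N1", "N2"), c(0.3, 0.4), "norem")
  expect_warning(
    res2 <- sleepstager:::screen_from_features(osa_model, nrem_only,
                                               hypnogram(c("N1", "N2")), "norem"),
    "imputing")
  expect_true(res2$outcome %in% c("healthy", "osa"))
})

test_that("NREM aggregates are stable under dropping 10% of epochs", {
  set.seed(47)
  n <- 100
  vals <- 0.3 + rnorm(n, 0, 0.03)
  feats <- fake_feats(rep("N2", n), vals, "stab")
  feats <- dplyr::bind_rows(feats, fake_feats(c("R", "R"), c(0.3, 0.35), "stab"))
  full <- aggregate_profile(feats)
  rng <- max(vals) - min(vals)
  for (i in 1:10) {
    drop <- sample(n, n / 10)
    sub <- feats[-drop, ]
    thinned <- aggregate_profile(sub)
    expect_lt(abs(thinned$nrem.F3.low_delta - full$nrem.F3.low_delta),
              0.1 * rng)
  }
})
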