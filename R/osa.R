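#' Aggregate per-epoch features into a subject profile
#'
#' Collapses one subject's per-epoch feature matrix into the
#' stage-conditioned averages used for apnea screening: the unweighted
#' mean feature vector over REM epochs and over pooled NREM epochs (N1,
#' N2 and N3 together, at the epoch level).  Wake epochs are excluded
#' entirely.  A missing sleep compartment (no REM or no NREM epochs)
#' yields `NA` for that aggregate and a flag; a subject with neither is
#' an error.
#'
#' @param feats Feature tibble for a single subject (`stage` + 48
#'   feature columns).
#' @param meta Optional one-row metadata (subject_id, age_group,
#'   osa_class, spo2) carried onto the profile.
#' @return A one-row tibble: `subject_id`, `age_group`, `osa_class`,
#'   `spo2`, `n_rem`, `n_nrem`, then `rem.<feature>` and
#'   `nrem.<feature>` columns.
#' @export
aggregate_profile <- function(feats, meta = NULL) {
  if ("subject_id" %in% names(feats) && length(unique(feats$subject_id)) > 1)
    abort("aggregate_profile expects epochs from a single subject")
  fcols <- feature_columns(feats)
  st <- as.character(feats$stage)
  rem_rows <- which(st == "R")
  nrem_rows <- which(st %in% c("N1", "N2", "N3"))
  if (length(rem_rows) == 0 && length(nrem_rows) == 0)
    abort("subject has no REM and no NREM epochs; nothing to aggregate")
  colmeans_or_na <- function(rows) {
    if (length(rows) == 0) return(rep(NA_real_, length(fcols)))
    colMeans(as.matrix(feats[rows, fcols, drop = FALSE]))
  }
  rem <- colmeans_or_na(rem_rows)
  nrem <- colmeans_or_na(nrem_rows)
  sid <- if (!is.null(meta)) meta$subject_id else unique(feats$subject_id)[1] %||% "subject"
  tibble::tibble(
    subject_id = as.character(sid),
    age_group = if (!is.null(meta)) meta$age_group else NA_character_,
    osa_class = if (!is.null(meta)) meta$osa_class else NA_character_,
    spo2 = if (!is.null(meta)) as.numeric(meta$spo2) else NA_real_,
    n_rem = length(rem_rows), n_nrem = length(nrem_rows),
    !!!setNames(as.list(rem), paste0("rem.", fcols)),
    !!!setNames(as.list(nrem), paste0("nrem.", fcols))
  )
}

#' Assemble the screening design matrix from subject profiles
#'
#' Restricts the profile table to the task's class set -- three-class
#' (healthy vs mild-to-moderate vs severe) or the binary healthy vs
#' severe screener, which deliberately excludes the intermediate
#' mild-to-moderate group from training -- and returns the 96 REM+NREM
#' feature columns (97 when the oximetry scalar is included).  Subjects
#' with a missing aggregate are dropped with a warning.
#'
#' @param profiles Tibble of stacked [aggregate_profile()] rows.
#' @param class_set Character vector of classes kept for training:
#'   `c("healthy", "mtom", "severe")` or `c("healthy", "severe")`.
#' @param use_spo2 Include the `spo2` column as a feature?
#' @return A tibble with `subject_id`, `osa_class` and the feature
#'   columns, ready for [fit_osa_model()].
#' @export
build_profile_table <- function(profiles,
                                class_set = c("healthy", "severe"),
                                use_spo2 = FALSE) {
  allowed <- list(c("healthy", "mtom", "severe"), c("healthy", "severe"))
  if (!any(vapply(allowed, identical, logical(1), y = class_set)))
    abort("class_set must be healthy/mtom/severe or healthy/severe")
  keep <- profiles$osa_class %in% class_set
  out <- profiles[keep, , drop = FALSE]
  fcols <- grep("^(rem|nrem)\\.", names(out), value = TRUE)
  complete <- stats::complete.cases(out[, fcols])
  if (use_spo2) complete <- complete & !is.na(out$spo2)
  if (any(!complete)) {
    warn(sprintf("dropping %d subject(s) with missing aggregates: %s",
                 sum(!complete), paste(out$subject_id[!complete], collapse = ", ")))
    out <- out[complete, , drop = FALSE]
  }
  if (length(unique(out$osa_class)) < 2)
    abort("fewer than two classes remain after filtering")
  cols <- c("subject_id", "osa_class", if (use_spo2) "spo2", fcols)
  out[, cols]
}

#' Fit the apnea screening classifier
#'
#' Identical training contract to [fit_staging_model()] -- same grids,
#' z-score scaler from training data, inner-CV grid search -- applied to
#' the per-subject REM/NREM profile table with `osa_class` labels.  The
#' training-population REM and NREM mean profiles are stored so a
#' recording whose predicted hypnogram lacks one compartment can still
#' be screened (mean imputation, with a warning at predict time).
#'
#' @inheritParams fit_staging_model
#' @param table Profile table from [build_profile_table()].
#' @return A `sleep_model` with an `impute_means` field.
#' @export
fit_osa_model <- function(table, algorithm = c("svm", "knn", "mlp"),
                          seed = 0L, grid = NULL, inner_k = 3) {
  model <- fit_staging_model(table, algorithm = algorithm, seed = seed,
                             grid = grid, inner_k = inner_k,
                             label_col = "osa_class")
  model$impute_means <- colMeans(as.matrix(table[, model$feature_names]), na.rm = TRUE)
  model
}

#' Fill missing profile aggregates with a model's training means
#'
#' A subject without REM (or NREM) epochs has `NA` aggregate features.
#' At deployment the screener imputes them with the training-population
#' means stored in the fitted model; this helper applies the same policy
#' to a profile table, e.g. before evaluating on held-out subjects.
#'
#' @param profiles Profile tibble (rows = subjects).
#' @param model A [fit_osa_model()] result (supplies `impute_means`).
#' @return The tibble with `NA` feature values replaced.
#' @export
impute_profile_missing <- function(profiles, model) {
  for (cc in model$feature_names) {
    v <- profiles[[cc]]
    if (anyNA(v)) {
      v[is.na(v)] <- model$impute_means[[cc]]
      profiles[[cc]] <- v
    }
  }
  profiles
}

#' Integrated screening of a raw recording
#'
#' The end-to-end deployment path: bandpass filter, segment into 30-s
#' epochs, extract the 48 features per epoch, predict the hypnogram with
#' the staging model, average features over the *predicted* REM and NREM
#' epochs, and apply the screening model (trained healthy vs severe,
#' applied to all comers as a healthy-vs-OSA screener).
#'
#' If the predicted hypnogram lacks REM or NREM epochs the missing
#' aggregate is imputed with the screening model's training-population
#' mean (warning).  An all-wake prediction is unscreenable and returns
#' `outcome = "unscreenable"` rather than a silent guess.
#'
#' @param staging_model Staging `sleep_model` (five stages).
#' @param osa_model Screening `sleep_model` from [fit_osa_model()].
#' @param rec Raw [eeg_recording()] (unfiltered).
#' @param spo2 Optional oximetry scalar, required only if the screening
#'   model was trained with `use_spo2`.
#' @param low,high Preprocessing band edges in Hz.
#' @return A one-row tibble: `subject_id`, `outcome` (`"healthy"`,
#'   `"osa"` or `"unscreenable"`), `predicted_class`, per-class scores,
#'   and predicted stage counts.
#' @export
integrated_screen <- function(staging_model, osa_model, rec, spo2 = NA_real_,
                              low = 0.5, high = 50) {
  stopifnot(inherits(rec, "eeg_recording"))
  filtered <- bandpass(rec, low, high)
  epochs <- segment_epochs(filtered)
  feats <- featurize_subject(epochs, filtered$fs, subject_id = rec$subject_id)
  hyp <- predict_stages(staging_model, feats)
  screen_from_features(osa_model, feats, hyp, rec$subject_id, spo2)
}

# screening given already-computed features and a (predicted or expert)
# hypnogram; split out so a perfect-staging oracle is exactly equivalent
# to expert-stage screening
screen_from_features <- function(osa_model, feats, hyp, subject_id,
                                 spo2 = NA_real_) {
  stages <- as.character(hyp$stage)
  counts <- table(factor(stages, levels = sleep_stages()))
  feats$stage <- factor(stages, levels = sleep_stages())
  if (all(stages == "W")) {
    return(tibble::tibble(subject_id = subject_id, outcome = "unscreenable",
                          predicted_class = NA_character_,
                          score_healthy = NA_real_, score_osa = NA_real_,
                          !!!setNames(as.list(as.integer(counts)),
                                      paste0("n_", names(counts)))))
  }
  profile <- aggregate_profile(feats, meta = list(subject_id = subject_id,
                                                  age_group = NA, osa_class = NA,
                                                  spo2 = spo2))
  x <- profile[, osa_model$feature_names, drop = FALSE]
  imputed <- !stats::complete.cases(x)
  if (imputed) {
    miss <- names(x)[vapply(x, anyNA, logical(1))]
    warn(sprintf("subject %s: imputing %d missing aggregate feature(s) with training means",
                 subject_id, length(miss)))
    for (m in miss) x[[m]] <- osa_model$impute_means[[m]]
  }
  pred <- as.character(predict(osa_model, x))
  outcome <- if (pred == "healthy") "healthy" else "osa"
  tibble::tibble(
    subject_id = subject_id, outcome = outcome, predicted_class = pred,
    score_healthy = as.numeric(pred == "healthy"),
    score_osa = as.numeric(pred != "healthy"),
    !!!setNames(as.list(as.integer(counts)), paste0("n_", names(counts)))
  )
}
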