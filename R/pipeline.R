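#' Build and validate a pipeline configuration
#'
#' A single nested configuration drives the end-to-end run: cohort
#' simulation parameters, preprocessing band, model algorithms and seed,
#' evaluation protocol and screening task.  Every run writes the fully
#' resolved configuration next to its outputs so a completed run can be
#' re-executed from that file alone.
#'
#' @param ... Overrides of the default fields, as nested lists (e.g.
#'   `cohort = list(n_per_cell = 2)`).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  config <- list(
    cohort = list(n_per_cell = 3, epochs_per_subject = 60, subject_sd = 0.15),
    preprocessing = list(low = 0.5, high = 50),
    model = list(algorithms = c("svm", "knn", "mlp"), seed = 0L,
                 grid = "default"),
    evaluation = list(k = 5, reps = 2, split_unit = "subject"),
    screening = list(task = "healthy_severe", use_spo2 = FALSE,
                     holdout_fraction = 0.25)
  )
  config <- modifyList(config, list(...))
  validate_pipeline_config(config)
  structure(config, class = c("pipeline_config", "list"))
}

validate_pipeline_config <- function(config) {
  pp <- config$preprocessing
  if (!(pp$low > 0 && pp$low < pp$high))
    abort("preprocessing: require 0 < low < high")
  if (!all(config$model$algorithms %in% c("svm", "knn", "mlp")))
    abort("model: unknown algorithm")
  if (config$evaluation$k < 2) abort("evaluation: k must be >= 2")
  if (!config$evaluation$split_unit %in% c("subject", "epoch"))
    abort("evaluation: split_unit must be subject or epoch")
  if (!config$screening$task %in% c("healthy_severe", "three_class"))
    abort("screening: unknown task")
  invisible(config)
}

pipeline_log <- function(con, stage, ...) {
  entry <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage = stage),
             list(...))
  writeLines(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA), con)
  inform(sprintf("[%s] %s", stage,
                 paste(names(list(...)), unlist(list(...)), sep = "=", collapse = " ")))
}

#' Run the integrated pipeline end-to-end
#'
#' Simulate -> preprocess/featurize -> train staging models -> repeated
#' CV evaluation -> train the OSA screener on expert-stage profiles ->
#' integrated predicted-stage screening of held-out subjects.  All
#' artifacts (feature CSV, models, JSON reports, predicted hypnograms,
#' the resolved configuration and a JSON-lines log) are written under
#' `out_dir`; given the same configuration and seed the reports are
#' reproduced identically.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the run's main results (`features`,
#'   `models`, `evaluation`, `screening`, paths).
#' @export
run_pipeline <- function(config, out_dir) {
  validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(out_dir, "log.jsonl"), "w")
  on.exit(close(log_con))
  yaml::write_yaml(unclass(config), file.path(out_dir, "config_resolved.yaml"))
  seed <- config$model$seed

  spec <- cohort_spec(n_per_cell = config$cohort$n_per_cell,
                      epochs_per_subject = config$cohort$epochs_per_subject,
                      subject_sd = config$cohort$subject_sd, seed = seed)
  cohort <- simulate_cohort(spec)
  pipeline_log(log_con, "simulate", n_subjects = nrow(cohort$meta),
               epochs_per_subject = spec$epochs_per_subject)

  feats <- featurize_cohort(cohort)
  write_features(feats, file.path(out_dir, "features.csv"))
  write_metadata(cohort$meta, file.path(out_dir, "metadata.csv"))
  pipeline_log(log_con, "features", n_epochs = nrow(feats),
               n_features = length(feature_columns(feats)))

  # subject-level holdout for the integrated test, stratified by cell
  set.seed(seed)
  subjects <- cohort$meta$subject_id
  strata <- paste(cohort$meta$age_group, cohort$meta$osa_class)
  holdout <- unlist(lapply(unique(strata), function(s) {
    ids <- subjects[strata == s]
    n_hold <- max(1, round(length(ids) * config$screening$holdout_fraction))
    sample(ids, n_hold)
  }))
  train_feats <- feats[!feats$subject_id %in% holdout, ]
  pipeline_log(log_con, "split", n_train = length(setdiff(subjects, holdout)),
               n_holdout = length(holdout))

  grid_of <- function(alg) {
    if (identical(config$model$grid, "default")) NULL else config$model$grid[[alg]]
  }
  models <- list()
  for (alg in config$model$algorithms) {
    models[[alg]] <- fit_staging_model(train_feats, alg, seed = seed,
                                       grid = grid_of(alg))
    save_model(models[[alg]], file.path(out_dir, paste0("staging_", alg, ".model")))
    pipeline_log(log_con, "train_staging", algorithm = alg,
                 inner_accuracy = max(models[[alg]]$grid_accuracy))
  }

  evaluation <- lapply(config$model$algorithms, function(alg) {
    cv <- repeated_cv(train_feats, alg, k = config$evaluation$k,
                      reps = config$evaluation$reps,
                      split_unit = config$evaluation$split_unit,
                      seed = seed, grid = grid_of(alg), meta = cohort$meta)
    pipeline_log(log_con, "evaluate", algorithm = alg,
                 mean_accuracy = mean(cv$scores$accuracy))
    list(algorithm = alg, accuracies = cv$scores$accuracy,
         mean_accuracy = mean(cv$scores$accuracy),
         confusion = cv$confusion)
  })
  names(evaluation) <- config$model$algorithms
  jsonlite::write_json(evaluation, file.path(out_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")

  profiles <- purrr::map_dfr(setdiff(subjects, holdout), function(sid) {
    aggregate_profile(feats[feats$subject_id == sid, ],
                      meta = cohort$meta[cohort$meta$subject_id == sid, ])
  })
  class_set <- if (config$screening$task == "three_class")
    c("healthy", "mtom", "severe") else c("healthy", "severe")
  table <- build_profile_table(profiles, class_set,
                               use_spo2 = config$screening$use_spo2)
  osa_alg <- config$model$algorithms[length(config$model$algorithms)]
  osa_model <- fit_osa_model(table, osa_alg, seed = seed)
  save_model(osa_model, file.path(out_dir, "osa.model"))
  pipeline_log(log_con, "train_osa", algorithm = osa_alg, n_subjects = nrow(table))

  staging_alg <- config$model$algorithms[1]
  screening <- purrr::map_dfr(holdout, function(sid) {
    res <- integrated_screen(models[[staging_alg]], osa_model,
                             cohort$recordings[[sid]],
                             spo2 = cohort$spo2[[sid]])
    hyp <- predict_stages(models[[staging_alg]], feats[feats$subject_id == sid, ])
    write_hypnogram(hyp, file.path(out_dir, paste0(sid, "_predicted.csv")))
    res$true_class <- cohort$meta$osa_class[cohort$meta$subject_id == sid]
    res
  })
  screening$true_binary <- ifelse(screening$true_class == "healthy", "healthy", "osa")
  screened <- screening$outcome != "unscreenable"
  accuracy <- mean(screening$outcome[screened] == screening$true_binary[screened])
  jsonlite::write_json(
    list(staging_algorithm = staging_alg, osa_algorithm = osa_alg,
         n_screened = sum(screened), accuracy = accuracy,
         subjects = screening),
    file.path(out_dir, "screening.json"), auto_unbox = TRUE, digits = NA)
  pipeline_log(log_con, "screen", n_screened = sum(screened), accuracy = accuracy)

  invisible(list(features = feats, models = models, osa_model = osa_model,
                 evaluation = evaluation, screening = screening,
                 out_dir = out_dir))
}
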