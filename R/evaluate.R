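#' Accuracy, per-stage F1 and confusion matrix of a predicted hypnogram
#'
#' Compares predicted against reference stage sequences: overall
#' accuracy, one-vs-rest F1 per stage (harmonic mean of precision and
#' recall; undefined -- `NA` -- for a stage absent from both truth and
#' prediction, and excluded from averages), and the 5x5 confusion matrix
#' with rows indexed by the true stage.
#'
#' @param true,pred [hypnogram()]s (or stage character vectors) of equal
#'   length.
#' @return A list of class `stage_metrics`: `accuracy`, `f1` (named
#'   vector over stages), `confusion` (counts), `confusion_rates`
#'   (row-normalized).
#' @export
stage_metrics <- function(true, pred) {
  tv <- if (inherits(true, "hypnogram")) as.character(true$stage) else as.character(true)
  pv <- if (inherits(pred, "hypnogram")) as.character(pred$stage) else as.character(pred)
  if (length(tv) != length(pv))
    abort(sprintf("length mismatch: %d true vs %d predicted labels", length(tv), length(pv)))
  assert_stage_labels(tv); assert_stage_labels(pv)
  lv <- sleep_stages()
  conf <- table(factor(tv, levels = lv), factor(pv, levels = lv))
  conf <- unclass(conf)
  f1 <- vapply(lv, function(s) {
    tp <- conf[s, s]; fp <- sum(conf[, s]) - tp; fn <- sum(conf[s, ]) - tp
    if (tp + fp + fn == 0) return(NA_real_)  # stage absent from both
    if (tp == 0) return(0)
    prec <- tp / (tp + fp); rec <- tp / (tp + fn)
    2 * prec * rec / (prec + rec)
  }, numeric(1))
  rs <- rowSums(conf)
  rates <- sweep(conf, 1, ifelse(rs > 0, rs, 1), "/")
  structure(list(accuracy = mean(tv == pv), f1 = f1,
                 confusion = conf, confusion_rates = rates),
            class = "stage_metrics")
}

#' @export
print.stage_metrics <- function(x, ...) {
  cat(sprintf("<stage_metrics> accuracy %.3f; f1: %s\n", x$accuracy,
              paste(names(x$f1), sprintf("%.3f", x$f1), sep = "=", collapse = " ")))
  invisible(x)
}

#' One-way ANOVA with Bonferroni post-hoc t-tests
#'
#' Classical between/within sums-of-squares F test across groups of
#' accuracy values, with degrees of freedom (groups - 1, total -
#' groups).  When the omnibus test is significant at the stated level,
#' pairwise two-sided pooled-variance t-tests are run with Bonferroni
#' correction (p multiplied by the number of pairs, capped at 1).
#' Degenerate data with zero variance everywhere and equal means yields
#' F = 0.
#'
#' @param groups Named (or unnamed) list of numeric vectors, one per
#'   model/group, each of length >= 2.
#' @param alpha Significance level for the omnibus test and post-hoc
#'   flags (default 0.01).
#' @return A list of class `anova_report`: `F`, `df_between`,
#'   `df_within`, `p`, and `posthoc` (tibble of pair, t, p_bonferroni,
#'   significant), empty when the omnibus test is not significant.
#' @export
one_way_anova <- function(groups, alpha = 0.01) {
  if (length(groups) < 2) abort("need at least two groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    abort("each group needs at least two values")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))),
              levels = names(groups))
  df_b <- nlevels(g) - 1L
  df_w <- length(values) - nlevels(g)
  if (stats::var(values) == 0) {
    # no variance anywhere with equal means: F defined as 0
    Fv <- 0; pv <- 1
  } else {
    tab <- anova(aov(values ~ g))
    Fv <- tab$`F value`[1]
    pv <- tab$`Pr(>F)`[1]
    if (!is.finite(Fv)) { Fv <- 0; pv <- 1 }
  }
  posthoc <- tibble::tibble(pair = character(), t = numeric(),
                            p_bonferroni = numeric(), significant = logical())
  if (is.finite(pv) && pv < alpha) {
    pairs <- utils::combn(names(groups), 2, simplify = FALSE)
    rows <- lapply(pairs, function(pr) {
      tt <- t.test(groups[[pr[1]]], groups[[pr[2]]], var.equal = TRUE)
      tibble::tibble(pair = paste(pr, collapse = " vs "),
                     t = unname(tt$statistic),
                     p_bonferroni = min(1, tt$p.value * length(pairs)))
    })
    posthoc <- dplyr::bind_rows(rows)
    posthoc$significant <- posthoc$p_bonferroni < alpha
  }
  structure(list(F = Fv, df_between = df_b, df_within = df_w, p = pv,
                 posthoc = posthoc, alpha = alpha),
            class = "anova_report")
}

#' @export
print.anova_report <- function(x, ...) {
  cat(sprintf("<anova_report> F(%d,%d) = %.3f, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  if (nrow(x$posthoc) > 0) print(x$posthoc)
  invisible(x)
}

#' @method tidy anova_report
#' @export
tidy.anova_report <- function(x, ...) x$posthoc

#' @method glance anova_report
#' @export
glance.anova_report <- function(x, ...) {
  tibble::tibble(F = x$F, df_between = x$df_between,
                 df_within = x$df_within, p = x$p)
}

#' Repeated stratified k-fold cross-validation
#'
#' The validation harness: `reps` independent shuffles, each split into
#' `k` folds; per fold the model is fitted (including its inner
#' grid search) on the remaining folds and scored on the held-out fold,
#' yielding `k * reps` accuracy values (50 under the 10 x 5 default),
#' per-stage F1 for each fold, and the summed confusion matrix.
#'
#' Splitting unit is either `"epoch"` (folds stratified by stage) or
#' `"subject"` (whole subjects assigned to folds, stratified by
#' age group x OSA class when available; no subject ever appears in both
#' train and test of one fold).
#'
#' @param data Feature tibble (`stage`, feature columns; `subject_id`
#'   required for subject splits).
#' @param algorithm `"svm"`, `"knn"` or `"mlp"`.
#' @param k Folds per repetition (default 5).
#' @param reps Repetitions (default 10).
#' @param split_unit `"subject"` (default) or `"epoch"`.
#' @param seed Integer seed; fold shuffles and fits derive from it.
#' @param grid Optional hyperparameter grid (defaults to the full
#'   declared grid).
#' @param meta Optional metadata tibble for subject-split
#'   stratification.
#' @param inner_k Inner grid-search folds.
#' @return Object of class `cv_result`: `scores` tibble (rep, fold,
#'   accuracy, one `f1_<stage>` column each), `confusion`, `config`.
#' @export
repeated_cv <- function(data, algorithm = c("svm", "knn", "mlp"), k = 5,
                        reps = 10, split_unit = c("subject", "epoch"),
                        seed = 0L, grid = NULL, meta = NULL, inner_k = 3) {
  algorithm <- match.arg(algorithm)
  split_unit <- match.arg(split_unit)
  if (nrow(data) == 0) abort("empty feature table")
  lv <- sleep_stages()
  conf_total <- matrix(0L, length(lv), length(lv), dimnames = list(lv, lv))
  rows <- list()
  for (r in seq_len(reps)) {
    set.seed(seed + r * 1000L)
    fold_of_row <- cv_fold_assignment(data, k, split_unit, meta)
    for (f in seq_len(k)) {
      te <- fold_of_row == f
      train <- data[!te, , drop = FALSE]
      test <- data[te, , drop = FALSE]
      if (!all(lv %in% unique(as.character(train$stage))))
        warn(sprintf("rep %d fold %d: training set is missing stage(s) %s", r, f,
                     paste(setdiff(lv, unique(as.character(train$stage))), collapse = ",")))
      model <- fit_staging_model(train, algorithm, seed = seed + r * 1000L + f,
                                 grid = grid, inner_k = inner_k)
      pred <- as.character(predict(model, test))
      m <- stage_metrics(as.character(test$stage), pred)
      conf_total <- conf_total + m$confusion
      rows[[length(rows) + 1]] <- tibble::tibble(
        rep = r, fold = f, n_test = nrow(test), accuracy = m$accuracy,
        !!!setNames(as.list(m$f1), paste0("f1_", names(m$f1))))
    }
  }
  structure(list(scores = dplyr::bind_rows(rows), confusion = conf_total,
                 config = list(k = k, reps = reps, split_unit = split_unit,
                               seed = seed, algorithm = algorithm)),
            class = "cv_result")
}

cv_fold_assignment <- function(data, k, split_unit, meta = NULL) {
  if (split_unit == "epoch") {
    stratified_fold_ids(as.character(data$stage), k)
  } else {
    if (!"subject_id" %in% names(data))
      abort("subject-level splits require a subject_id column")
    subjects <- unique(data$subject_id)
    if (length(subjects) < k)
      abort(sprintf("subject-level %d-fold CV needs >= %d subjects, got %d",
                    k, k, length(subjects)))
    strata <- rep("all", length(subjects))
    if (!is.null(meta)) {
      mm <- meta[match(subjects, meta$subject_id), ]
      strata <- paste(mm$age_group, mm$osa_class)
    }
    sub_fold <- stratified_fold_ids(strata, k)
    sub_fold[match(data$subject_id, subjects)]
  }
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, %d x %d-fold (%s split): accuracy %.3f +/- %.3f over %d values\n",
              x$config$algorithm, x$config$reps, x$config$k, x$config$split_unit,
              mean(x$scores$accuracy), sd(x$scores$accuracy), nrow(x$scores)))
  invisible(x)
}

#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) x$scores

#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  f1_cols <- grep("^f1_", names(x$scores), value = TRUE)
  out <- tibble::tibble(
    algorithm = x$config$algorithm, k = x$config$k, reps = x$config$reps,
    split_unit = x$config$split_unit, n_scores = nrow(x$scores),
    mean_accuracy = mean(x$scores$accuracy),
    sd_accuracy = sd(x$scores$accuracy))
  for (cc in f1_cols)
    out[[paste0("mean_", cc)]] <- mean(x$scores[[cc]], na.rm = TRUE)
  out
}

#' Same-group and cross-group validation (Y-Y, Y-O, O-O, O-Y)
#'
#' For each ordered pair of groups (e.g. younger/older): same-group
#' cells are scored by k-fold CV within the group; cross-group cells
#' train on each of the training folds of the train group and evaluate
#' on the entire other group.  Quantifies how well a group-specific
#' model transfers across groups.
#'
#' @param data Feature tibble with `stage` and a grouping column.
#' @param group_col Name of the grouping column (default `"age_group"`).
#' @param algorithm,k,seed,grid,inner_k As in [repeated_cv()].
#' @return A tibble: `train_group`, `eval_group`, `fold`, `accuracy`
#'   (one row per fold per ordered pair).
#' @export
cross_group_validation <- function(data, group_col = "age_group",
                                   algorithm = c("svm", "knn", "mlp"),
                                   k = 5, seed = 0L, grid = NULL, inner_k = 3) {
  algorithm <- match.arg(algorithm)
  if (!group_col %in% names(data)) abort(sprintf("no '%s' column", group_col))
  grp <- as.character(data[[group_col]])
  groups <- unique(grp)
  if (length(groups) < 2) abort("need at least two groups")
  rows <- list()
  for (gtrain in groups) {
    gdata <- data[grp == gtrain, , drop = FALSE]
    set.seed(seed)
    folds <- stratified_fold_ids(as.character(gdata$stage), k)
    for (f in seq_len(k)) {
      model <- fit_staging_model(gdata[folds != f, , drop = FALSE], algorithm,
                                 seed = seed + f, grid = grid, inner_k = inner_k)
      for (geval in groups) {
        test <- if (geval == gtrain) gdata[folds == f, , drop = FALSE]
                else data[grp == geval, , drop = FALSE]
        acc <- mean(as.character(predict(model, test)) == as.character(test$stage))
        rows[[length(rows) + 1]] <- tibble::tibble(
          train_group = gtrain, eval_group = geval, fold = f, accuracy = acc)
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Inter-subject correlation of stage-mean feature vectors
#'
#' Pearson correlation between every pair of subjects' mean feature
#' vectors within one stage -- a homogeneity measure: tighter groups
#' (e.g. younger cohorts) show higher between-subject correlations.
#'
#' @param feats Feature tibble with `subject_id`, `stage` and feature
#'   columns (multiple subjects).
#' @param stage Stage label to condition on.
#' @param group Optional named vector mapping subject_id to a group for
#'   the summary.
#' @return List of class `subject_correlation`: `correlation` (symmetric
#'   matrix, `NA` where a subject's vector is constant), `summary`
#'   tibble of mean off-diagonal correlation per group.
#' @export
inter_subject_correlation <- function(feats, stage, group = NULL) {
  keep <- as.character(feats$stage) == stage
  if (!any(keep)) abort(sprintf("no epochs of stage %s", stage))
  fcols <- feature_columns(feats)
  means <- feats[keep, ] |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(fcols), mean), .groups = "drop")
  if (nrow(means) < 2) abort("need at least two subjects with this stage")
  m <- t(as.matrix(means[, fcols]))
  colnames(m) <- means$subject_id
  constant <- apply(m, 2, function(v) sd(v) == 0)
  cc <- suppressWarnings(cor(m))
  cc[constant, ] <- NA; cc[, constant] <- NA
  diag(cc) <- 1
  grp <- if (is.null(group)) setNames(rep("all", ncol(m)), colnames(m)) else group
  summary <- lapply(unique(grp[colnames(m)]), function(g) {
    ids <- colnames(m)[grp[colnames(m)] == g]
    sub <- cc[ids, ids, drop = FALSE]
    off <- sub[lower.tri(sub)]
    tibble::tibble(group = g, n_subjects = length(ids),
                   mean_correlation = mean(off, na.rm = TRUE))
  }) |> dplyr::bind_rows()
  structure(list(correlation = cc, summary = summary),
            class = "subject_correlation")
}
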