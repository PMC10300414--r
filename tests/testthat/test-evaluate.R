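test_that("stage metrics match hand-computed precision/recall", {
  m <- stage_metrics(c("W", "W", "N2", "N2"), c("W", "N2", "N2", "N2"))
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$f1[["W"]], 2 / 3)
  expect_equal(m$f1[["N2"]], 0.8)
  expect_true(is.na(m$f1[["N3"]]))  # absent from both

  perfect <- stage_metrics(sleep_stages(), sleep_stages())
  expect_equal(perfect$accuracy, 1)
  expect_equal(unname(perfect$f1), rep(1, 5))
  expect_equal(unname(diag(perfect$confusion)), rep(1L, 5), ignore_attr = TRUE)

  expect_error(stage_metrics(c("W", "N1"), c("W")), "length mismatch")
})

test_that("confusion matrix conserves epochs and accuracy equals its trace ratio", {
  set.seed(31)
  true <- sample(sleep_stages(), 400, replace = TRUE)
  pred <- ifelse(runif(400) < 0.7, true, sample(sleep_stages(), 400, replace = TRUE))
  m <- stage_metrics(true, pred)
  expect_equal(sum(m$confusion), 400)
  expect_equal(m$accuracy, sum(diag(m$confusion)) / sum(m$confusion))
  expect_equal(unname(rowSums(m$confusion)),
               unname(as.vector(table(factor(true, levels = sleep_stages())))))
})

test_that("one-way ANOVA matches a from-definition sums-of-squares oracle", {
  groups <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5))
  values <- unlist(groups)
  grand <- mean(values)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  F_oracle <- (ssb / 2) / (ssw / 6)
  rep <- one_way_anova(groups)
  expect_equal(rep$F, F_oracle, tolerance = 1e-10)
  expect_equal(rep$df_between, 2)
  expect_equal(rep$df_within, 6)

  # three groups of 50 values give the (2, 147) degrees of freedom shape
  set.seed(32)
  g50 <- list(rnorm(50), rnorm(50), rnorm(50))
  r50 <- one_way_anova(g50)
  expect_equal(r50$df_between, 2)
  expect_equal(r50$df_within, 147)

  identical_groups <- list(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1))
  expect_equal(one_way_anova(identical_groups)$F, 0)
})

test_that("ANOVA F is shift-invariant and scale-invariant, post hoc is Bonferroni", {
  set.seed(33)
  g <- list(a = rnorm(20, 0), b = rnorm(20, 0.5), c = rnorm(20, 2))
  base <- one_way_anova(g)
  shifted <- one_way_anova(lapply(g, function(v) v + 100))
  scaled <- one_way_anova(lapply(g, function(v) v * 3.7))
  expect_equal(base$F, shifted$F, tolerance = 1e-10)
  expect_equal(base$F, scaled$F, tolerance = 1e-10)
  expect_true(base$p < 0.01)
  expect_equal(nrow(base$posthoc), 3)
  tt <- t.test(g$a, g$c, var.equal = TRUE)
  row <- base$posthoc[base$posthoc$pair == "a vs c", ]
  expect_equal(row$p_bonferroni, min(1, tt$p.value * 3))
  expect_equal(glance(base)$F, base$F)
})

test_that("repeated CV yields k x reps scores and subject splits never leak", {
  data <- toy_features(n_per_stage = 30)
  cv <- suppressWarnings(
    repeated_cv(data, "knn", k = 5, reps = 2, split_unit = "epoch",
                seed = 3, grid = tiny_knn_grid))
  expect_equal(nrow(cv$scores), 10)
  expect_equal(sum(cv$confusion), nrow(data) * 2)
  expect_true(all(cv$scores$accuracy > 0.9))  # separable toy classes

  # subject split: reconstruct assignments and check exclusivity
  set.seed(3 + 1000)
  folds <- sleepstager:::cv_fold_assignment(data, 4, "subject")
  for (f in 1:4) {
    train_subj <- unique(data$subject_id[folds != f])
    test_subj <- unique(data$subject_id[folds == f])
    expect_length(intersect(train_subj, test_subj), 0)
  }
  expect_error(repeated_cv(data[0, ], "knn"), "empty")
})

test_that("chance-level accuracy arises on permuted labels", {
  set.seed(35)
  n <- 500
  data <- tibble::tibble(
    subject_id = "s1", epoch = seq_len(n) - 1L,
    stage = factor(sample(rep(sleep_stages(), each = n / 5)),
                   levels = sleep_stages()),
    f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n))
  cv <- suppressWarnings(
    repeated_cv(data, "knn", k = 5, reps = 2, split_unit = "epoch",
                seed = 7, grid = list(list(n_neighbors = 9, weights = "uniform",
                                           metric = "euclidean"))))
  se <- sqrt(0.2 * 0.8 / (n * 2))
  expect_lt(abs(mean(cv$scores$accuracy) - 0.2), 3 * se + 1e-12)
})

test_that("cross-group validation produces all ordered pairs with sane ordering", {
  data <- toy_features(n_per_stage = 30)
  data$age_group <- rep(c("younger", "older"), length.out = nrow(data))
  # disjoint supports: shift the older group's features far away
  data$f1[data$age_group == "older"] <- data$f1[data$age_group == "older"] + 50
  res <- cross_group_validation(data, "age_group", "knn", k = 3, seed = 2,
                                grid = tiny_knn_grid)
  expect_equal(nrow(res), 2 * 2 * 3)
  expect_setequal(unique(paste(res$train_group, res$eval_group)),
                  c("younger younger", "younger older",
                    "older older", "older younger"))
  agg <- dplyr::summarise(dplyr::group_by(res, train_group, eval_group),
                          acc = mean(accuracy), .groups = "drop")
  same <- agg$acc[agg$train_group == agg$eval_group]
  cross <- agg$acc[agg$train_group != agg$eval_group]
  expect_true(all(cross <= min(same) + 1e-9))
})

test_that("inter-subject correlation flags constants and ranks homogeneity", {
  base <- rnorm(12)
  mk <- function(id, vec) {
    tibble::tibble(subject_id = id, epoch = 0:1,
                   stage = factor("R", levels = sleep_stages()),
                   !!!setNames(as.list(vec), paste0("f", seq_along(vec))))
  }
  feats <- dplyr::bind_rows(mk("a", base), mk("b", base), mk("c", -base))
  res <- inter_subject_correlation(feats, "R")
  expect_equal(res$correlation["a", "b"], 1)
  expect_equal(res$correlation["a", "c"], -1)

  # homogeneous group (small noise) correlates more than heterogeneous
  set.seed(36)
  hom <- dplyr::bind_rows(lapply(1:6, function(i) mk(paste0("h", i), base + rnorm(12, 0, 0.3))))
  het <- dplyr::bind_rows(lapply(1:6, function(i) mk(paste0("x", i), base + rnorm(12, 0, 1.2))))
  all_feats <- dplyr::bind_rows(hom, het)
  grp <- setNames(rep(c("hom", "het"), each = 6), c(paste0("h", 1:6), paste0("x", 1:6)))
  res2 <- inter_subject_correlation(all_feats, "R", group = grp)
  s <- res2$summary
  expect_gt(s$mean_correlation[s$group == "hom"],
            s$mean_correlation[s$group == "het"])

  const <- dplyr::bind_rows(mk("a", base), mk("z", rep(1, 12)))
  res3 <- inter_subject_correlation(const, "R")
  expect_true(is.na(res3$correlation["a", "z"]))
})

test_that("groups drawn from one distribution transfer across groups", {
  # same-distribution null: cross-group accuracy is statistically
  # indistinguishable from same-group accuracy
  data <- toy_features(n_per_stage = 40, sd = 0.4, seed = 91)
  set.seed(92)
  data$age_group <- sample(rep(c("younger", "older"), length.out = nrow(data)))
  res <- cross_group_validation(data, "age_group", "knn", k = 5, seed = 3,
                                grid = tiny_knn_grid)
  agg <- dplyr::summarise(dplyr::group_by(res, train_group, eval_group),
                          m = mean(accuracy), s = sd(accuracy), n = dplyr::n(),
                          .groups = "drop")
  same <- agg[agg$train_group == agg$eval_group, ]
  cross <- agg[agg$train_group != agg$eval_group, ]
  for (g in same$train_group) {
    mu_s <- same$m[same$train_group == g]
    ci_s <- 2 * same$s[same$train_group == g] / sqrt(5)
    mu_c <- cross$m[cross$train_group == g]
    ci_c <- 2 * cross$s[cross$train_group == g] / sqrt(5)
    expect_lt(abs(mu_s - mu_c), ci_s + ci_c + 0.05)
  }
})
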