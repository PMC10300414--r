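#' Hyperparameter grids for the three learning algorithms
#'
#' The candidate sets searched during model selection:
#' * `svm` -- RBF kernel, `C` in \{0.1, 1, 10, 100\} crossed with `gamma`
#'   in \{0.001, 0.01, 0.1, 1, 10\} (20 candidates);
#' * `knn` -- `n_neighbors` in \{1, 3, ..., 19\}, vote `weights` in
#'   \{uniform, distance\}, `metric` in \{euclidean, manhattan\}
#'   (40 candidates);
#' * `mlp` -- 1 or 2 hidden layers with \{16, 32, 64\} nodes chosen
#'   independently per layer (3 + 9 = 12 candidates); Adam optimizer,
#'   ReLU activation, at most 200 iterations.
#'
#' @param algorithm One of `"svm"`, `"knn"`, `"mlp"`.
#' @return A list of candidate hyperparameter lists, in tie-break order
#'   (earlier candidates win ties).
#' @export
default_grid <- function(algorithm = c("svm", "knn", "mlp")) {
  algorithm <- match.arg(algorithm)
  switch(algorithm,
    svm = {
      out <- list()
      for (C in c(0.1, 1, 10, 100))
        for (gamma in c(0.001, 0.01, 0.1, 1, 10))
          out[[length(out) + 1]] <- list(C = C, gamma = gamma)
      out
    },
    knn = {
      out <- list()
      for (k in seq(1, 19, by = 2))
        for (w in c("uniform", "distance"))
          for (m in c("euclidean", "manhattan"))
            out[[length(out) + 1]] <- list(n_neighbors = k, weights = w, metric = m)
      out
    },
    mlp = {
      out <- lapply(c(16, 32, 64), function(h) list(hidden = h))
      for (h1 in c(16, 32, 64))
        for (h2 in c(16, 32, 64))
          out[[length(out) + 1]] <- list(hidden = c(h1, h2))
      out
    }
  )
}

feature_columns <- function(data) {
  setdiff(names(data), c("subject_id", "epoch", "stage", "label",
                         "osa_class", "age_group", "class"))
}

# per-feature z-score parameters from training data only
fit_scaler <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, sd)
  scale[!is.finite(scale) | scale <= 0] <- 1
  list(center = center, scale = scale)
}

apply_scaler <- function(x, scaler) {
  sweep(sweep(as.matrix(x), 2, scaler$center, "-"), 2, scaler$scale, "/")
}

# round-robin stratified fold assignment after a shuffle (uses the
# caller's RNG stream)
stratified_fold_ids <- function(strata, k) {
  folds <- integer(length(strata))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

fit_candidate <- function(x, y, algorithm, params, classes, seed) {
  switch(algorithm,
    svm = e1071::svm(x = x, y = factor(y, levels = classes),
                     kernel = "radial", cost = params$C, gamma = params$gamma,
                     scale = FALSE),
    knn = knn_fit(x, y, n_neighbors = params$n_neighbors,
                  weights = params$weights, metric = params$metric,
                  classes = classes),
    mlp = mlp_fit(x, y, hidden = params$hidden, classes = classes, seed = seed)
  )
}

predict_candidate <- function(fit, x) as.character(predict(fit, x))

# mean inner-CV accuracy per grid candidate; kNN shares each fold's
# distance matrix across all (k, weights) candidates of a metric
grid_search <- function(x, y, algorithm, grid, classes, seed, inner_k = 3) {
  folds <- stratified_fold_ids(y, inner_k)
  acc <- matrix(NA_real_, length(grid), inner_k)
  for (f in seq_len(inner_k)) {
    tr <- folds != f; te <- !tr
    if (length(unique(y[tr])) < 2) next
    if (algorithm == "knn") {
      for (m in c("euclidean", "manhattan")) {
        cand <- which(vapply(grid, function(g) identical(g$metric, m), logical(1)))
        if (!length(cand)) next
        d <- knn_distance(x[te, , drop = FALSE], x[tr, , drop = FALSE], m)
        kmax <- min(max(vapply(grid[cand], `[[`, numeric(1), "n_neighbors")), sum(tr))
        nbr <- knn_neighbours(d, kmax)
        for (ci in cand) {
          g <- grid[[ci]]
          kk <- min(g$n_neighbors, sum(tr))
          pred <- knn_vote(d, nbr, y[tr], classes, kk, g$weights)
          acc[ci, f] <- mean(pred == y[te])
        }
      }
    } else {
      for (ci in seq_along(grid)) {
        fit <- fit_candidate(x[tr, , drop = FALSE], y[tr], algorithm,
                             grid[[ci]], classes, seed = seed + ci)
        pred <- predict_candidate(fit, x[te, , drop = FALSE])
        acc[ci, f] <- mean(pred == y[te])
      }
    }
  }
  rowMeans(acc, na.rm = TRUE)
}

#' Fit a stage or screening classifier with grid-searched hyperparameters
#'
#' Standardizes features with training-set statistics only (z-score),
#' selects hyperparameters by mean accuracy under stratified inner
#' cross-validation over the declared grid (ties break to the
#' first-listed candidate), and refits the winner on the full training
#' set.  Deterministic given `seed`.
#'
#' @param train Tibble holding a label column plus feature columns.
#'   Staging uses `stage`; screening uses `osa_class` (see
#'   [fit_osa_model()]).  Columns `subject_id`/`epoch` are ignored.
#' @param algorithm `"svm"`, `"knn"` or `"mlp"`.
#' @param seed Integer seed governing fold shuffles and MLP
#'   initialization.
#' @param grid Candidate list as from [default_grid()]; defaults to the
#'   full declared grid.
#' @param inner_k Inner CV folds for model selection (default 3).
#' @param label_col Name of the label column (default `"stage"`).
#' @return An object of class `sleep_model`: algorithm id, selected
#'   hyperparameters, per-candidate inner accuracies, scaler, class
#'   order, feature names and the fitted state.
#' @export
fit_staging_model <- function(train, algorithm = c("svm", "knn", "mlp"),
                              seed = 0L, grid = NULL, inner_k = 3,
                              label_col = "stage") {
  algorithm <- match.arg(algorithm)
  grid <- grid %||% default_grid(algorithm)
  if (length(grid) == 0) abort("empty hyperparameter grid")
  if (!label_col %in% names(train)) abort(sprintf("no '%s' column in training data", label_col))
  y <- as.character(train[[label_col]])
  classes <- if (label_col == "stage") intersect(sleep_stages(), unique(y)) else sort(unique(y))
  if (length(classes) < 2) abort("training data must contain at least two classes")
  fcols <- feature_columns(train)
  x <- as.matrix(train[, fcols])
  if (anyNA(x)) abort("missing values in feature columns")
  scaler <- fit_scaler(x)
  xs <- apply_scaler(x, scaler)

  set.seed(seed)
  mean_acc <- if (length(grid) > 1) {
    grid_search(xs, y, algorithm, grid, classes, seed, inner_k)
  } else 1
  best <- which.max(mean_acc)  # which.max returns the first maximum
  fit <- fit_candidate(xs, y, algorithm, grid[[best]], classes, seed = seed + best)

  structure(
    list(algorithm = algorithm, hyperparams = grid[[best]],
         grid = grid, grid_accuracy = as.numeric(mean_acc),
         scaler = scaler, classes = classes, feature_names = fcols,
         label_col = label_col, n_train = nrow(x), seed = seed, fit = fit),
    class = "sleep_model"
  )
}

#' @export
print.sleep_model <- function(x, ...) {
  hp <- paste(names(x$hyperparams),
              vapply(x$hyperparams, function(v) paste(v, collapse = "x"), ""),
              sep = "=", collapse = ", ")
  cat(sprintf("<sleep_model> %s (%s): %d training rows, classes [%s]\n",
              x$algorithm, hp, x$n_train, paste(x$classes, collapse = ",")))
  invisible(x)
}

#' @export
predict.sleep_model <- function(object, newdata, ...) {
  fcols <- object$feature_names
  missing <- setdiff(fcols, names(newdata))
  extra <- setdiff(feature_columns(newdata), fcols)
  if (length(missing) > 0 || length(extra) > 0)
    abort(sprintf("feature columns do not match training layout%s%s",
                  if (length(missing)) paste0("; missing: ", paste(missing, collapse = ",")) else "",
                  if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ",")) else ""))
  x <- as.matrix(newdata[, fcols])
  if (anyNA(x))
    abort("missing feature values in newdata; impute (e.g. with impute_profile_missing()) before prediction")
  xs <- apply_scaler(x, object$scaler)
  factor(as.character(predict(object$fit, xs)), levels = object$classes)
}

#' Predict a hypnogram from per-epoch features
#'
#' Applies the stored feature scaler and the fitted staging classifier
#' row-wise, returning the predicted stage sequence as a [hypnogram()].
#'
#' @param model A staging [fit_staging_model()] result.
#' @param feats Feature tibble whose feature columns match the training
#'   layout.
#' @return A [hypnogram()] with one label per row of `feats`.
#' @export
predict_stages <- function(model, feats) {
  stopifnot(inherits(model, "sleep_model"))
  if (!all(model$classes %in% sleep_stages()))
    abort("model was not trained on sleep-stage labels")
  labels <- as.character(predict(model, feats))
  sid <- if ("subject_id" %in% names(feats)) unique(feats$subject_id)[1] else "subject"
  hypnogram(labels, subject_id = sid)
}

#' @method tidy sleep_model
#' @export
tidy.sleep_model <- function(x, ...) {
  tibble::tibble(
    candidate = seq_along(x$grid),
    !!!purrr::map_dfr(x$grid, function(g)
      purrr::map(g, function(v) paste(v, collapse = "x"))),
    mean_inner_accuracy = x$grid_accuracy,
    selected = seq_along(x$grid) == which.max(x$grid_accuracy)
  )
}

#' @method glance sleep_model
#' @export
glance.sleep_model <- function(x, ...) {
  tibble::tibble(
    algorithm = x$algorithm,
    hyperparams = paste(names(x$hyperparams),
                        vapply(x$hyperparams, function(v) paste(v, collapse = "x"), ""),
                        sep = "=", collapse = ", "),
    n_train = x$n_train,
    n_classes = length(x$classes),
    inner_accuracy = max(x$grid_accuracy),
    seed = x$seed
  )
}

model_magic <- "sleepstager-model-v1\n"

#' Persist and restore fitted models
#'
#' Models are written as a versioned container: a magic line, a JSON
#' metadata header (algorithm, selected hyperparameters, feature names,
#' class order) readable without deserializing the fitted state, then
#' the serialized model payload.  [model_info()] reads only the header.
#'
#' @param model A `sleep_model`.
#' @param path Destination file.
#' @return `load_model()` the restored `sleep_model`; `model_info()` the
#'   metadata list; `save_model()` `path` invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "sleep_model"))
  meta <- list(format = "sleepstager-model", version = 1L,
               algorithm = model$algorithm, hyperparams = model$hyperparams,
               classes = model$classes, feature_names = model$feature_names,
               label_col = model$label_col, n_train = model$n_train)
  meta_raw <- charToRaw(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(model_magic), con)
  writeBin(length(meta_raw), con, size = 4, endian = "little")
  writeBin(meta_raw, con)
  writeBin(serialize(model, NULL), con)
  invisible(path)
}

#' @rdname save_model
#' @export
model_info <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", n = nchar(model_magic)))
  if (!identical(magic, model_magic))
    abort(sprintf("not a sleepstager model file: %s", path))
  len <- readBin(con, "integer", size = 4, endian = "little")
  if (length(len) != 1 || is.na(len) || len <= 0 || len > 1e7)
    abort("corrupted model file: bad metadata header")
  meta <- tryCatch(
    jsonlite::fromJSON(rawToChar(readBin(con, "raw", n = len)), simplifyVector = TRUE),
    error = function(e) abort("corrupted model file: unreadable metadata"))
  if (!identical(meta$format, "sleepstager-model"))
    abort("corrupted model file: wrong format tag")
  meta
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  meta <- model_info(path)
  if (meta$version != 1L)
    abort(sprintf("unsupported model file version %s", meta$version))
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = nchar(model_magic))
  len <- readBin(con, "integer", size = 4, endian = "little")
  readBin(con, "raw", n = len)
  payload <- readBin(con, "raw", n = file.size(path))
  model <- tryCatch(unserialize(payload),
                    error = function(e) abort("corrupted model file: payload unreadable"))
  if (!inherits(model, "sleep_model")) abort("corrupted model file: not a sleep_model")
  model
}
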