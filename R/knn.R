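# In-package k-nearest-neighbour classifier supporting uniform and
# inverse-distance vote weights and euclidean/manhattan metrics, with
# deterministic tie-breaking (nearer neighbour first, then lower training
# index; vote ties resolve to the earlier class in the stored class
# order).

knn_fit <- function(x, y, n_neighbors = 5, weights = "uniform",
                    metric = "euclidean", classes = NULL) {
  x <- as.matrix(x)
  y <- as.character(y)
  stopifnot(nrow(x) == length(y), n_neighbors >= 1)
  classes <- classes %||% sort(unique(y))
  structure(list(x = x, y = y, classes = classes,
                 n_neighbors = as.integer(n_neighbors),
                 weights = match.arg(weights, c("uniform", "distance")),
                 metric = match.arg(metric, c("euclidean", "manhattan"))),
            class = "knn_fit")
}

knn_distance <- function(test, train, metric) {
  test <- as.matrix(test); train <- as.matrix(train)
  if (metric == "euclidean") {
    d2 <- outer(rowSums(test^2), rowSums(train^2), "+") - 2 * tcrossprod(test, train)
    sqrt(pmax(d2, 0))
  } else {
    d <- matrix(0, nrow(test), nrow(train))
    for (j in seq_len(ncol(test)))
      d <- d + abs(outer(test[, j], train[, j], "-"))
    d
  }
}

# ordered neighbour indices (columns = rank 1..k_max) for each test row
knn_neighbours <- function(dist_mat, k_max) {
  nbr <- apply(dist_mat, 1, function(d) order(d)[seq_len(k_max)])
  # apply() drops to a vector when k_max == 1
  if (is.matrix(nbr)) t(nbr) else matrix(nbr, ncol = 1)
}

knn_vote <- function(dist_mat, nbr, y, classes, k, weights) {
  n <- nrow(dist_mat)
  out <- character(n)
  for (i in seq_len(n)) {
    idx <- nbr[i, seq_len(k)]
    d <- dist_mat[i, idx]
    if (weights == "uniform") {
      w <- rep(1, k)
    } else if (any(d == 0)) {
      w <- as.numeric(d == 0)  # exact matches dominate, as is conventional
    } else {
      w <- 1 / d
    }
    tot <- vapply(classes, function(cl) sum(w[y[idx] == cl]), numeric(1))
    out[i] <- classes[which.max(tot)]
  }
  out
}

#' @export
predict.knn_fit <- function(object, newdata, ...) {
  d <- knn_distance(as.matrix(newdata), object$x, object$metric)
  nbr <- knn_neighbours(d, object$n_neighbors)
  factor(knn_vote(d, nbr, object$y, object$classes, object$n_neighbors,
                  object$weights),
         levels = object$classes)
}
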