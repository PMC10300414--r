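# In-package multilayer perceptron classifier: ReLU hidden layers,
# softmax output, cross-entropy loss, minibatch Adam optimization.
# Glorot-uniform initialization from a seeded RNG makes fits
# reproducible.  Training runs at most `max_iter` epochs and stops early
# when the training loss has not improved by more than `tol` for
# `n_iter_no_change` consecutive epochs.

mlp_fit <- function(x, y, hidden = c(32), classes = NULL, seed = 0L,
                    max_iter = 200L, learning_rate = 1e-3, batch_size = 200L,
                    alpha = 1e-4, tol = 1e-4, n_iter_no_change = 10L) {
  x <- as.matrix(x)
  y <- as.character(y)
  classes <- classes %||% sort(unique(y))
  n <- nrow(x); p <- ncol(x); k <- length(classes)
  yi <- match(y, classes)
  target <- matrix(0, n, k); target[cbind(seq_len(n), yi)] <- 1

  rng <- local({ set.seed(seed); .Random.seed })
  old <- .Random.seed_restore(rng)
  on.exit(old(), add = TRUE)

  sizes <- c(p, hidden, k)
  L <- length(sizes) - 1
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    lim <- sqrt(6 / (sizes[l] + sizes[l + 1]))
    W[[l]] <- matrix(runif(sizes[l] * sizes[l + 1], -lim, lim), sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(bb) bb * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; tstep <- 0

  batch_size <- min(batch_size, n)
  best_loss <- Inf; stall <- 0L
  for (epoch in seq_len(max_iter)) {
    perm <- sample.int(n)
    epoch_loss <- 0
    for (start in seq(1, n, by = batch_size)) {
      idx <- perm[start:min(start + batch_size - 1, n)]
      xb <- x[idx, , drop = FALSE]; tb <- target[idx, , drop = FALSE]
      # forward
      act <- vector("list", L + 1); act[[1]] <- xb
      for (l in seq_len(L)) {
        z <- sweep(act[[l]] %*% W[[l]], 2, b[[l]], "+")
        act[[l + 1]] <- if (l < L) pmax(z, 0) else softmax_rows(z)
      }
      probs <- act[[L + 1]]
      epoch_loss <- epoch_loss -
        sum(tb * log(pmax(probs, 1e-12))) +
        0.5 * alpha * sum(vapply(W, function(w) sum(w^2), numeric(1))) *
          length(idx) / n
      # backward
      delta <- (probs - tb) / length(idx)
      for (l in rev(seq_len(L))) {
        gW <- crossprod(act[[l]], delta) + alpha * W[[l]] / n
        gb <- colSums(delta)
        if (l > 1) delta <- (delta %*% t(W[[l]])) * (act[[l]] > 0)
        tstep <- tstep + 1
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        corr1 <- 1 - beta1^tstep; corr2 <- 1 - beta2^tstep
        W[[l]] <- W[[l]] - learning_rate * (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + eps)
        b[[l]] <- b[[l]] - learning_rate * (mb[[l]] / corr1) / (sqrt(vb[[l]] / corr2) + eps)
      }
    }
    epoch_loss <- epoch_loss / n
    if (epoch_loss < best_loss - tol) { best_loss <- epoch_loss; stall <- 0L }
    else stall <- stall + 1L
    if (stall >= n_iter_no_change) break
  }
  structure(list(W = W, b = b, classes = classes, hidden = hidden,
                 n_iter = epoch, loss = epoch_loss),
            class = "mlp_fit")
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

# run fn under a temporarily seeded RNG stream, restoring global state
.Random.seed_restore <- function(new_seed) {
  prev <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", new_seed, globalenv())
  function() {
    if (is.null(prev)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", prev, globalenv())
  }
}

#' @export
predict.mlp_fit <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  a <- as.matrix(newdata)
  L <- length(object$W)
  for (l in seq_len(L)) {
    z <- sweep(a %*% object$W[[l]], 2, object$b[[l]], "+")
    a <- if (l < L) pmax(z, 0) else softmax_rows(z)
  }
  colnames(a) <- object$classes
  if (type == "prob") return(a)
  factor(object$classes[max.col(a, ties.method = "first")],
         levels = object$classes)
}
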