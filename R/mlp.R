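# Small fully-connected multilayer perceptron for the room classifier:
# ReLU hidden layers, softmax output, cross-entropy loss with L2 penalty,
# full-batch training with either an adaptive-moment solver ("adam") or
# gradient descent with classical momentum ("sgd").

relu <- function(z) pmax(z, 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

mlp_forward <- function(net, x) {
  a <- list(x)
  L <- length(net$W)
  for (l in seq_len(L)) {
    z <- a[[l]] %*% net$W[[l]] + matrix(net$b[[l]], nrow(x), length(net$b[[l]]), byrow = TRUE)
    a[[l + 1]] <- if (l < L) relu(z) else softmax_rows(z)
  }
  a
}

#' Fit a multilayer perceptron classifier
#'
#' Three ReLU hidden layers of 10 nodes by default, softmax output trained by
#' full-batch minimisation of the cross-entropy with a small L2 penalty.
#' Solvers: `"adam"` (adaptive moments) or `"sgd"` (gradient descent with
#' classical momentum). Training is deterministic given `seed`.
#'
#' @param x numeric matrix (n x d) of features.
#' @param y factor of class labels (length n).
#' @param hidden integer vector of hidden-layer widths.
#' @param solver `"adam"` or `"sgd"`.
#' @param learning_rate step size.
#' @param momentum momentum coefficient (sgd only; ignored by adam).
#' @param alpha L2 penalty weight.
#' @param max_epochs maximum number of full-batch epochs.
#' @param tol minimum loss improvement counted as progress.
#' @param patience epochs without progress before early stop.
#' @param seed RNG seed for weight initialisation.
#' @return object of class `mlp` with weights, class levels and the loss trace.
#' @export
fit_mlp <- function(x, y, hidden = c(10, 10, 10), solver = c("adam", "sgd"),
                    learning_rate = 1e-2, momentum = 0.9, alpha = 1e-4,
                    max_epochs = 400, tol = 1e-5, patience = 30, seed = 1) {
  solver <- match.arg(solver)
  x <- as.matrix(x)
  y <- factor(y)
  lev <- levels(y)
  n <- nrow(x)
  sizes <- c(ncol(x), hidden, length(lev))
  L <- length(sizes) - 1L

  set.seed(seed)
  W <- lapply(seq_len(L), function(l) {
    matrix(rnorm(sizes[l] * sizes[l + 1], 0, sqrt(2 / sizes[l])), sizes[l], sizes[l + 1])
  })
  b <- lapply(seq_len(L), function(l) rep(0, sizes[l + 1]))
  tmat <- diag(length(lev))[as.integer(y), , drop = FALSE]

  vW <- lapply(W, function(w) w * 0); vb <- lapply(b, function(v) v * 0)
  mW <- vW; mb <- vb; sW <- vW; sb <- vb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best <- Inf; stall <- 0L; trace <- numeric(0)

  for (epoch in seq_len(max_epochs)) {
    a <- mlp_forward(list(W = W, b = b), x)
    p <- a[[L + 1]]
    loss <- -mean(log(pmax(rowSums(p * tmat), 1e-12))) +
      alpha / 2 * sum(vapply(W, function(w) sum(w^2), numeric(1))) / n
    trace <- c(trace, loss)
    if (loss < best - tol) { best <- loss; stall <- 0L } else stall <- stall + 1L
    if (stall >= patience) break

    delta <- (p - tmat) / n
    for (l in rev(seq_len(L))) {
      gW <- crossprod(a[[l]], delta) + alpha * W[[l]] / n
      gb <- colSums(delta)
      if (l > 1) {
        delta <- (delta %*% t(W[[l]])) * (a[[l]] > 0)
      }
      if (solver == "adam") {
        mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
        sW[[l]] <- b2 * sW[[l]] + (1 - b2) * gW^2
        mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb
        sb[[l]] <- b2 * sb[[l]] + (1 - b2) * gb^2
        mhW <- mW[[l]] / (1 - b1^epoch); shW <- sW[[l]] / (1 - b2^epoch)
        mhb <- mb[[l]] / (1 - b1^epoch); shb <- sb[[l]] / (1 - b2^epoch)
        W[[l]] <- W[[l]] - learning_rate * mhW / (sqrt(shW) + eps)
        b[[l]] <- b[[l]] - learning_rate * mhb / (sqrt(shb) + eps)
      } else {
        vW[[l]] <- momentum * vW[[l]] - learning_rate * gW
        vb[[l]] <- momentum * vb[[l]] - learning_rate * gb
        W[[l]] <- W[[l]] + vW[[l]]
        b[[l]] <- b[[l]] + vb[[l]]
      }
    }
  }
  structure(list(W = W, b = b, levels = lev, hidden = hidden, solver = solver,
                 learning_rate = learning_rate, momentum = momentum,
                 epochs_run = length(trace), loss = trace),
            class = "mlp")
}

#' Predict from a fitted MLP
#' @param object an `mlp`.
#' @param newdata numeric matrix of features.
#' @param type `"class"` for labels (ties broken towards the lexicographically
#'   lowest label) or `"prob"` for the softmax matrix.
#' @param ... unused.
#' @return factor of labels or probability matrix.
#' @export
predict.mlp <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  p <- mlp_forward(object, as.matrix(newdata))[[length(object$W) + 1]]
  colnames(p) <- object$levels
  if (type == "prob") return(p)
  # levels are stored sorted; max.col "first" therefore resolves ties to the
  # lexicographically lowest label
  factor(object$levels[max.col(p, ties.method = "first")], levels = object$levels)
}
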