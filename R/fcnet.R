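# A compact 4-layer fully connected network: input -> 64 -> 32 -> softmax.
# Trained full-batch with Adam on the cross-entropy loss. Only the two
# tunable hyperparameters (training passes and Adam learning rate) are
# exposed to the model-selection loop; the architecture is fixed.

fcnet_init <- function(p, h1, h2, n_class) {
  he <- function(nin, nout) matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)),
                                   nin, nout)
  list(W1 = he(p, h1), b1 = rep(0, h1),
       W2 = he(h1, h2), b2 = rep(0, h2),
       W3 = he(h2, n_class), b3 = rep(0, n_class))
}

fcnet_forward <- function(par, X) {
  A1 <- pmax(sweep(X %*% par$W1, 2L, par$b1, "+"), 0)
  A2 <- pmax(sweep(A1 %*% par$W2, 2L, par$b2, "+"), 0)
  Z3 <- sweep(A2 %*% par$W3, 2L, par$b3, "+")
  Z3 <- Z3 - apply(Z3, 1L, max)              # stabilised softmax
  E <- exp(Z3)
  list(A1 = A1, A2 = A2, P = E / rowSums(E))
}

#' Fit the compact fully connected network classifier
#'
#' Four layers (input, two hidden rectified-linear layers of width 64 and
#' 32, softmax output) trained with full-batch Adam on cross-entropy. The
#' fit is deterministic given `seed`.
#'
#' @param X Numeric matrix, subjects x features (already standardised).
#' @param y Factor of class labels.
#' @param epochs Number of training passes over the data (default 100).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param hidden Widths of the two hidden layers (default `c(64, 32)`).
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `fcnet`.
#' @export
fcnet_fit <- function(X, y, epochs = 100L, learning_rate = 1e-3,
                      hidden = c(64L, 32L), seed = 1L) {
  X <- as.matrix(X); y <- droplevels(as.factor(y))
  n <- nrow(X); p <- ncol(X); K <- nlevels(y)
  if (K < 2L) stop("need at least two classes")
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), as.integer(y))] <- 1
  par <- with_seed(seed, fcnet_init(p, hidden[1L], hidden[2L], K))
  m <- lapply(par, function(w) w * 0)        # Adam first moment
  v <- lapply(par, function(w) w * 0)        # Adam second moment
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (t in seq_len(epochs)) {
    fw <- fcnet_forward(par, X)
    dZ3 <- (fw$P - Y) / n
    g <- list(W3 = t(fw$A2) %*% dZ3, b3 = colSums(dZ3))
    dA2 <- dZ3 %*% t(par$W3); dZ2 <- dA2 * (fw$A2 > 0)
    g$W2 <- t(fw$A1) %*% dZ2; g$b2 <- colSums(dZ2)
    dA1 <- dZ2 %*% t(par$W2); dZ1 <- dA1 * (fw$A1 > 0)
    g$W1 <- t(X) %*% dZ1; g$b1 <- colSums(dZ1)
    for (k in names(par)) {
      m[[k]] <- b1 * m[[k]] + (1 - b1) * g[[k]]
      v[[k]] <- b2 * v[[k]] + (1 - b2) * g[[k]]^2
      mhat <- m[[k]] / (1 - b1^t)
      vhat <- v[[k]] / (1 - b2^t)
      par[[k]] <- par[[k]] - learning_rate * mhat / (sqrt(vhat) + eps)
    }
  }
  structure(list(par = par, levels = levels(y), epochs = epochs,
                 learning_rate = learning_rate, hidden = hidden,
                 seed = seed),
            class = "fcnet")
}

#' @rdname fcnet_fit
#' @param object A fitted `fcnet`.
#' @param newdata Matrix of features on the training scale.
#' @param ... Unused.
#' @return `predict()` returns a subjects x classes matrix of softmax
#'   probabilities.
#' @export
predict.fcnet <- function(object, newdata, ...) {
  P <- fcnet_forward(object$par, as.matrix(newdata))$P
  colnames(P) <- object$levels
  P
}

#' @export
print.fcnet <- function(x, ...) {
  cat(sprintf("fcnet: %d-%d-%d-%d fully connected network (%d passes, lr %g)\n",
              nrow(x$par$W1), x$hidden[1L], x$hidden[2L], length(x$levels),
              x$epochs, x$learning_rate))
  invisible(x)
}
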