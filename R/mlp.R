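# Single-hidden-layer perceptron with rectifier activation, sigmoid output,
# cross-entropy loss (+ optional L2 penalty on weights), trained full-batch
# with Adam. Kept self-contained so the ensemble stages have exactly the
# architecture they specify: one ReLU hidden layer, cross entropy, L2.

#' Fit a one-hidden-layer ReLU network
#'
#' Binary classifier: `p(x) = sigmoid(relu(x W1 + b1) w2 + b2)`, minimizing
#' mean cross entropy plus `l2/(2n) * (||W1||^2 + ||w2||^2)` (biases are not
#' penalized) by full-batch Adam. Deterministic given `seed`.
#'
#' @param x numeric matrix (n x d) of inputs (scale them first; see
#'   [fit_scaler()]).
#' @param y binary 0/1 response of length n.
#' @param hidden hidden-layer width (>= 1).
#' @param l2 L2 penalty coefficient (>= 0).
#' @param epochs number of Adam steps (full batch).
#' @param lr Adam learning rate.
#' @param seed integer seed for the weight initialization.
#' @return object of class `mlp_model`.
#' @export
mlp_fit <- function(x, y, hidden, l2 = 0, epochs = 300L, lr = 0.01, seed = 1L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(x), all(y %in% c(0, 1)))
  if (hidden < 1L) stop("hidden size must be >= 1")
  if (l2 < 0) stop("l2 must be >= 0")
  n <- nrow(x); d <- ncol(x)
  set.seed(as.integer(seed))
  # He initialization for the rectifier layer
  W1 <- matrix(rnorm(d * hidden, sd = sqrt(2 / max(d, 1))), d, hidden)
  b1 <- numeric(hidden)
  w2 <- matrix(rnorm(hidden, sd = sqrt(2 / hidden)), hidden, 1)
  b2 <- 0
  params <- list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
  mom <- lapply(params, function(p) p * 0)
  vel <- mom
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  for (t in seq_len(epochs)) {
    g <- mlp_grad(params, x, y, l2)
    for (nm in names(params)) {
      mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * g[[nm]]
      vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * g[[nm]]^2
      mhat <- mom[[nm]] / (1 - beta1^t)
      vhat <- vel[[nm]] / (1 - beta2^t)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  structure(c(params, list(hidden = hidden, l2 = l2, epochs = epochs, lr = lr)),
            class = "mlp_model")
}

mlp_forward <- function(params, x) {
  h <- x %*% params$W1
  h <- sweep(h, 2, params$b1, "+")
  h[h < 0] <- 0
  z <- drop(h %*% params$w2) + params$b2
  list(h = h, p = 1 / (1 + exp(-z)))
}

mlp_loss <- function(params, x, y, l2) {
  p <- mlp_forward(params, x)$p
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  ce <- -mean(y * log(p) + (1 - y) * log(1 - p))
  ce + l2 / (2 * length(y)) * (sum(params$W1^2) + sum(params$w2^2))
}

mlp_grad <- function(params, x, y, l2) {
  n <- length(y)
  fw <- mlp_forward(params, x)
  dz <- (fw$p - y) / n                       # d(ce)/dz for sigmoid + CE
  dw2 <- crossprod(fw$h, dz) + (l2 / n) * params$w2
  db2 <- sum(dz)
  dh <- (dz %*% t(params$w2)) * (fw$h > 0)   # rectifier gate
  dW1 <- crossprod(x, dh) + (l2 / n) * params$W1
  db1 <- colSums(dh)
  list(W1 = dW1, b1 = db1, w2 = dw2, b2 = db2)
}

#' Predict probabilities from a fitted MLP
#'
#' @param model an [mlp_fit()] result.
#' @param x input matrix with the same columns used for fitting.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
mlp_predict <- function(model, x) {
  stopifnot(inherits(model, "mlp_model"))
  unname(mlp_forward(model, as.matrix(x))$p)
}

#' Fit / apply a column scaler
#'
#' Per-column z-scoring fitted on training data only; zero-variance columns
#' are centered but left unscaled.
#'
#' @param x training matrix.
#' @return a `scaler` object for [apply_scaler()].
#' @export
fit_scaler <- function(x) {
  mu <- colMeans(x)
  sig <- apply(x, 2, sd)
  sig[!is.finite(sig) | sig < 1e-12] <- 1
  structure(list(center = mu, scale = sig), class = "scaler")
}

#' @rdname fit_scaler
#' @param scaler a fitted scaler.
#' @param newx matrix to transform.
#' @export
apply_scaler <- function(scaler, newx) {
  stopifnot(inherits(scaler, "scaler"))
  sweep(sweep(as.matrix(newx), 2, scaler$center), 2, scaler$scale, "/")
}
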