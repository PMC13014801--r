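# Symbolic neural networks: three-layer networks whose activation units are
# arithmetic operations (identity, product, power, bounded division) with a
# sigmoid head, so that a pruned network reads as a closed-form expression.
#
# Layer shapes are fixed: 5 pre-activation units feeding 3 outputs in layers 1
# and 2, and a single sigmoid output unit. Layer 1 activations are
# (z1, z2*z3, (|z4|+eps)^z5); layer 2 activations are
# (z1, z2*z3, z4/(|z5|+1)); the head is sigmoid. The small eps guard on the
# power base keeps the unit (and its gradient) finite at base zero.

POWER_EPS <- 1e-8

#' Symbolic network configuration
#'
#' @param n_inputs Length of the covariate input vector.
#' @return A `snnm_snn_config` object with the fixed layer widths (5, 5, 1).
#' @export
snnConfig <- function(n_inputs) {
  if (n_inputs < 1) stopf("n_inputs must be >= 1")
  structure(list(n_inputs = as.integer(n_inputs), widths = c(5L, 5L, 1L)),
            class = "snnm_snn_config")
}

#' Initialize dense network parameters
#'
#' Weights are drawn uniformly on (-scale, scale), biases start at zero, and
#' the prune mask is all-active. The sigmoid head of a fresh network therefore
#' sits near 0.5 before the row bound is applied.
#'
#' @param config A [snnConfig()].
#' @param seed Integer seed (use `NULL` to draw from the current RNG stream).
#' @param scale Half-width of the uniform weight initialization.
#' @return A `snnm_snn_params` object: weight/bias arrays plus a binary
#'   `mask` of identical shapes.
#' @export
snnInit <- function(config, seed = NULL, scale = 0.1) {
  if (!is.null(seed)) {
    old <- .Random.seed_exists(); on.exit(restore_rng(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  np <- config$n_inputs
  params <- list(
    W1 = matrix(stats::runif(5 * np, -scale, scale), 5, np),
    b1 = numeric(5),
    W2 = matrix(stats::runif(15, -scale, scale), 5, 3),
    b2 = numeric(5),
    W3 = stats::runif(3, -scale, scale),
    b3 = 0
  )
  mask <- list(W1 = matrix(1, 5, np), b1 = rep(1, 5), W2 = matrix(1, 5, 3),
               b2 = rep(1, 5), W3 = rep(1, 3), b3 = 1)
  structure(list(params = params, mask = mask, config = config),
            class = "snnm_snn_params")
}

# Flat layout (must match src/snn_likelihood.cpp): W1 column-major, b1,
# W2 column-major, b2, W3, b3.
flattenSnn <- function(x) {
  c(as.vector(x$W1), x$b1, as.vector(x$W2), x$b2, x$W3, x$b3)
}

unflattenSnn <- function(theta, config) {
  np <- config$n_inputs
  stopifnot(length(theta) == 5 * np + 29)
  i <- 0
  take <- function(n) { v <- theta[(i + 1):(i + n)]; i <<- i + n; v }
  list(
    W1 = matrix(take(5 * np), 5, np), b1 = take(5),
    W2 = matrix(take(15), 5, 3), b2 = take(5),
    W3 = take(3), b3 = take(1)
  )
}

# Layer labels for each flat index, used in salience reports and tie-breaking.
snnParamLabels <- function(config) {
  np <- config$n_inputs
  c(sprintf("W1[%d,%d]", rep(1:5, np), rep(seq_len(np), each = 5)),
    sprintf("b1[%d]", 1:5),
    sprintf("W2[%d,%d]", rep(1:5, 3), rep(1:3, each = 5)),
    sprintf("b2[%d]", 1:5),
    sprintf("W3[%d]", 1:3), "b3")
}

#' Count active (unmasked) parameters
#'
#' @param snn A `snnm_snn_params` object.
#' @return Number of unmasked weights and biases.
#' @export
countActiveParameters <- function(snn) {
  as.integer(sum(vapply(snn$mask, sum, 0)))
}

#' Forward pass of a symbolic network
#'
#' Evaluates the masked network on one covariate vector or on a matrix of
#' vectors (one per row). The output is a transition probability strictly
#' inside (0, 1).
#'
#' @param snn A `snnm_snn_params` object.
#' @param phi Numeric vector of length `n_inputs`, or a matrix with
#'   `n_inputs` columns.
#' @return Numeric vector of probabilities, one per input row.
#' @export
snnForward <- function(snn, phi) {
  p <- snn$params; m <- snn$mask
  W1 <- p$W1 * m$W1; b1 <- p$b1 * m$b1
  W2 <- p$W2 * m$W2; b2 <- p$b2 * m$b2
  W3 <- p$W3 * m$W3; b3 <- p$b3 * m$b3
  if (is.null(dim(phi))) phi <- matrix(phi, 1)
  if (ncol(phi) != snn$config$n_inputs)
    stopf("phi has %d columns; network expects %d", ncol(phi), snn$config$n_inputs)
  Z1 <- phi %*% t(W1) + matrix(b1, nrow(phi), 5, byrow = TRUE)
  X2 <- cbind(Z1[, 1], Z1[, 2] * Z1[, 3], (abs(Z1[, 4]) + POWER_EPS)^Z1[, 5])
  if (any(!is.finite(X2[, 3]))) stopf("non-finite value in the layer-1 power unit")
  Z2 <- X2 %*% t(W2) + matrix(b2, nrow(phi), 5, byrow = TRUE)
  X3 <- cbind(Z2[, 1], Z2[, 2] * Z2[, 3], Z2[, 4] / (abs(Z2[, 5]) + 1))
  if (any(!is.finite(X3))) stopf("non-finite value in a layer-2 unit")
  z3 <- drop(X3 %*% W3) + b3
  # keep the head strictly inside (0,1) under floating-point saturation
  pmin(pmax(sigm(z3), 1e-300), 1 - 1e-12)
}

#' @export
print.snnm_snn_params <- function(x, ...) {
  cat(sprintf("<snnm_snn_params> %d inputs, %d/%d parameters active\n",
              x$config$n_inputs, countActiveParameters(x),
              5 * x$config$n_inputs + 29))
  invisible(x)
}
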