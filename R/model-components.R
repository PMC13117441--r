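#' Build the primary regressor
#'
#' The deployable forecaster: a multilayer perceptron mapping a history window
#' of `n` scaled glucose values to an `m`-step prediction-horizon sequence.
#' Architecture: input layer, 50-unit dense layer, 20-unit dense layer and an
#' `m`-unit dense output layer, ReLU activations throughout (so outputs are
#' always non-negative, matching the [0,1] min-max scaling of the targets).
#' Weights use seeded Glorot-style uniform initialisation, so the same seed
#' always yields identical initial weights.
#'
#' @param n history length in samples (>= 1).
#' @param m prediction-horizon length in samples (>= 1).
#' @param seed integer seed for weight initialisation.
#' @return A `regressor_model`. Parameter count is
#'   `50*(n+1) + 20*51 + m*21` (1,796 for n = 12, m = 6).
#' @export
build_primary_regressor <- function(n, m, seed = 1L) {
  n <- as.integer(n)
  m <- as.integer(m)
  if (n < 1L || m < 1L) stop("n and m must be positive", call. = FALSE)
  net <- mlp_init(c(n, 50L, 20L, m), seed)
  structure(
    list(input_len = n, output_len = m, net = net, seed = as.integer(seed), role = "primary"),
    class = "regressor_model"
  )
}

#' Build the auxiliary regressor
#'
#' Identical architecture to the primary regressor except that its input is
#' the concatenation of the history window and the primary regressor's
#' predicted horizon (width `n + m`); it forecasts the post-horizon segment of
#' length `m`. During CL/ACL training its loss is backpropagated through the
#' predicted horizon into the primary regressor.
#'
#' @inheritParams build_primary_regressor
#' @return A `regressor_model` with input width `n + m` (parameter count 2,096
#'   for n = 12, m = 6).
#' @export
build_auxiliary_regressor <- function(n, m, seed = 1L) {
  n <- as.integer(n)
  m <- as.integer(m)
  if (n < 1L || m < 1L) stop("n and m must be positive", call. = FALSE)
  net <- mlp_init(c(n + m, 50L, 20L, m), seed)
  structure(
    list(input_len = n + m, output_len = m, net = net, seed = as.integer(seed), role = "auxiliary"),
    class = "regressor_model"
  )
}

#' Build the auxiliary discriminator
#'
#' A 1-D convolutional classifier that judges whether the horizon segment
#' inside a full (history, horizon, post-horizon) sequence of length `n + 2m`
#' is real or predicted. Architecture: 20-filter Conv1D, 10-filter Conv1D
#' (kernel 3, stride 1, no padding, ReLU) and a single sigmoid output unit;
#' trained with binary cross-entropy.
#'
#' @inheritParams build_primary_regressor
#' @param kernel convolution kernel width (default 3, the minimal nontrivial
#'   choice; recorded in the model so it can be varied).
#' @return A `discriminator_model` accepting inputs of length `n + 2m` and
#'   returning a scalar probability in (0, 1).
#' @export
build_discriminator <- function(n, m, seed = 1L, kernel = 3L) {
  n <- as.integer(n)
  m <- as.integer(m)
  if (n < 1L || m < 1L) stop("n and m must be positive", call. = FALSE)
  net <- conv_net_init(n + 2L * m, seed, kernel = as.integer(kernel))
  structure(
    list(input_len = n + 2L * m, n = n, m = m, net = net, seed = as.integer(seed)),
    class = "discriminator_model"
  )
}

#' Count trainable parameters
#'
#' @param model a `regressor_model` or `discriminator_model`.
#' @return Integer number of trainable scalars.
#' @export
count_parameters <- function(model) {
  params <- if (inherits(model, "regressor_model")) {
    mlp_params(model$net)
  } else if (inherits(model, "discriminator_model")) {
    conv_net_params(model$net)
  } else {
    stop("unsupported model type", call. = FALSE)
  }
  sum(vapply(params, length, integer(1)))
}

#' Forward pass of a regressor
#'
#' @param object a `regressor_model`.
#' @param newdata numeric matrix (N x input_len) or vector of length
#'   `input_len`, on the scaled range used in training.
#' @param ... unused.
#' @return N x output_len matrix of non-negative predictions.
#' @export
predict.regressor_model <- function(object, newdata, ...) {
  X <- as_input_matrix(newdata, object$input_len)
  mlp_forward(object$net, X)$output
}

#' Forward pass of the discriminator
#'
#' @param object a `discriminator_model`.
#' @param newdata numeric matrix (N x input_len) or vector.
#' @param ... unused.
#' @return Numeric vector of probabilities in (0, 1), one per row.
#' @export
predict.discriminator_model <- function(object, newdata, ...) {
  X <- as_input_matrix(newdata, object$input_len)
  conv_net_forward(object$net, X)$prob
}

as_input_matrix <- function(x, width) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != width) {
    stop(sprintf("input width %d does not match expected %d", ncol(x), width),
      call. = FALSE
    )
  }
  x
}

#' @export
print.regressor_model <- function(x, ...) {
  cat(sprintf(
    "<%s regressor> %d -> 50 -> 20 -> %d (ReLU), %d parameters\n",
    x$role, x$input_len, x$output_len, count_parameters(x)
  ))
  invisible(x)
}

#' @export
print.discriminator_model <- function(x, ...) {
  cat(sprintf(
    "<discriminator> input %d -> Conv1D(20) -> Conv1D(10) -> sigmoid, %d parameters\n",
    x$input_len, count_parameters(x)
  ))
  invisible(x)
}
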