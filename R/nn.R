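# Compact neural-network primitives used by the learning frameworks.
#
# The component networks are small (a few thousand parameters), so forward
# and backward passes are written directly as base-R matrix algebra: dense
# layers as GEMMs, 1-D convolutions via an im2col expansion. No dropout or
# batch normalisation anywhere, so a forward pass is a pure function of
# (weights, input) and training is bitwise reproducible under a seed.

relu <- function(z) {
  z[z < 0] <- 0
  z
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Glorot-style uniform initialisation: U(-l, l), l = sqrt(6 / (fan_in + fan_out)).
glorot_uniform <- function(nrow, ncol, fan_in = nrow, fan_out = ncol) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow = nrow, ncol = ncol)
}

add_bias <- function(Z, b) sweep(Z, 2L, b, `+`)

# ---- fully connected ReLU network ------------------------------------------

# Biases start positive: with ReLU on every layer (including the output) a
# unit whose pre-activation goes negative for all inputs receives no gradient
# and is dead for good. Hidden biases start at 0.1; the output bias starts at
# 0.5, the midpoint of the [0,1]-scaled target range, so output units keep a
# positive margin while the weights adapt.
mlp_init <- function(sizes, seed, bias_init = 0.1, output_bias_init = 0.5) {
  with_seed(seed, {
    L <- length(sizes) - 1L
    W <- vector("list", L)
    b <- vector("list", L)
    for (l in seq_len(L)) {
      W[[l]] <- glorot_uniform(sizes[l], sizes[l + 1L])
      b[[l]] <- rep(if (l == L) output_bias_init else bias_init, sizes[l + 1L])
    }
    list(sizes = sizes, W = W, b = b)
  })
}

# X: N x sizes[1]. All layers (including the output) use ReLU.
mlp_forward <- function(net, X) {
  L <- length(net$W)
  A <- vector("list", L + 1L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    A[[l + 1L]] <- relu(add_bias(A[[l]] %*% net$W[[l]], net$b[[l]]))
  }
  list(output = A[[L + 1L]], activations = A)
}

# dY: gradient of the loss w.r.t. the network output.
# Returns parameter gradients and the gradient w.r.t. the input.
mlp_backward <- function(net, cache, dY) {
  L <- length(net$W)
  A <- cache$activations
  dW <- vector("list", L)
  db <- vector("list", L)
  delta <- dY * (A[[L + 1L]] > 0)
  for (l in L:1) {
    dW[[l]] <- crossprod(A[[l]], delta)
    db[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(net$W[[l]])) * (A[[l]] > 0)
    } else {
      dX <- delta %*% t(net$W[[l]])
    }
  }
  list(dW = dW, db = db, dX = dX)
}

mlp_params <- function(net) c(net$W, net$b)
mlp_set_params <- function(net, params) {
  L <- length(net$W)
  net$W <- params[seq_len(L)]
  net$b <- params[L + seq_len(L)]
  net
}

# ---- 1-D convolutional discriminator ---------------------------------------
# input (length L, 1 channel) -> Conv1D(20 filters, kernel 3) -> ReLU
# -> Conv1D(10 filters, kernel 3) -> ReLU -> flatten -> dense 1 -> sigmoid

conv_net_init <- function(input_len, seed, filters1 = 20L, filters2 = 10L, kernel = 3L) {
  if (input_len < 2L * (kernel - 1L) + 1L) {
    stop("input too short for two unpadded convolutions", call. = FALSE)
  }
  p1 <- input_len - kernel + 1L
  p2 <- p1 - kernel + 1L
  with_seed(seed, {
    list(
      input_len = input_len, kernel = kernel,
      filters1 = filters1, filters2 = filters2, p1 = p1, p2 = p2,
      K1 = glorot_uniform(kernel, filters1,
        fan_in = kernel, fan_out = kernel * filters1
      ),
      b1 = numeric(filters1),
      K2 = glorot_uniform(kernel * filters1, filters2,
        fan_in = kernel * filters1, fan_out = kernel * filters2
      ),
      b2 = numeric(filters2),
      W3 = glorot_uniform(p2 * filters2, 1L),
      b3 = 0
    )
  })
}

# im2col for a single-channel sequence: rows indexed (sample, position),
# sample fastest; columns are the kernel offsets.
im2col1 <- function(X, kernel, positions) {
  do.call(cbind, lapply(seq_len(kernel), function(o) {
    as.vector(X[, o:(o + positions - 1L), drop = FALSE])
  }))
}

conv_net_forward <- function(net, X) {
  N <- nrow(X)
  k <- net$kernel
  # layer 1
  A1 <- im2col1(X, k, net$p1) # (N*p1) x k
  H1 <- relu(add_bias(A1 %*% net$K1, net$b1)) # (N*p1) x f1, rows (i, p)
  # layer 2: patches over positions with channels; for offset o the rows of
  # H1 with position p in o..(o+p2-1) form a contiguous block
  A2 <- do.call(cbind, lapply(seq_len(k), function(o) {
    H1[((o - 1L) * N + 1L):((o + net$p2 - 1L) * N), , drop = FALSE]
  })) # (N*p2) x (k*f1)
  H2 <- relu(add_bias(A2 %*% net$K2, net$b2)) # (N*p2) x f2
  Fl <- matrix(as.vector(H2), nrow = N) # N x (p2*f2), pure reshape
  z <- as.vector(Fl %*% net$W3) + net$b3
  prob <- sigmoid(z)
  list(
    prob = prob,
    cache = list(X = X, A1 = A1, H1 = H1, A2 = A2, H2 = H2, Fl = Fl, N = N)
  )
}

# dz: gradient w.r.t. the pre-sigmoid logit (length N).
conv_net_backward <- function(net, cache, dz) {
  N <- cache$N
  k <- net$kernel
  dW3 <- crossprod(cache$Fl, dz)
  db3 <- sum(dz)
  dFl <- tcrossprod(dz, as.vector(net$W3)) # N x (p2*f2)
  dH2 <- matrix(as.vector(dFl), nrow = N * net$p2) * (cache$H2 > 0)
  dK2 <- crossprod(cache$A2, dH2)
  db2 <- colSums(dH2)
  dA2 <- dH2 %*% t(net$K2)
  dH1 <- matrix(0, nrow = N * net$p1, ncol = net$filters1)
  for (o in seq_len(k)) {
    rows <- ((o - 1L) * N + 1L):((o + net$p2 - 1L) * N)
    cols <- (o - 1L) * net$filters1 + seq_len(net$filters1)
    dH1[rows, ] <- dH1[rows, ] + dA2[, cols, drop = FALSE]
  }
  dH1 <- dH1 * (cache$H1 > 0)
  dK1 <- crossprod(cache$A1, dH1)
  db1 <- colSums(dH1)
  dA1 <- dH1 %*% t(net$K1)
  dX <- matrix(0, nrow = N, ncol = net$input_len)
  for (o in seq_len(k)) {
    dX[, o:(o + net$p1 - 1L)] <- dX[, o:(o + net$p1 - 1L)] +
      matrix(dA1[, o], nrow = N)
  }
  list(
    grads = list(dK1, db1, dK2, db2, dW3, db3),
    dX = dX
  )
}

conv_net_params <- function(net) list(net$K1, net$b1, net$K2, net$b2, net$W3, net$b3)
conv_net_set_params <- function(net, params) {
  net$K1 <- params[[1]]
  net$b1 <- params[[2]]
  net$K2 <- params[[3]]
  net$b2 <- params[[4]]
  net$W3 <- params[[5]]
  net$b3 <- params[[6]]
  net
}

# ---- Adam optimiser ---------------------------------------------------------

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(state, params, grads, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    g <- grads[[i]]
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g * g
    params[[i]] <- params[[i]] -
      lr * (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps)
  }
  list(params = params, state = state)
}
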