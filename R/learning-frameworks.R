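#' Training configuration for a learning framework
#'
#' Defaults follow the common optimisation setting used for all four
#' frameworks: Adam, 600 epochs, batch size 128, learning rate 0.002, with
#' the composite loss formed as the unweighted sum of its active components.
#'
#' @param framework one of `"IL"`, `"AL"`, `"CL"`, `"ACL"`.
#' @param epochs number of training epochs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam learning rate.
#' @param seed integer seed governing weight initialisation and batch
#'   shuffling; the same seed always reproduces the identical trained system.
#' @return A list of class `training_config`.
#' @export
training_config <- function(framework = c("IL", "AL", "CL", "ACL"),
                            epochs = 600L, batch_size = 128L,
                            learning_rate = 0.002, seed = 1L) {
  framework <- match.arg(toupper(framework[1]), c("IL", "AL", "CL", "ACL"))
  if (epochs < 0) stop("epochs must be non-negative", call. = FALSE)
  if (batch_size < 1) stop("batch_size must be positive", call. = FALSE)
  if (learning_rate <= 0) stop("learning_rate must be positive", call. = FALSE)
  structure(
    list(
      framework = framework, epochs = as.integer(epochs),
      batch_size = as.integer(batch_size), learning_rate = learning_rate,
      optimiser = "adam", loss_weights = c(1, 1, 1), seed = as.integer(seed)
    ),
    class = "training_config"
  )
}

#' Predictive loss
#'
#' Mean squared error between the predicted and real prediction-horizon
#' sequences, the regression objective shared by all four frameworks.
#'
#' @param pred N x m matrix of predictions.
#' @param target N x m matrix of real values.
#' @return Non-negative scalar; zero iff `pred == target`.
#' @export
predictive_loss <- function(pred, target) {
  pred <- as.matrix(pred)
  target <- as.matrix(target)
  if (!all(dim(pred) == dim(target))) {
    stop("pred and target must have identical dimensions", call. = FALSE)
  }
  mean((pred - target)^2)
}

#' Discriminator loss
#'
#' Binary cross-entropy training signal for the auxiliary discriminator,
#' which is taught to score real sequences as 0 and sequences containing a
#' predicted horizon as 1: `BCE(d_real, 0) + BCE(d_fake, 1)`, each averaged
#' over the batch. Minimal when `d_real -> 0` and `d_fake -> 1`.
#'
#' @param d_real discriminator probabilities on real sequences, in (0, 1).
#' @param d_fake discriminator probabilities on predicted sequences, in (0, 1).
#' @return Non-negative scalar.
#' @export
discriminator_loss <- function(d_real, d_fake) {
  check_prob(d_real)
  check_prob(d_fake)
  mean(-log(1 - d_real)) + mean(-log(d_fake))
}

#' Adversarial loss of the primary regressor
#'
#' The generator-side objective: the primary regressor is rewarded when the
#' discriminator scores its predicted sequences as real (label 0). The same
#' squared-error functional used for the regression losses is applied to the
#' discriminator score, `mean((d_fake - 0)^2)` -- a least-squares adversarial
#' term. Its gradient through the sigmoid vanishes when the discriminator
#' classifies confidently, so a temporarily winning discriminator cannot
#' destabilise the regressor; the binary cross-entropy alternative grows
#' unboundedly in that regime and empirically collapses joint training.
#'
#' @param d_fake discriminator probabilities on predicted sequences, in (0, 1).
#' @return Scalar in (0, 1); tends to 0 as the discriminator is fooled.
#' @export
generator_adversarial_loss <- function(d_fake) {
  check_prob(d_fake)
  mean(d_fake^2)
}

check_prob <- function(p) {
  if (any(p <= 0 | p >= 1)) {
    stop("probabilities must lie strictly inside (0, 1)", call. = FALSE)
  }
  invisible(p)
}

#' Collaborative loss
#'
#' Mean squared error between the auxiliary regressor's post-horizon forecast
#' (computed from the history concatenated with the primary regressor's
#' predicted horizon) and the real post-horizon sequence. During training
#' this loss is backpropagated through the predicted horizon into the primary
#' regressor -- the mechanism that shapes horizon predictions to stay
#' informative about what follows them.
#'
#' @param post_pred N x m matrix of post-horizon forecasts.
#' @param post_target N x m matrix of real post-horizon values.
#' @return Non-negative scalar.
#' @export
collaborative_loss <- function(post_pred, post_target) {
  predictive_loss(post_pred, post_target)
}

framework_uses <- function(framework) {
  list(
    adversarial = framework %in% c("AL", "ACL"),
    collaborative = framework %in% c("CL", "ACL")
  )
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 100003) * 1009 + 7919 * k) %% 2147483647L
}

#' Train a forecasting system under one of the four frameworks
#'
#' Trains the primary regressor (plus auxiliary components as dictated by the
#' framework) by minibatch Adam. Every batch performs one discriminator step
#' on its own loss (AL/ACL), followed by one joint step on the regressor
#' objective: `LP` (IL), `LP + LA` (AL), `LP + LC` (CL) or `LP + LA + LC`
#' (ACL), with unweighted components. The auxiliary regressor receives its
#' gradient through the collaborative loss within the same joint step.
#'
#' The optional ablation switches exist to probe the training mechanics:
#' `block_collab_gradient` stops the collaborative gradient at the predicted
#' horizon (the auxiliary regressor still learns, but no longer shapes the
#' primary one), and `detach_auxiliary` both detaches the auxiliary outputs
#' and zeroes their loss terms, which reduces any framework's primary-regressor
#' trajectory to independent learning under the same seed.
#'
#' @param data a `windowed_dataset` scaled to [0, 1]; must include post-horizon
#'   targets for AL, CL and ACL.
#' @param cfg a [training_config()].
#' @param block_collab_gradient if `TRUE`, stop gradients of the collaborative
#'   loss at the predicted horizon.
#' @param detach_auxiliary if `TRUE`, remove all auxiliary influence on the
#'   primary regressor (adversarial and collaborative terms detached and
#'   zeroed).
#' @return A `trained_system` holding the trained primary regressor, any
#'   auxiliary components, the per-epoch [loss history][loss_history] and the
#'   configuration.
#' @export
train_system <- function(data, cfg, block_collab_gradient = FALSE,
                         detach_auxiliary = FALSE) {
  stopifnot(inherits(data, "windowed_dataset"), inherits(cfg, "training_config"))
  uses <- framework_uses(cfg$framework)
  needs_post <- uses$adversarial || uses$collaborative
  if (needs_post && is.null(data$post_targets)) {
    stop(sprintf(
      "framework %s needs post-horizon targets; reframe with include_post = TRUE",
      cfg$framework
    ), call. = FALSE)
  }
  n <- data$config$history_len
  m <- data$config$ph_len
  N <- n_windows(data)
  Hx <- data$histories
  PHx <- data$ph_targets
  PPHx <- data$post_targets

  pr <- build_primary_regressor(n, m, seed = derive_seed(cfg$seed, 1L))
  ar <- if (uses$collaborative) {
    build_auxiliary_regressor(n, m, seed = derive_seed(cfg$seed, 2L))
  }
  disc <- if (uses$adversarial) {
    build_discriminator(n, m, seed = derive_seed(cfg$seed, 3L))
  }

  pr_net <- pr$net
  ar_net <- if (!is.null(ar)) ar$net
  d_net <- if (!is.null(disc)) disc$net

  opt_pr <- adam_init(mlp_params(pr_net))
  opt_ar <- if (!is.null(ar_net)) adam_init(mlp_params(ar_net))
  opt_d <- if (!is.null(d_net)) adam_init(conv_net_params(d_net))
  lr <- cfg$learning_rate

  # pre-draw every epoch's shuffle from a dedicated stream so that the RNG
  # consumption is identical across frameworks under the same seed
  perms <- with_seed(derive_seed(cfg$seed, 4L), {
    lapply(seq_len(cfg$epochs), function(e) sample.int(N))
  })

  eps <- 1e-12
  history <- matrix(NA_real_, nrow = cfg$epochs, ncol = 5L)
  colnames(history) <- c("lp", "la", "lc", "ls", "ld")

  for (epoch in seq_len(cfg$epochs)) {
    perm <- perms[[epoch]]
    batch_starts <- seq.int(1L, N, by = cfg$batch_size)
    acc <- c(lp = 0, la = 0, lc = 0, ld = 0)
    nb <- 0L
    for (bs in batch_starts) {
      idx <- perm[bs:min(N, bs + cfg$batch_size - 1L)]
      B <- length(idx)
      bH <- Hx[idx, , drop = FALSE]
      bP <- PHx[idx, , drop = FALSE]
      bPP <- if (!is.null(PPHx)) PPHx[idx, , drop = FALSE]

      # -- discriminator step on its own loss --------------------------------
      ld <- 0
      if (!is.null(d_net)) {
        fake_ph <- mlp_forward(pr_net, bH)$output # detached
        real_fw <- conv_net_forward(d_net, cbind(bH, bP, bPP))
        fake_fw <- conv_net_forward(d_net, cbind(bH, fake_ph, bPP))
        p_real <- pmin(1 - eps, pmax(eps, real_fw$prob))
        p_fake <- pmin(1 - eps, pmax(eps, fake_fw$prob))
        ld <- mean(-log(1 - p_real)) + mean(-log(p_fake))
        # d/dz of BCE against label y for sigmoid output: (p - y) / B
        bw_real <- conv_net_backward(d_net, real_fw$cache, (p_real - 0) / B)
        bw_fake <- conv_net_backward(d_net, fake_fw$cache, (p_fake - 1) / B)
        g <- Map(`+`, bw_real$grads, bw_fake$grads)
        upd <- adam_step(opt_d, conv_net_params(d_net), g, lr)
        d_net <- conv_net_set_params(d_net, upd$params)
        opt_d <- upd$state
      }

      # -- joint regressor step ---------------------------------------------
      fw_pr <- mlp_forward(pr_net, bH)
      ph_hat <- fw_pr$output
      lp <- mean((ph_hat - bP)^2)
      d_ph_hat <- 2 * (ph_hat - bP) / (B * m)

      la <- 0
      if (!is.null(d_net)) {
        fw_d <- conv_net_forward(d_net, cbind(bH, ph_hat, bPP))
        p_fake <- pmin(1 - eps, pmax(eps, fw_d$prob))
        la <- mean(p_fake^2)
        if (!detach_auxiliary) {
          # d(mean(p^2))/dz = 2 p * p(1-p) / B through the sigmoid
          dz <- 2 * p_fake * p_fake * (1 - p_fake) / B
          bw_d <- conv_net_backward(d_net, fw_d$cache, dz)
          d_ph_hat <- d_ph_hat + bw_d$dX[, n + seq_len(m), drop = FALSE]
        }
      }

      lc <- 0
      ar_grads <- NULL
      if (!is.null(ar_net)) {
        fw_ar <- mlp_forward(ar_net, cbind(bH, ph_hat))
        lc <- mean((fw_ar$output - bPP)^2)
        bw_ar <- mlp_backward(ar_net, fw_ar, 2 * (fw_ar$output - bPP) / (B * m))
        ar_grads <- c(bw_ar$dW, bw_ar$db)
        if (!detach_auxiliary && !block_collab_gradient) {
          d_ph_hat <- d_ph_hat + bw_ar$dX[, n + seq_len(m), drop = FALSE]
        }
      }

      bw_pr <- mlp_backward(pr_net, fw_pr, d_ph_hat)
      upd <- adam_step(opt_pr, mlp_params(pr_net), c(bw_pr$dW, bw_pr$db), lr)
      pr_net <- mlp_set_params(pr_net, upd$params)
      opt_pr <- upd$state
      if (!is.null(ar_grads)) {
        upd <- adam_step(opt_ar, mlp_params(ar_net), ar_grads, lr)
        ar_net <- mlp_set_params(ar_net, upd$params)
        opt_ar <- upd$state
      }

      if (detach_auxiliary) {
        la <- 0
        lc <- 0
      }
      acc <- acc + c(lp = lp, la = la, lc = lc, ld = ld)
      nb <- nb + 1L
    }
    ep <- acc / nb
    if (!all(is.finite(ep))) {
      stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch),
        call. = FALSE
      )
    }
    history[epoch, ] <- c(ep[["lp"]], ep[["la"]], ep[["lc"]],
      ep[["lp"]] + ep[["la"]] + ep[["lc"]], ep[["ld"]])
  }

  pr$net <- pr_net
  if (!is.null(ar)) ar$net <- ar_net
  if (!is.null(disc)) disc$net <- d_net
  structure(
    list(
      framework = cfg$framework,
      primary = pr,
      auxiliary = ar,
      discriminator = disc,
      history = data.frame(epoch = seq_len(cfg$epochs), history),
      config = cfg,
      seed = cfg$seed
    ),
    class = "trained_system"
  )
}

#' Per-epoch loss history of a trained system
#'
#' @param system a `trained_system`.
#' @return Data frame with columns `epoch`, `lp` (predictive), `la`
#'   (adversarial, 0 when absent), `lc` (collaborative, 0 when absent), `ls`
#'   (system loss, the exact sum of the active components) and `ld`
#'   (discriminator loss, 0 when absent).
#' @export
loss_history <- function(system) {
  stopifnot(inherits(system, "trained_system"))
  system$history
}

#' Forecast with a trained system
#'
#' Deployment uses only the trained primary regressor: a stateless forward
#' pass mapping history windows to horizon predictions, consuming no future
#' information. Predictions are invariant to batch partitioning.
#'
#' @param object a `trained_system`.
#' @param newdata N x n matrix of history windows, scaled consistently with
#'   training.
#' @param ... unused.
#' @return N x m matrix of scaled predictions.
#' @export
predict.trained_system <- function(object, newdata, ...) {
  predict(object$primary, newdata)
}

#' @export
print.trained_system <- function(x, ...) {
  h <- x$history
  cat(sprintf(
    "<trained_system> framework %s, %d epochs%s\n",
    x$framework, nrow(h),
    if (nrow(h)) sprintf(", final LS %.5f", h$ls[nrow(h)]) else ""
  ))
  invisible(x)
}

#' Naive last-value forecast
#'
#' The persistence baseline: every future step repeats the final value of the
#' history window.
#'
#' @param history numeric vector (one history window) or N x n matrix.
#' @param m number of future steps.
#' @return Length-`m` vector, or N x m matrix for matrix input.
#' @export
naive_forecast <- function(history, m) {
  if (m < 1) stop("m must be positive", call. = FALSE)
  if (is.null(dim(history))) {
    if (!length(history)) stop("history must be non-empty", call. = FALSE)
    rep(history[length(history)], m)
  } else {
    if (!ncol(history)) stop("history must be non-empty", call. = FALSE)
    matrix(history[, ncol(history)], nrow = nrow(history), ncol = m)
  }
}
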