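# ---------------------------------------------------------------------------
# Reference models and metrics: a layered network trained with exact
# backpropagation, the leaky self-recurrent network trained with
# backpropagation through time for the memory task, and the
# weight-update alignment angle.
# ---------------------------------------------------------------------------

#' Layered feedforward reference network
#'
#' A plain hierarchical network `r_l = phi_l(gain_l * W_l r_{l-1})` with
#' weights initialised from `U(-1, 1)`. The optional per-layer input gain
#' expresses the conductance attenuation `g_rep / g_tot` of a microcircuit
#' soma, so that a microcircuit in the weak-nudging limit maps exactly
#' onto such a network (see [as_ann()]).
#'
#' @param sizes Layer sizes, input first.
#' @param act Activation: a name, an [activation_fn()], or one per
#'   non-input layer.
#' @param gains Per-layer input gain (recycled).
#' @param weights Optional list of preset weight matrices.
#' @return An object of class `"layered_ann"`.
#' @export
layered_ann <- function(sizes, act = "tanh", gains = 1, weights = NULL) {
  nL <- length(sizes) - 1L
  stopifnot(nL >= 1L)
  if (inherits(act, "mc_activation")) act <- list(act)
  if (is.character(act)) act <- lapply(act, activation_fn)
  if (length(act) == 1L) act <- rep(act, nL)
  stopifnot(length(act) == nL)
  if (is.null(weights))
    weights <- lapply(seq_len(nL), function(l)
      matrix(stats::runif(sizes[l + 1] * sizes[l], -1, 1),
             sizes[l + 1], sizes[l]))
  structure(list(sizes = sizes, W = weights, act = act,
                 gains = rep_len(gains, nL)),
            class = "layered_ann")
}

#' @export
print.layered_ann <- function(x, ...) {
  cat(sprintf("<layered_ann [%s]>\n", paste(x$sizes, collapse = "-")))
  invisible(x)
}

#' Forward pass of a layered network
#'
#' @param ann A [layered_ann()].
#' @param x Input vector.
#' @return List with per-layer preactivations `v` and rates `r`
#'   (`r[[1]]` is the input).
#' @export
ann_forward <- function(ann, x) {
  nL <- length(ann$W)
  r <- vector("list", nL + 1L); v <- vector("list", nL + 1L)
  r[[1]] <- as.numeric(x)
  for (l in seq_len(nL)) {
    v[[l + 1]] <- ann$gains[l] * drop(ann$W[[l]] %*% r[[l]])
    r[[l + 1]] <- phi(ann$act[[l]], v[[l + 1]])
  }
  list(v = v, r = r)
}

#' Batched forward pass (rows of `X` are samples)
#' @param ann A [layered_ann()].
#' @param X Input matrix `n x d`.
#' @return Output matrix `n x k`.
#' @export
ann_forward_batch <- function(ann, X) {
  R <- t(X)
  for (l in seq_along(ann$W)) {
    V <- ann$gains[l] * (ann$W[[l]] %*% R)
    R <- matrix(phi(ann$act[[l]], V), nrow = nrow(V))
  }
  t(R)
}

#' Exact backpropagation reference update
#'
#' For the squared-error loss `L = 0.5 * ||r_tgt - r_N||^2`:
#' `delta_N = phi'(v_N) * (r_tgt - r_N)`,
#' `delta_l = phi'(v_l) * (gain_{l+1} W_{l+1}^T delta_{l+1})`, and the
#' negative gradient `dW_l = gain_l * delta_l r_{l-1}^T` (which reduces to
#' the plain update `delta_l r_{l-1}^T` at unit gains).
#'
#' @param ann A [layered_ann()].
#' @param input Input vector.
#' @param target Target rate vector.
#' @return List with per-layer `delta` and update matrices `dW`.
#' @export
bp_reference_update <- function(ann, input, target) {
  nL <- length(ann$W)
  fwd <- ann_forward(ann, input)
  delta <- vector("list", nL + 1L)
  delta[[nL + 1]] <- phi_prime(ann$act[[nL]], fwd$v[[nL + 1]]) *
    (as.numeric(target) - fwd$r[[nL + 1]])
  if (nL > 1L) for (l in (nL - 1L):1L) {
    delta[[l + 1]] <- phi_prime(ann$act[[l]], fwd$v[[l + 1]]) *
      (ann$gains[l + 1] * drop(crossprod(ann$W[[l + 1]], delta[[l + 2]])))
  }
  dW <- lapply(seq_len(nL), function(l)
    ann$gains[l] * tcrossprod(delta[[l + 1]], fwd$r[[l]]))
  list(delta = delta[-1], dW = dW, forward = fwd)
}

#' Train a layered network with vanilla stochastic gradient descent
#'
#' Batch size 1, samples in dataset order. A subset of weight matrices can
#' be trained while the rest stay frozen at initialisation (e.g. training
#' only the last three matrices of a deep student).
#'
#' @param ann A [layered_ann()].
#' @param data Training [mc_dataset()] (static inputs).
#' @param epochs Number of passes.
#' @param lr Learning rate.
#' @param trainable Indices of trainable weight matrices (default all).
#' @param eval_data Optional dataset for per-epoch test loss.
#' @param eval_every Evaluation stride.
#' @return List with the trained `ann` and a `record` data frame.
#' @export
ann_train <- function(ann, data, epochs, lr, trainable = seq_along(ann$W),
                      eval_data = NULL, eval_every = 10L) {
  rec <- list()
  for (ep in seq_len(epochs)) {
    for (i in seq_len(data$n)) {
      upd <- bp_reference_update(ann, data$inputs[i, ], data$targets[i, ])
      for (l in trainable) ann$W[[l]] <- ann$W[[l]] + lr * upd$dW[[l]]
    }
    if (!is.null(eval_data) && (ep %% eval_every == 0L || ep == epochs)) {
      v <- evaluate_outputs(ann_forward_batch(ann, eval_data$inputs),
                            eval_data$targets, "mse_loss")
      rec[[length(rec) + 1L]] <- data.frame(epoch = ep, split = eval_data$split,
                                            metric = "mse_loss", value = v)
    }
  }
  list(ann = ann, record = do.call(rbind, rec))
}

#' Map a strictly hierarchical microcircuit onto its equivalent layered network
#'
#' In the weak-nudging limit a settled microcircuit computes
#' `r_l = phi(g_rep / g_tot * W_l r_{l-1})`; the returned network carries
#' the same weights and activations with per-layer gain `g_rep / g_tot`,
#' and is the reference for update-alignment comparisons.
#'
#' @param net A strictly hierarchical [mc_network()].
#' @return A [layered_ann()].
#' @export
as_ann <- function(net) {
  nA <- length(net$n_R)
  dir <- sign(net$target_area - net$input_area)
  order_flow <- seq(net$input_area, net$target_area, by = dir)
  W <- vector("list", nA - 1L)
  for (b in net$W) {
    pos_t <- match(b$tgt, order_flow); pos_s <- match(b$src, order_flow)
    if (pos_t != pos_s + 1L)
      stop("as_ann requires a strictly hierarchical network")
    W[[pos_s]] <- b$mat
  }
  layered_ann(net$n_R[order_flow], act = net$act_r[order_flow[-1]],
              gains = net$cond$g_rep / net$cond$g_tot, weights = W)
}

# ---------------------------------------------------------------------------

#' Leaky self-recurrent baseline for the match-to-sample task
#'
#' One input, `n_hidden` hidden and one output unit; every hidden and
#' output unit is self-recurrently connected with leak `alpha = dt / tau`,
#' implementing leaky integration of its bottom-up input (no other
#' recurrence). Activations default to the microcircuit's memory-task
#' choices: sharp softplus hidden units and a `20 tanh(x - 0.5)` readout.
#'
#' @param n_hidden Hidden units.
#' @param tau Self-recurrence time constant in ticks.
#' @param act_h,act_o Hidden and output activations.
#' @return An object of class `"rnn_baseline"`.
#' @export
rnn_baseline <- function(n_hidden = 2L, tau = 217,
                         act_h = activation_fn("softplus", beta = 10),
                         act_o = activation_fn("scaled_tanh", scale = 20, shift = 0.5)) {
  structure(list(
    W1 = matrix(stats::runif(n_hidden, -1, 1), n_hidden, 1),
    W2 = matrix(stats::runif(n_hidden, -1, 1), 1, n_hidden),
    alpha = 1 / tau, act_h = act_h, act_o = act_o),
    class = "rnn_baseline")
}

#' Forward pass of the recurrent baseline over one trial
#'
#' @param rnn A [rnn_baseline()].
#' @param x Input signal (numeric vector, one value per tick).
#' @return List of per-tick hidden/output voltages and rates.
#' @export
rnn_forward <- function(rnn, x) {
  T_ <- length(x); a <- rnn$alpha
  nh <- nrow(rnn$W1)
  Vh <- matrix(0, nh, T_); Vo <- numeric(T_)
  vh <- numeric(nh); vo <- 0
  Rh <- matrix(0, nh, T_)
  for (t in seq_len(T_)) {
    vh <- (1 - a) * vh + a * drop(rnn$W1 %*% x[t])
    rh <- phi(rnn$act_h, vh)
    vo <- (1 - a) * vo + a * drop(rnn$W2 %*% rh)
    Vh[, t] <- vh; Rh[, t] <- rh; Vo[t] <- vo
  }
  list(Vh = Vh, Rh = Rh, Vo = Vo, out = phi(rnn$act_o, Vo[T_]))
}

#' Unrolled gradient of the final-step squared error
#'
#' Backpropagation through time for `L = 0.5 (target - out_T)^2`, with the
#' loss applied at the last tick only.
#'
#' @param rnn A [rnn_baseline()].
#' @param x Input signal.
#' @param target Scalar target.
#' @return List with `dW1`, `dW2` (negative gradients), `out` and `loss`.
#' @export
rnn_bptt_grad <- function(rnn, x, target) {
  fw <- rnn_forward(rnn, x)
  T_ <- length(x); a <- rnn$alpha
  err <- as.numeric(target) - fw$out
  dW1 <- rnn$W1 * 0; dW2 <- rnn$W2 * 0
  a_vo <- 0; a_vh <- numeric(nrow(rnn$W1))
  for (t in T_:1) {
    if (t == T_) a_vo <- a_vo + err * phi_prime(rnn$act_o, fw$Vo[T_])
    dW2 <- dW2 + a * a_vo * matrix(fw$Rh[, t], 1)
    d_rh <- a * a_vo * drop(t(rnn$W2))
    a_vh <- a_vh + d_rh * phi_prime(rnn$act_h, fw$Vh[, t])
    dW1 <- dW1 + a * matrix(a_vh, ncol = 1) %*% x[t]
    a_vo <- (1 - a) * a_vo
    a_vh <- (1 - a) * a_vh
  }
  list(dW1 = dW1, dW2 = dW2, out = fw$out, loss = 0.5 * err^2)
}

#' Train the recurrent baseline with backpropagation through time
#'
#' @param rnn A [rnn_baseline()].
#' @param data A time-series [mc_dataset()] (match-to-sample trials).
#' @param epochs Training passes.
#' @param lr Learning rate.
#' @param eval_data Optional dataset for per-epoch accuracy.
#' @return List with the trained `rnn` and a `record` data frame of
#'   per-epoch accuracies.
#' @export
train_rnn_bptt <- function(rnn, data, epochs, lr, eval_data = NULL) {
  rec <- list()
  for (ep in seq_len(epochs)) {
    for (i in seq_len(data$n)) {
      g <- rnn_bptt_grad(rnn, data$inputs[[i]][1, ], data$targets[i, 1])
      rnn$W1 <- rnn$W1 + lr * g$dW1
      rnn$W2 <- rnn$W2 + lr * g$dW2
    }
    if (!is.null(eval_data)) {
      acc <- rnn_accuracy(rnn, eval_data)
      rec[[length(rec) + 1L]] <- data.frame(epoch = ep, split = eval_data$split,
                                            metric = "accuracy", value = acc)
    }
  }
  list(rnn = rnn, record = do.call(rbind, rec))
}

#' Sign accuracy of the recurrent baseline on a trial set
#' @param rnn A [rnn_baseline()].
#' @param data A time-series [mc_dataset()].
#' @return Fraction of trials whose final output sign matches the target.
#' @export
rnn_accuracy <- function(rnn, data) {
  preds <- vapply(seq_len(data$n), function(i)
    rnn_forward(rnn, data$inputs[[i]][1, ])$out, 0)
  mean(sign(preds) == sign(data$targets[, 1]))
}

# ---------------------------------------------------------------------------

#' Alignment angle between two sets of weight updates
#'
#' Per matched block, the angle
#' `arccos(<vec(dW_a), vec(dW_b)> / (||dW_a|| ||dW_b||))` in degrees;
#' blocks with a zero-norm update are undefined and excluded from the
#' aggregate. 0 degrees means identical direction, 90 orthogonal, 180
#' opposed.
#'
#' @param dW_model,dW_ref Lists of update matrices with matching shapes.
#' @param aggregate Return the median over blocks (`TRUE`) or the
#'   per-block vector.
#' @return Angle(s) in degrees.
#' @export
alignment_angle <- function(dW_model, dW_ref, aggregate = TRUE) {
  stopifnot(length(dW_model) == length(dW_ref))
  ang <- vapply(seq_along(dW_model), function(i) {
    a <- as.numeric(dW_model[[i]]); b <- as.numeric(dW_ref[[i]])
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) return(NA_real_)
    acos(max(-1, min(1, sum(a * b) / (na * nb)))) * 180 / pi
  }, 0)
  if (aggregate) stats::median(ang, na.rm = TRUE) else ang
}
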