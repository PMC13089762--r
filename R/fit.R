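# ---------------------------------------------------------------------------
# Fitting surface: train a microcircuit on a dataset and return a classed
# model object with the usual methods.
# ---------------------------------------------------------------------------

#' Supervised dataset container
#'
#' Holds a sequence of (input, target, presentation duration) items. Inputs
#' are either static vectors (rows of a matrix, presented for `T_pres` time
#' units each) or time series (a list of `d x T` matrices, one column per
#' tick).
#'
#' @param inputs Numeric matrix (`n x d`, static inputs) or list of `d x T`
#'   matrices (time series at tick resolution).
#' @param targets Numeric matrix `n x k` of target rates.
#' @param T_pres Presentation duration per item in time units (static
#'   inputs only; recycled).
#' @param active_from Tick index (1-based, within the presentation window)
#'   from which the output-area nudging is active; 1 = always (recycled).
#' @param split `"train"`, `"val"` or `"test"`.
#' @return An object of class `"mc_dataset"`.
#' @export
mc_dataset <- function(inputs, targets, T_pres = NA_real_, active_from = 1L,
                       split = c("train", "val", "test")) {
  split <- match.arg(split)
  series <- is.list(inputs)
  n <- if (series) length(inputs) else nrow(inputs)
  targets <- as.matrix(targets)
  stopifnot(nrow(targets) == n)
  if (series) {
    d <- unique(vapply(inputs, nrow, 0L))
    if (length(d) != 1L) stop("all time-series items must share the input dimension")
  }
  structure(
    list(inputs = inputs, targets = targets, series = series,
         T_pres = rep_len(T_pres, n), active_from = rep_len(as.integer(active_from), n),
         split = split, n = n,
         n_in = if (series) nrow(inputs[[1]]) else ncol(inputs),
         n_out = ncol(targets)),
    class = "mc_dataset")
}

#' @export
print.mc_dataset <- function(x, ...) {
  cat(sprintf("<mc_dataset: %d %s item(s), %d -> %d, %s>\n", x$n,
              if (x$series) "time-series" else "static", x$n_in, x$n_out, x$split))
  invisible(x)
}

#' @export
`[.mc_dataset` <- function(x, i) {
  mc_dataset(if (x$series) x$inputs[i] else x$inputs[i, , drop = FALSE],
             x$targets[i, , drop = FALSE], x$T_pres[i], x$active_from[i],
             split = x$split)
}

# convert a dataset into the item list consumed by the compiled core
.build_items <- function(data, dt, with_targets = TRUE) {
  lapply(seq_len(data$n), function(i) {
    if (data$series) {
      inp <- data$inputs[[i]]
      T_ticks <- ncol(inp)
    } else {
      inp <- matrix(data$inputs[i, ], ncol = 1)
      T_ticks <- max(1L, as.integer(round(data$T_pres[i] / dt)))
    }
    list(input = inp,
         target = if (with_targets) as.numeric(data$targets[i, ]) else numeric(0),
         active_from = if (with_targets) data$active_from[i] else -1L,
         T_ticks = as.integer(T_ticks))
  })
}

#' Train a microcircuit network
#'
#' Runs the phaseless training loop: for every sample the input rates are
#' clamped, voltages settle for `net$settle_steps` plasticity-free ticks,
#' then the sample is presented for its duration with neuronal dynamics and
#' (if enabled) the delta-rule plasticity and feedback refresh applied on
#' every tick. Network state persists across samples and epochs; samples
#' are presented in dataset order, so runs are exactly reproducible from
#' the initialisation seed.
#'
#' @param net An [mc_network()] object.
#' @param data Training [mc_dataset()].
#' @param epochs Number of passes over the dataset.
#' @param eval_data Optional dataset evaluated with plasticity off and
#'   free (non-nudged) dynamics.
#' @param eval_every Evaluate every this many epochs.
#' @param metrics Character vector of metrics for evaluation records;
#'   see [evaluate_outputs()].
#' @param plasticity Set to `FALSE` for a pure simulation run.
#' @param verbose Print per-evaluation progress.
#' @return An object of class `"mc_fit"` with components `net` (trained
#'   network), `record` (long data frame: epoch, split, metric, value),
#'   `state` (final network state) and `data` dimensions.
#' @export
mc_fit <- function(net, data, epochs = 1L, eval_data = NULL, eval_every = 1L,
                   metrics = "mse_loss", plasticity = TRUE, verbose = FALSE) {
  stopifnot(inherits(net, "mc_network"), inherits(data, "mc_dataset"))
  if (data$n_in != net$n_R[net$input_area])
    stop("dataset input dimension does not match the input area")
  if (data$n_out != net$n_R[net$target_area])
    stop("dataset target dimension does not match the target area")
  items <- .build_items(data, net$dt, with_targets = TRUE)
  st <- mc_state(net)
  rec <- list()
  for (ep in seq_len(epochs)) {
    res <- .mc_run(net, st, items, plasticity)
    net <- res$net; st <- res$state
    for (m in metrics)
      rec[[length(rec) + 1L]] <- data.frame(
        epoch = ep, split = "train", metric = m,
        value = evaluate_outputs(res$outputs, data$targets, m))
    if (!is.null(eval_data) && (ep %% eval_every == 0L || ep == epochs)) {
      pred <- mc_predict(net, eval_data)
      for (m in metrics) {
        v <- evaluate_outputs(pred, eval_data$targets, m)
        rec[[length(rec) + 1L]] <- data.frame(
          epoch = ep, split = eval_data$split, metric = m, value = v)
        if (verbose) message(sprintf("epoch %d: %s %s = %.6g",
                                     ep, eval_data$split, m, v))
      }
    }
  }
  structure(list(net = net, state = st, record = do.call(rbind, rec),
                 epochs = epochs, data_dim = c(n = data$n, d = data$n_in,
                                               k = data$n_out),
                 train_data = data, eval_data = eval_data,
                 call = match.call()),
            class = "mc_fit")
}

#' Free-dynamics predictions of a microcircuit
#'
#' Presents each item from a fresh rest state with plasticity off and no
#' target nudging, and reads the output-area rates at the final tick.
#'
#' @param net An [mc_network()] or [mc_fit()] object.
#' @param data An [mc_dataset()] or a numeric input matrix (`n x d`).
#' @param T_pres Presentation duration when `data` is a bare matrix.
#' @return Matrix `n x k` of output rates.
#' @export
mc_predict <- function(net, data, T_pres = NULL) {
  if (inherits(net, "mc_fit")) net <- net$net
  if (!inherits(data, "mc_dataset")) {
    data <- mc_dataset(as.matrix(data),
                       matrix(0, nrow(as.matrix(data)), net$n_R[net$target_area]),
                       T_pres = if (is.null(T_pres)) net$T_pres else T_pres)
  }
  items <- .build_items(data, net$dt, with_targets = FALSE)
  .mc_run(net, mc_state(net), items, plasticity = FALSE)$outputs
}

#' Evaluate network outputs against targets
#'
#' * `mse_loss`: mean over samples of the summed squared output error.
#' * `accuracy`: fraction of correct decisions -- the output sign for
#'   scalar outputs, the argmax for multi-class targets.
#'
#' @param outputs,targets Matrices `n x k`.
#' @param metric `"mse_loss"` or `"accuracy"`.
#' @return Scalar metric value.
#' @export
evaluate_outputs <- function(outputs, targets, metric = c("mse_loss", "accuracy")) {
  metric <- match.arg(metric)
  outputs <- as.matrix(outputs); targets <- as.matrix(targets)
  if (nrow(outputs) == 0L) stop("empty record")
  stopifnot(all(dim(outputs) == dim(targets)))
  if (metric == "mse_loss") {
    mean(rowSums((outputs - targets)^2))
  } else {
    if (ncol(outputs) == 1L) {
      mean(sign(outputs) == sign(targets))
    } else {
      mean(max.col(outputs) == max.col(targets))
    }
  }
}

#' @export
print.mc_fit <- function(x, ...) {
  cat("Trained error-neuron microcircuit\n")
  print(x$net)
  fin <- x$record[x$record$epoch == max(x$record$epoch), ]
  for (i in seq_len(nrow(fin)))
    cat(sprintf("  final %s %s: %.6g\n", fin$split[i], fin$metric[i], fin$value[i]))
  invisible(x)
}

#' @export
summary.mc_fit <- function(object, ...) {
  rec <- object$record
  out <- list(
    network = object$net,
    epochs = object$epochs,
    n_weights = sum(vapply(object$net$W, function(b) length(b$mat), 0)),
    final = rec[rec$epoch == max(rec$epoch), ],
    best = do.call(rbind, lapply(split(rec, paste(rec$split, rec$metric)),
                                 function(d) d[which.min(d$value), ])))
  class(out) <- "summary.mc_fit"
  out
}

#' @export
print.summary.mc_fit <- function(x, ...) {
  print(x$network)
  cat(sprintf("  %d trainable weights, %d epochs\n", x$n_weights, x$epochs))
  cat("Final metrics:\n"); print(x$final, row.names = FALSE)
  invisible(x)
}

#' @export
coef.mc_fit <- function(object, ...) {
  nm <- object$net$graph$names
  W <- lapply(object$net$W, `[[`, "mat")
  names(W) <- vapply(object$net$W, function(b)
    paste0(nm[b$tgt], "<-", nm[b$src]), "")
  W
}

#' @export
predict.mc_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$train_data
  mc_predict(object$net, newdata)
}

#' @export
residuals.mc_fit <- function(object, data = NULL, ...) {
  if (is.null(data)) data <- object$train_data
  data$targets - mc_predict(object$net, data)
}

#' @export
plot.mc_fit <- function(x, metric = "mse_loss", log = "y", ...) {
  rec <- x$record[x$record$metric == metric, ]
  splits <- unique(rec$split)
  cols <- seq_along(splits)
  graphics::matplot(
    x = unique(rec$epoch),
    y = sapply(splits, function(s) rec$value[rec$split == s]),
    type = "l", lty = 1, col = cols, log = log,
    xlab = "epoch", ylab = metric, ...)
  graphics::legend("topright", legend = splits, col = cols, lty = 1, bty = "n")
  invisible(x)
}

#' Simulate network trajectories
#'
#' Runs the reference (pure-R) dynamics for one input, recording the full
#' per-tick state trajectory; useful for inspecting voltage and rate
#' traces.
#'
#' @param object An [mc_fit()] or [mc_network()] object.
#' @param nsim Number of ticks to simulate.
#' @param seed Optional seed (only relevant for stochastic inputs).
#' @param input Input rate vector (or `d x nsim` matrix of frames).
#' @param target Optional target vector presented throughout.
#' @param ... Unused.
#' @return A data frame with one row per (tick, area) and list columns of
#'   rate vectors.
#' @export
simulate.mc_fit <- function(object, nsim = 100, seed = NULL, input, target = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  net <- if (inherits(object, "mc_fit")) object$net else object
  st <- mc_state(net)
  if (is.null(dim(input))) input <- matrix(input, ncol = 1)
  out <- vector("list", nsim)
  for (t in seq_len(nsim)) {
    frame <- input[, min(t, ncol(input))]
    st <- mc_tick(net, st, frame, target)$state
    out[[t]] <- data.frame(
      tick = t, area = seq_along(net$n_R),
      r_r = I(st$r_r), u_som = I(st$u_som), e_prosp = I(st$e_prosp))
  }
  do.call(rbind, out)
}

#' @export
simulate.mc_network <- simulate.mc_fit
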