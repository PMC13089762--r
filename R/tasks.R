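# ---------------------------------------------------------------------------
# Benchmark task suite: cart pole distilled from an LQR teacher, delayed
# match-to-sample, Yin-Yang, teacher-student regression, class-conditioned
# image generation. All generators are pure functions of (parameters, seed).
# ---------------------------------------------------------------------------

#' Physical parameters of the cart-pole plant
#'
#' Standard frictionless cart-pole: cart mass 1.0, pole mass 0.1, pole
#' half-length 0.5, gravity 9.8, with one controller tick per physical
#' Euler step of 0.02 time units (so a 2 s episode is 100 ticks).
#'
#' @param m_cart,m_pole,half_length,gravity Plant constants.
#' @param dt Physical step per controller tick.
#' @param reset_angle Absolute pole angle (radians) that triggers a reset.
#' @param force_scale Gain applied to the controller's scalar output.
#' @return A list of parameters.
#' @export
cartpole_params <- function(m_cart = 1.0, m_pole = 0.1, half_length = 0.5,
                            gravity = 9.8, dt = 0.02,
                            reset_angle = 70 * pi / 180, force_scale = 1) {
  list(m_cart = m_cart, m_pole = m_pole, half_length = half_length,
       gravity = gravity, dt = dt, reset_angle = reset_angle,
       force_scale = force_scale)
}

# time derivative of the cart-pole state [x, xdot, theta, thetadot]
.cartpole_deriv <- function(s, F, p) {
  theta <- s[3]; thetadot <- s[4]
  mt <- p$m_cart + p$m_pole
  ct <- cos(theta); st <- sin(theta)
  tmp <- (F + p$m_pole * p$half_length * thetadot^2 * st) / mt
  thetaacc <- (p$gravity * st - ct * tmp) /
    (p$half_length * (4 / 3 - p$m_pole * ct^2 / mt))
  xacc <- tmp - p$m_pole * p$half_length * thetaacc * ct / mt
  c(s[2], xacc, thetadot, thetaacc)
}

#' Advance the cart pole by one Euler step
#'
#' @param state Numeric vector `c(x, xdot, theta, thetadot)`.
#' @param F Applied force.
#' @param params A [cartpole_params()] list.
#' @param dt Step length (defaults to `params$dt`).
#' @return List with the new `state` and a logical `reset` flag raised when
#'   the absolute pole angle exceeds the reset angle (70 degrees).
#' @export
cartpole_step <- function(state, F, params = cartpole_params(), dt = params$dt) {
  stopifnot(all(is.finite(state)), length(state) == 4L)
  state <- state + dt * .cartpole_deriv(state, F, params)
  list(state = state, reset = abs(state[3]) > params$reset_angle)
}

#' LQR gain for the linearised cart pole
#'
#' Linearises the plant around the upright equilibrium (numerically),
#' discretises with the controller step and solves the discrete-time
#' algebraic Riccati equation by value iteration,
#' `P <- Q + A'PA - A'PB (R + B'PB)^-1 B'PA`, returning the feedback gain
#' `K` of the control law `F = -K s`.
#'
#' @param Q State cost matrix (4 x 4).
#' @param R Control cost (scalar).
#' @param params A [cartpole_params()] list.
#' @param tol Convergence tolerance of the value iteration.
#' @return List with gain row vector `K`, Riccati solution `P`, and the
#'   discrete closed-loop eigenvalue moduli `eig_mod` (all < 1 for a
#'   stabilising gain).
#' @export
lqr_gain <- function(Q = diag(c(1, 1, 10, 1)), R = 5,
                     params = cartpole_params(), tol = 1e-13) {
  # numerical linearisation around the upright fixed point
  eps <- 1e-6
  A <- sapply(1:4, function(j) {
    e <- numeric(4); e[j] <- eps
    (.cartpole_deriv(e, 0, params) - .cartpole_deriv(-e, 0, params)) / (2 * eps)
  })
  B <- matrix((.cartpole_deriv(numeric(4), eps, params) -
                 .cartpole_deriv(numeric(4), -eps, params)) / (2 * eps), 4, 1)
  Ad <- diag(4) + params$dt * A
  Bd <- params$dt * B
  P <- Q
  for (i in 1:100000) {
    S <- R + crossprod(Bd, P %*% Bd)
    K <- solve(S, crossprod(Bd, P %*% Ad))
    Pn <- Q + crossprod(Ad, P %*% (Ad - Bd %*% K))
    Pn <- (Pn + t(Pn)) / 2
    if (max(abs(Pn - P)) < tol) { P <- Pn; break }
    P <- Pn
  }
  K <- solve(R + crossprod(Bd, P %*% Bd), crossprod(Bd, P %*% Ad))
  eig_mod <- Mod(eigen(Ad - Bd %*% K, only.values = TRUE)$values)
  list(K = K, P = P, A = A, B = B, Ad = Ad, Bd = Bd, eig_mod = eig_mod)
}

#' Teacher dataset distilled from the LQR controller
#'
#' Static input vectors `[x, xdot, theta, thetadot] ~ U(-1.5, 1.5)^4` with
#' the LQR force `F = -K s` as regression target.
#'
#' @param ctrl Result of [lqr_gain()].
#' @param n Number of samples (500 in the reference protocol).
#' @param T_pres Presentation duration per sample in time units.
#' @return An [mc_dataset()].
#' @export
lqr_teacher_dataset <- function(ctrl, n = 500, T_pres = 1) {
  if (any(ctrl$eig_mod >= 1))
    stop("LQR gain does not stabilise the linearised plant; refusing to distil")
  X <- matrix(stats::runif(4 * n, -1.5, 1.5), n, 4)
  Y <- -X %*% t(ctrl$K)
  mc_dataset(X, Y, T_pres = T_pres)
}

#' Closed-loop cart-pole rollout
#'
#' Runs the plant under a controller callback, resetting the state every
#' `reset_every` ticks (2 s by default) and latching a "fallen" state when
#' the pole passes the reset angle; fallen episodes stay down until the
#' next scheduled reset. The penalty log counts ticks spent fallen; a
#' secondary counter reports ticks with `|x| > 0.5` after the first half
#' of each episode.
#'
#' @param controller Function `state -> F` (scalar force).
#' @param inits Matrix of initial states (one row per episode) or `NULL`
#'   to draw `n_episodes` from `U(-1, 1)^4`.
#' @param n_episodes Number of 2 s episodes when `inits` is `NULL`.
#' @param params A [cartpole_params()] list.
#' @param reset_every Episode length in ticks.
#' @return List with `penalty` (fallen ticks), `x_penalty`, `n_ticks` and
#'   the per-tick `trajectory` matrix.
#' @export
cartpole_rollout <- function(controller, inits = NULL, n_episodes = 10,
                             params = cartpole_params(), reset_every = 100) {
  if (is.null(inits))
    inits <- matrix(stats::runif(4 * n_episodes, -1, 1), n_episodes, 4)
  n_ticks <- nrow(inits) * reset_every
  traj <- matrix(NA_real_, n_ticks, 6,
                 dimnames = list(NULL, c("x", "xdot", "theta", "thetadot",
                                         "F", "fallen")))
  penalty <- 0L; x_penalty <- 0L; t <- 0L
  for (ep in seq_len(nrow(inits))) {
    s <- inits[ep, ]; fallen <- FALSE
    for (k in seq_len(reset_every)) {
      t <- t + 1L
      F <- if (fallen) 0 else params$force_scale * controller(s)
      if (!fallen) {
        stp <- cartpole_step(s, F, params)
        s <- stp$state
        if (stp$reset) fallen <- TRUE
      }
      if (fallen) penalty <- penalty + 1L
      if (k > reset_every / 2 && abs(s[1]) > 0.5) x_penalty <- x_penalty + 1L
      traj[t, ] <- c(s, F, fallen)
    }
  }
  list(penalty = penalty, x_penalty = x_penalty, n_ticks = n_ticks,
       trajectory = traj)
}

# ---------------------------------------------------------------------------

#' Delayed match-to-sample trials
#'
#' Each trial is a one-dimensional time series: fixation (250 ms), first
#' stimulus (250 ms, amplitude +1 or -1), a delay of random length
#' `U(50, 250) ms`, and a second stimulus (250 ms). The target is the
#' temporal XNOR of the two stimulus signs (+1 match, -1 non-match) and is
#' provided only during the last step of the trial -- the final stimulus
#' stage (`target_window = "stim2"`, the default) or literally the final
#' `post_target_ticks` ticks (`target_window = "final"`); see the methods
#' vignette for why the lag-driven weight decay of retrospective units
#' makes the phase-length window the workable reading. Trial durations
#' lie in [800, 1000] ms and conditions are balanced across the four
#' sign pairs.
#'
#' Time is expressed in units of 100 ms with a tick of `dt` units, so the
#' default `dt = 0.01` gives 1 ms ticks and 800-1000 ticks per trial.
#'
#' @param n Number of trials.
#' @param dt Tick length in time units of 100 ms.
#' @param amplitude Stimulus amplitude.
#' @param target_amplitude Magnitude of the +-target, scaled to the range
#'   of the `20 tanh(x - 0.5)` readout so the learned decision margin is
#'   robust (default 5, a quarter of the range).
#' @param target_window `"stim2"` (nudging active throughout the second
#'   stimulus stage) or `"final"` (last ticks only).
#' @param post_target_ticks Extra held ticks when `target_window = "final"`,
#'   letting the error traverse the areas under synchronous updates.
#' @param split Dataset split label.
#' @return An [mc_dataset()] of time-series items; trial conditions are in
#'   `attr(, "condition")` and nominal durations (ticks) in
#'   `attr(, "duration")`.
#' @export
generate_dms <- function(n, dt = 0.01, amplitude = 1, target_amplitude = 5,
                         target_window = c("stim2", "final"),
                         post_target_ticks = 3L, split = "train") {
  target_window <- match.arg(target_window)
  ticks <- function(units) as.integer(round(units / dt))
  conds <- list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  cond_id <- sample(rep_len(1:4, n))
  items <- vector("list", n); tgt <- numeric(n); dur <- integer(n)
  active <- integer(n)
  for (i in seq_len(n)) {
    s <- conds[[cond_id[i]]] * amplitude
    delay <- ticks(stats::runif(1, 0.5, 2.5))
    sig <- c(rep(0, ticks(2.5)), rep(s[1], ticks(2.5)), rep(0, delay),
             rep(s[2], ticks(2.5)))
    dur[i] <- length(sig)
    if (target_window == "final") {
      active[i] <- dur[i]
      sig <- c(sig, rep(s[2], post_target_ticks))
    } else {
      active[i] <- dur[i] - ticks(2.5) + 1L
    }
    items[[i]] <- matrix(sig, nrow = 1)
    tgt[i] <- target_amplitude * sign(s[1] * s[2])
  }
  ds <- mc_dataset(items, matrix(tgt, ncol = 1),
                   active_from = active, split = split)
  attr(ds, "condition") <- c("upup", "updown", "downup", "downdown")[cond_id]
  attr(ds, "duration") <- dur
  ds
}

# ---------------------------------------------------------------------------

#' Yin-Yang classification dataset
#'
#' Points in the yin-yang disc (outer radius `r` centred at (0.5, 0.5),
#' half-circles of radius `r/2`, dots of radius `r/4`), labelled yin, yang
#' or dot, sampled uniformly within each class region with probabilistic
#' class balancing (expected one third per class, following the standard
#' benchmark construction). Inputs use the four-dimensional mirrored
#' encoding `(x, y, 1 - x, 1 - y)`; targets are one-hot.
#'
#' @param n Number of points.
#' @param r Outer radius.
#' @param split Dataset split label.
#' @param T_pres Presentation duration in time units.
#' @return An [mc_dataset()]; classes in `attr(, "class_id")`
#'   (1 yin, 2 yang, 3 dot).
#' @export
generate_yinyang <- function(n, r = 0.5, split = "train", T_pres = 0.2) {
  cx <- 0.5; cy <- 0.5
  classify <- function(x, y) {
    d_r <- sqrt((x - (cx + r / 2))^2 + (y - cy)^2)
    d_l <- sqrt((x - (cx - r / 2))^2 + (y - cy)^2)
    if (d_r <= r / 4 || d_l <= r / 4) return(3L)
    yin <- (d_r <= r / 2) || (y >= cy && d_l > r / 2)
    if (yin) 1L else 2L
  }
  # analytic class areas within the disc -> acceptance probabilities
  areas <- c(yin = 7 / 16, yang = 7 / 16, dot = 1 / 8) * pi * r^2
  p_accept <- min(areas) / areas
  X <- matrix(NA_real_, n, 4); cls <- integer(n); got <- 0L
  while (got < n) {
    x <- stats::runif(1, cx - r, cx + r); y <- stats::runif(1, cy - r, cy + r)
    if ((x - cx)^2 + (y - cy)^2 > r^2) next
    cl <- classify(x, y)
    if (stats::runif(1) > p_accept[cl]) next
    got <- got + 1L
    X[got, ] <- c(x, y, 1 - x, 1 - y)
    cls[got] <- cl
  }
  Y <- diag(3)[cls, , drop = FALSE]
  ds <- mc_dataset(X, Y, T_pres = T_pres, split = split)
  attr(ds, "class_id") <- cls
  ds
}

# ---------------------------------------------------------------------------

#' Teacher-student regression task
#'
#' Records the input-output map of a randomly initialised, fixed teacher
#' network and packages it as train/validation/test datasets. Teacher
#' architectures halve the layer width towards the scalar output
#' (complexity 1 is `[2-1]`, complexity 5 is `[32-16-8-4-2-1]`), so that
#' solving the task requires training every area. Teachers are resampled
#' (bounded attempts) until the map is non-trivial, operationalised as a
#' target variance of at least `1e-3` on the training inputs.
#'
#' @param complexity Integer 1-5, or give `arch` directly.
#' @param arch Optional explicit layer-size vector.
#' @param sizes Train/validation/test sample counts.
#' @param T_pres Presentation duration per sample in time units.
#' @param max_attempts Teacher resampling bound.
#' @return List with the three [mc_dataset()]s (`train`, `val`, `test`)
#'   and the `teacher` network ([layered_ann()]).
#' @export
generate_teacher_student <- function(complexity = 1L, arch = NULL,
                                     sizes = c(100, 100, 100), T_pres = 0.2,
                                     max_attempts = 100L) {
  if (is.null(arch)) {
    stopifnot(complexity >= 1L, complexity <= 5L)
    arch <- 2^(complexity:0)
  }
  n_all <- sum(sizes)
  for (att in seq_len(max_attempts)) {
    teacher <- layered_ann(arch, act = "tanh")
    X <- matrix(stats::runif(n_all * arch[1], 0, 1), n_all, arch[1])
    Y <- ann_forward_batch(teacher, X)
    if (stats::var(as.numeric(Y[seq_len(sizes[1]), ])) >= 1e-3) {
      idx <- split(seq_len(n_all), rep(c("train", "val", "test"), sizes))
      mk <- function(sp) mc_dataset(X[idx[[sp]], , drop = FALSE],
                                    Y[idx[[sp]], , drop = FALSE],
                                    T_pres = T_pres, split = sp)
      return(list(train = mk("train"), val = mk("val"), test = mk("test"),
                  teacher = teacher))
    }
  }
  stop("could not sample a non-trivial teacher in ", max_attempts, " attempts")
}

# ---------------------------------------------------------------------------

#' Class-conditioned image-generation task
#'
#' Ten (one-hot class, image) pairs with deterministic class-to-image
#' mapping; train, validation and test sets coincide. The default source
#' renders ten distinct synthetic procedural patterns (oriented gratings
#' for even classes, centred rings for odd classes) with pixels in [0, 1].
#' Alternatively, a CSV of `1 + side^2` columns (label then pixels, one
#' image per class, the common flat-image dialect) can be loaded.
#'
#' @param source `"synthetic"` or `"external"`.
#' @param side Image side length in pixels (28 for the full-scale task).
#' @param path CSV path for `source = "external"`.
#' @param T_pres Presentation duration per sample in time units.
#' @return List with `data` (an [mc_dataset()]: 10 one-hot inputs, pixel
#'   targets), `images` (list of `side x side` matrices) and `side`.
#' @export
generate_image_task <- function(source = c("synthetic", "external"),
                                side = 28L, path = NULL, T_pres = 0.2) {
  source <- match.arg(source)
  if (source == "synthetic") {
    co <- (seq_len(side) - 0.5) / side
    xg <- matrix(co, side, side); yg <- t(xg)
    images <- lapply(0:9, function(cl) {
      if (cl %% 2 == 0) {
        ang <- pi * cl / 10
        img <- 0.5 + 0.5 * cos(2 * pi * (2 + cl / 2) *
                                 (xg * cos(ang) + yg * sin(ang)))
      } else {
        d <- sqrt((xg - 0.5)^2 + (yg - 0.5)^2)
        img <- exp(-((d - 0.05 * cl) / 0.08)^2)
      }
      pmin(pmax(img, 0), 1)
    })
  } else {
    if (is.null(path)) stop("external source requires a file path")
    df <- utils::read.csv(path, header = FALSE)
    if (ncol(df) != side^2 + 1L)
      stop("expected ", side^2 + 1L, " columns (label + pixels)")
    labs <- df[[1]]
    if (!setequal(labs, 0:9) || nrow(df) != 10L)
      stop("external image file must contain exactly one image per class 0-9")
    df <- df[order(labs), ]
    images <- lapply(seq_len(10), function(i)
      matrix(as.numeric(df[i, -1]), side, side))
  }
  X <- diag(10)
  Y <- do.call(rbind, lapply(images, as.numeric))
  list(data = mc_dataset(X, Y, T_pres = T_pres), images = images, side = side)
}

# ---------------------------------------------------------------------------

#' Serialize a static dataset to CSV
#'
#' Flat layout: one row per item, input columns `x1..xd`, target columns
#' `y1..yk`, plus `T_pres` and `active_from`. Time-series datasets are
#' written in long format with `item`, `tick` and signal columns.
#'
#' @param data An [mc_dataset()].
#' @param path Output file.
#' @export
write_dataset_csv <- function(data, path) {
  if (!data$series) {
    df <- data.frame(data$inputs, data$targets, T_pres = data$T_pres,
                     active_from = data$active_from)
    names(df) <- c(paste0("x", seq_len(data$n_in)),
                   paste0("y", seq_len(data$n_out)), "T_pres", "active_from")
  } else {
    df <- do.call(rbind, lapply(seq_len(data$n), function(i) {
      inp <- data$inputs[[i]]
      data.frame(item = i, tick = seq_len(ncol(inp)), t(inp),
                 target = rep(data$targets[i, 1], ncol(inp)),
                 active_from = data$active_from[i])
    }))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
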