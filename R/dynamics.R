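#' @useDynLib errnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# ---------------------------------------------------------------------------
# Pure-R reference implementation of the network tick.
#
# This file is the readable specification of the dynamics; the compiled core
# in src/mc_core.cpp implements the identical update and is asserted to match
# it bit-for-bit in the test suite. All heavy training runs go through the
# compiled path; the R tick is used for closed-loop control, settling
# experiments and as the cross-check oracle.
#
# Update order within one tick (synchronous across areas):
#   1. all dendritic drives are computed from the previous tick's rates and
#      activation derivatives (u_pred, u_err, error-unit dendritic products,
#      output-area mismatch),
#   2. all somatic voltages take one Euler step,
#   3. prospective voltages, rates and derivatives are recomputed,
#   4. plasticity (if enabled) and the feedback-weight refresh are applied.
# ---------------------------------------------------------------------------

#' Initialise network state at rest
#'
#' All voltages and derivatives start at the leak potential (0); rates and
#' activation derivatives are initialised consistently with the prospective
#' voltage 0.
#'
#' @param net An [mc_network()] object.
#' @return An object of class `"mc_state"`: per-area lists of somatic,
#'   compartment and prospective voltages and rates for both populations.
#' @export
mc_state <- function(net) {
  nA <- length(net$n_R)
  zR <- lapply(net$n_R, numeric)
  zE <- lapply(net$n_E, numeric)
  st <- list(
    u_som = zR, du_som = zR, u_pred = zR, u_err = zR, u_breve = zR,
    r_r = lapply(seq_len(nA), function(l) phi(net$act_r[[l]], numeric(net$n_R[l]))),
    phi_p = lapply(seq_len(nA), function(l) phi_prime(net$act_r[[l]], numeric(net$n_R[l]))),
    e_som = zE, de_som = zE, e_prosp = zE,
    r_E = lapply(seq_len(nA), function(l) phi(net$act_e[[l]], numeric(net$n_E[l])))
  )
  class(st) <- "mc_state"
  st
}

#' Compartment potentials of a representation population
#'
#' The prediction-receiving compartment sums rate inputs from all other
#' areas through the corresponding weight blocks; the error-receiving
#' compartment reads the local error population through `L^RE`.
#'
#' @param net An [mc_network()] object.
#' @param rates_by_area List of representation rate vectors, one per area.
#' @param rates_E_by_area List of error rate vectors, one per area.
#' @param area Target area index.
#' @return List with elements `u_pred` and `u_err`.
#' @export
compartment_potentials <- function(net, rates_by_area, rates_E_by_area, area) {
  u_pred <- numeric(net$n_R[area])
  for (blk in net$W) {
    if (blk$tgt != area) next
    r <- rates_by_area[[blk$src]]
    if (ncol(blk$mat) != length(r))
      stop(sprintf(
        "weight block %d <- %d has %d columns but source area %d provides %d rates",
        blk$tgt, blk$src, ncol(blk$mat), blk$src, length(r)))
    u_pred <- u_pred + drop(blk$mat %*% r)
  }
  u_err <- if (net$n_E[area] > 0L) {
    drop(net$L_RE[[area]] %*% rates_E_by_area[[area]])
  } else {
    numeric(net$n_R[area])
  }
  list(u_pred = u_pred, u_err = u_err)
}

#' One Euler step of a representation population's somatic voltage
#'
#' Leaky integration of the prediction- and error-receiving compartments:
#' `C_m du/dt = -g_l u - g_rep (u - u_pred) - g_err (u - u_err)`.
#'
#' @param u_som Current somatic voltage vector.
#' @param u_pred,u_err Compartment voltages computed for this tick.
#' @param cond An [conductances()] object.
#' @param dt Tick length (> 0).
#' @return List with the updated `u_som` and its derivative `du_som`
#'   (retained for the prospective-rate computation).
#' @export
representation_step <- function(u_som, u_pred, u_err, cond, dt) {
  stopifnot(dt > 0)
  rhs <- function(u) (-cond$g_l * u - cond$g_rep * (u - u_pred) -
                        cond$g_err * (u - u_err)) / cond$C_m
  u <- u_som + dt * rhs(u_som)
  if (any(!is.finite(u)))
    stop(sprintf("non-finite somatic voltage after Euler step (neuron %d)",
                 which(!is.finite(u))[1L]))
  # the stored derivative is the analytic right-hand side at the updated
  # voltage; with tau_r = tau_m this makes the prospective voltage equal
  # (g_rep u_pred + g_err u_err) / g_tot exactly, tick by tick
  list(u_som = u, du_som = rhs(u))
}

#' Prospective rate of a population
#'
#' `rate = phi(u + tau_r * du/dt)` with the analytic right-hand side `du/dt`
#' of the same tick. `tau_r = 0` gives a retrospective (lagging) unit;
#' `tau_r = tau_m` compensates the membrane lag exactly.
#'
#' @param u Voltage vector.
#' @param du_dt Analytic voltage derivative from the same tick.
#' @param tau_r Prospective time constant (>= 0).
#' @param act An [activation_fn()] object.
#' @return Rate vector.
#' @export
prospective_rate <- function(u, du_dt, tau_r, act) {
  phi(act, u + tau_r * du_dt)
}

#' One Euler step of an error population
#'
#' Hidden areas: the soma is pulled towards the product of the
#' representation-receiving dendritic factor `L^ER phi'(u_breve)` and the
#' error-receiving compartment `sum_m B r_E(m)`. The output area instead
#' compares the local representation rate against the target rate,
#' `L^ER phi'(u_breve) * (r_tgt - r_out)`, coupled through `g_nudge`.
#'
#' @param e_som Current error somatic voltage vector.
#' @param dend Dendritic drive vector (`e_rep * e_err` for hidden areas,
#'   the gated mismatch for the output area); must be computed from the
#'   previous tick's rates.
#' @param cond An [conductances()] object.
#' @param mode `"hidden"` or `"output"`.
#' @param dt Tick length.
#' @param tau_r_E Prospective time constant of the error units.
#' @param act Error activation (linear in the reference configuration).
#' @return List with `e_som`, `de_som`, prospective voltage `e_prosp` and
#'   rate `r_E`.
#' @export
error_step <- function(e_som, dend, cond, mode = c("hidden", "output"),
                       dt, tau_r_E, act) {
  mode <- match.arg(mode)
  g_c <- if (mode == "output") cond$g_nudge else cond$g_den
  de <- (-cond$g_l * e_som - g_c * (e_som - dend)) / cond$C_m
  e <- e_som + dt * de
  e_prosp <- e + tau_r_E * ((-cond$g_l * e - g_c * (e - dend)) / cond$C_m)
  list(e_som = e, de_som = de, e_prosp = e_prosp, r_E = phi(act, e_prosp))
}

# dendritic drive of area l's error units from previous-tick quantities
.error_dendrite <- function(net, st, l, target) {
  if (net$n_E[l] == 0L) return(numeric(0))
  e_rep <- drop(net$L_ER[[l]] %*% st$phi_p[[l]])
  if (l == net$target_area) {
    if (is.null(target)) {
      numeric(net$n_E[l])
    } else {
      e_rep * (target - st$r_r[[l]])
    }
  } else {
    e_err <- numeric(net$n_E[l])
    for (blk in net$B) {
      if (blk$tgt != l) next
      e_err <- e_err + drop(blk$mat %*% st$r_E[[blk$src]])
    }
    e_rep * e_err
  }
}

#' Advance the network state by one tick (reference implementation)
#'
#' Applies the full synchronous update described in the package vignette:
#' dendritic drives from the previous tick's rates, Euler steps of all
#' somata, recomputation of prospective rates, then (optionally) the
#' delta-rule weight update and the feedback-weight refresh.
#'
#' @param net An [mc_network()] object (modified weights are returned as
#'   part of the result when plasticity is on).
#' @param st An [mc_state()] object.
#' @param input Rate vector clamped onto the input area.
#' @param target Target rate vector for the output area, or `NULL` when no
#'   target is presented (the output-area error dendrite then sees a zero
#'   mismatch).
#' @param plasticity Apply the delta-rule update and feedback refresh?
#' @return List with elements `state` and `net`.
#' @export
mc_tick <- function(net, st, input, target = NULL, plasticity = FALSE) {
  nA <- length(net$n_R)
  cond <- net$cond
  if (length(input) != net$n_R[net$input_area])
    stop("input length does not match the input area")
  if (!is.null(target) && length(target) != net$n_R[net$target_area])
    stop("target length does not match the target area")

  r_prev <- st$r_r

  # (1) dendritic drives from previous-tick rates
  comp <- lapply(seq_len(nA), function(l)
    compartment_potentials(net, r_prev, st$r_E, l))
  dend <- lapply(seq_len(nA), function(l) .error_dendrite(net, st, l, target))

  # (2)+(3) representation somata, prospective voltages and rates
  for (l in seq_len(nA)) {
    if (l == net$input_area) {
      st$u_som[[l]] <- input
      st$du_som[[l]] <- numeric(net$n_R[l])
      st$u_pred[[l]] <- comp[[l]]$u_pred
      st$u_err[[l]] <- comp[[l]]$u_err
      st$u_breve[[l]] <- input
      st$r_r[[l]] <- input                      # rates clamped, not nudged
      st$phi_p[[l]] <- phi_prime(net$act_r[[l]], input)
    } else {
      stp <- representation_step(st$u_som[[l]], comp[[l]]$u_pred,
                                 comp[[l]]$u_err, cond, net$dt)
      st$u_som[[l]] <- stp$u_som
      st$du_som[[l]] <- stp$du_som
      st$u_pred[[l]] <- comp[[l]]$u_pred
      st$u_err[[l]] <- comp[[l]]$u_err
      st$u_breve[[l]] <- stp$u_som + net$taur_r[l] * stp$du_som
      st$r_r[[l]] <- phi(net$act_r[[l]], st$u_breve[[l]])
      st$phi_p[[l]] <- phi_prime(net$act_r[[l]], st$u_breve[[l]])
    }
  }

  # error populations
  for (l in seq_len(nA)) {
    if (net$n_E[l] == 0L) next
    mode <- if (l == net$target_area) "output" else "hidden"
    es <- error_step(st$e_som[[l]], dend[[l]], cond, mode, net$dt,
                     net$taur_E[l], net$act_e[[l]])
    st$e_som[[l]] <- es$e_som
    st$de_som[[l]] <- es$de_som
    st$e_prosp[[l]] <- es$e_prosp
    st$r_E[[l]] <- es$r_E
  }

  # (4) plasticity and feedback refresh
  if (plasticity) {
    lam <- cond$g_rep / cond$g_tot
    err_form <- identical(net$plasticity_rule, "error_compartment")
    for (i in seq_along(net$W)) {
      blk <- net$W[[i]]
      if (!blk$plastic || blk$eta == 0) next
      post <- if (err_form) {
        (cond$g_err / cond$g_tot) * st$u_err[[blk$tgt]]
      } else {
        st$u_breve[[blk$tgt]] - lam * st$u_pred[[blk$tgt]]
      }
      net$W[[i]]$mat <- blk$mat +
        blk$eta * net$dt * tcrossprod(post, r_prev[[blk$src]])
    }
    net <- refresh_feedback_weights(net)
  }

  list(state = st, net = net)
}

#' Closed-form steady-state prospective error voltages
#'
#' Evaluates the equilibrium recursion for the prospective error voltage in
#' every area, given the activation derivatives and the output mismatch:
#' the output area carries
#' `g_nudge / (g_l + g_nudge) * L^ER phi' * (r_tgt - r_out)`, and each
#' hidden area `g_den / (g_l + g_den) * (L^ER phi') * sum_m B e_m`,
#' evaluated in topological order of the error-projection graph. Serves as
#' the analytic oracle for simulated equilibria.
#'
#' @param net An [mc_network()] object.
#' @param phi_p_by_area List of activation-derivative vectors per area.
#' @param mismatch Output mismatch vector `r_tgt - r_out`.
#' @return List of prospective error-voltage vectors per area.
#' @export
steady_state_errors <- function(net, phi_p_by_area, mismatch) {
  nA <- length(net$n_R)
  cond <- net$cond
  # edges m -> l for every B block (error flows from m into l)
  edges <- lapply(net$B, function(b) c(b$src, b$tgt))
  e_st <- vector("list", nA)
  done <- logical(nA)
  for (l in seq_len(nA)) if (net$n_E[l] == 0L) { e_st[[l]] <- numeric(0); done[l] <- TRUE }

  out <- net$target_area
  e_st[[out]] <- cond$g_nudge / (cond$g_l + cond$g_nudge) *
    drop(net$L_ER[[out]] %*% phi_p_by_area[[out]]) * mismatch
  done[out] <- TRUE

  remaining <- which(!done)
  while (length(remaining) > 0L) {
    progressed <- FALSE
    for (l in remaining) {
      srcs <- vapply(net$B, function(b) if (b$tgt == l) b$src else NA_integer_,
                     integer(1))
      srcs <- srcs[!is.na(srcs)]
      if (all(done[srcs])) {
        acc <- numeric(net$n_E[l])
        for (b in net$B) if (b$tgt == l) acc <- acc + drop(b$mat %*% e_st[[b$src]])
        e_st[[l]] <- cond$g_den / (cond$g_l + cond$g_den) *
          drop(net$L_ER[[l]] %*% phi_p_by_area[[l]]) * acc
        done[l] <- TRUE
        progressed <- TRUE
      }
    }
    if (!progressed)
      stop("cyclic error-projection graph: closed-form steady state unsupported")
    remaining <- which(!done)
  }
  e_st
}

#' Relax the network to (or towards) its fixed point
#'
#' Runs the reference tick with plasticity off for a fixed number of steps
#' under a constant input (and optionally a constant target).
#'
#' @inheritParams mc_tick
#' @param n_ticks Number of settling ticks.
#' @param use_cpp Use the compiled core (default) or the R reference tick.
#' @return The settled `"mc_state"`.
#' @export
mc_settle <- function(net, input, target = NULL, n_ticks,
                      st = NULL, use_cpp = TRUE) {
  if (is.null(st)) st <- mc_state(net)
  if (use_cpp) {
    res <- .mc_present_cpp(net, st, matrix(input, ncol = 1), target,
                           active = if (is.null(target)) integer(0) else seq_len(n_ticks),
                           n_ticks = n_ticks, plasticity = FALSE)
    res$state
  } else {
    for (i in seq_len(n_ticks)) st <- mc_tick(net, st, input, target)$state
    st
  }
}
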