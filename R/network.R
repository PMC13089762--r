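# ---------------------------------------------------------------------------
# Area graph and network construction: loose hierarchy with skip
# connections or strict hierarchy, generative / classifier configuration,
# ablation and activation-variability protocols.
# ---------------------------------------------------------------------------

#' Define the area graph of a microcircuit network
#'
#' Areas are listed in hierarchical order, shallow (primary) end first.
#' In the classifier configuration stimuli enter at the shallow end and
#' representations flow towards the deep end; the generative configuration
#' inverts the flow: a latent input is clamped at the deepest area and the
#' primary area carries the target (stimulus prediction).
#'
#' Inter-area projection strengths are given by a square `density` matrix
#' (rows: source, columns: target). Its diagonal must be zero (within-area
#' recurrence is carried by the local error/representation motif), and all
#' entries below `1e-2` are rounded down to zero. Only entries in the flow
#' direction seed representation-projecting weight blocks; feedback blocks
#' mirror them with reversed direction. A strict hierarchy uses adjacent
#' areas only.
#'
#' @param n_R Integer vector of representation-population sizes per area.
#' @param n_E Error-population sizes (default equal to `n_R`; 0 allowed).
#' @param names Optional area names.
#' @param mode `"classifier"` or `"generative"`.
#' @param hierarchy `"strict"` (adjacent areas only) or `"skip"` (use all
#'   nonzero density entries).
#' @param density Optional square density matrix; defaults to adjacent-area
#'   strength 1 for `"strict"`, or to [default_density()] for `"skip"`.
#' @return An object of class `"mc_area_graph"`.
#' @export
area_graph <- function(n_R, n_E = n_R, names = NULL,
                       mode = c("classifier", "generative"),
                       hierarchy = c("strict", "skip"),
                       density = NULL) {
  mode <- match.arg(mode)
  hierarchy <- match.arg(hierarchy)
  nA <- length(n_R)
  stopifnot(nA >= 2L, length(n_E) == nA, all(n_R >= 1L), all(n_E >= 0L))
  if (is.null(names)) names <- paste0("A", seq_len(nA))
  if (is.null(density)) {
    density <- if (hierarchy == "strict") {
      d <- matrix(0, nA, nA)
      d[cbind(seq_len(nA - 1L), seq_len(nA - 1L) + 1L)] <- 1
      d[cbind(seq_len(nA - 1L) + 1L, seq_len(nA - 1L))] <- 1
      d
    } else {
      default_density(nA)
    }
  }
  stopifnot(is.matrix(density), nrow(density) == nA, ncol(density) == nA)
  if (any(diag(density) != 0))
    stop("density diagonal must be zero (within-area recurrence is local)")
  density[density < 1e-2] <- 0            # round sub-threshold projections down
  if (hierarchy == "strict") {
    adj <- abs(row(density) - col(density)) == 1L
    density[!adj] <- 0
  }
  dimnames(density) <- list(names, names)
  g <- structure(
    list(n_R = as.integer(n_R), n_E = as.integer(n_E), names = names,
         mode = mode, hierarchy = hierarchy, density = density),
    class = "mc_area_graph")
  .set_mode_endpoints(g)
}

.set_mode_endpoints <- function(graph) {
  nA <- length(graph$n_R)
  if (graph$mode == "classifier") {
    graph$input_area <- 1L; graph$target_area <- nA
  } else {
    graph$input_area <- nA; graph$target_area <- 1L
  }
  if (graph$input_area == graph$target_area)
    stop("input and target area must differ")
  graph
}

#' Switch between generative and classifier configuration
#'
#' Swaps the input/target assignment and thereby inverts the direction of
#' the representation stream. Applying the operation twice restores the
#' original graph.
#'
#' @param graph An [area_graph()].
#' @param mode `"classifier"` or `"generative"`.
#' @return The reconfigured graph.
#' @export
configure_mode <- function(graph, mode = c("classifier", "generative")) {
  graph$mode <- match.arg(mode)
  .set_mode_endpoints(graph)
}

#' Default loose-hierarchy projection densities
#'
#' A plausible stand-in for measured inter-area projection densities:
#' strengths decay log-linearly with hierarchical distance
#' (`10^(-(d - 1))` for distance `d`), the diagonal is zero, and entries
#' below the `1e-2` threshold vanish. The matrix is an editable input
#' (see `inst/extdata/visual_density.csv` for the shipped file); measured
#' connectomes can be supplied via [read_density_csv()].
#'
#' @param n_areas Number of areas.
#' @return Square density matrix.
#' @export
default_density <- function(n_areas) {
  d <- abs(outer(seq_len(n_areas), seq_len(n_areas), "-"))
  dens <- 10^(-(d - 1))
  dens[d == 0L] <- 0
  dens[dens < 1e-2] <- 0
  dens
}

#' Read an area-density matrix from CSV
#'
#' Expected format: square numeric matrix with a header row and a leading
#' name column; rows are source areas, columns target areas.
#'
#' @param path CSV file path.
#' @return Named square matrix.
#' @export
read_density_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m)) stop("density matrix must be square")
  m
}

#' Build the weight set for an area graph
#'
#' Representation-projecting blocks `W` are created for every pair of
#' areas with nonzero density in the flow direction, initialised
#' elementwise from `U(-1, 1)` and scaled by the block's density relative
#' to the largest density in the graph (so two blocks with density ratio 3
#' start with weight scales in ratio 3). Feedback blocks `B` mirror the
#' `W` blocks with reversed direction; their frozen noise matrices `Xi`
#' are sampled once here from `U(-b_noise, b_noise)`.
#'
#' Uses the current R random-number state; seed upstream for
#' reproducibility.
#'
#' @param graph An [area_graph()].
#' @param b_noise Half-width of the frozen feedback noise.
#' @return List with elements `W` and `B` (lists of block records).
#' @keywords internal
build_connectivity <- function(graph, b_noise = 0.5) {
  nA <- length(graph$n_R)
  dir <- sign(graph$target_area - graph$input_area)
  W <- list()
  for (src in seq_len(nA)) {
    for (tgt in seq_len(nA)) {
      if (sign(tgt - src) != dir) next
      dens <- graph$density[src, tgt]
      if (dens == 0) next
      scale <- dens / max(graph$density)
      mat <- matrix(stats::runif(graph$n_R[tgt] * graph$n_R[src], -1, 1) * scale,
                    graph$n_R[tgt], graph$n_R[src])
      W[[length(W) + 1L]] <- list(tgt = tgt, src = src, mat = mat,
                                  eta = 0, plastic = TRUE, density = dens)
    }
  }
  B <- list()
  for (i in seq_along(W)) {
    l <- W[[i]]$src; m <- W[[i]]$tgt       # B_{l,m} pairs with W_{m,l}
    if (graph$n_E[l] == 0L || graph$n_E[m] == 0L) next
    Xi <- matrix(stats::runif(graph$n_E[l] * graph$n_E[m], -b_noise, b_noise),
                 graph$n_E[l], graph$n_E[m])
    B[[length(B) + 1L]] <- list(tgt = l, src = m, mat = Xi * 0, Xi = Xi,
                                w_index = i)
  }
  list(W = W, B = B)
}

#' Construct a microcircuit network
#'
#' Assembles the full simulateable network: connectivity, conductances,
#' prospective time constants, activation functions and local couplings.
#' All weights are initialised from the current R random-number state
#' (or from `seed` if given).
#'
#' @param graph An [area_graph()].
#' @param cond An [conductances()] object.
#' @param dt Tick length in time units (> 0).
#' @param act Representation activation: an [activation_fn()] object, a
#'   name string, or a list of one per area.
#' @param act_e Error-unit activation (linear by default; nonlinear error
#'   activations are accepted but are flagged as a non-reference
#'   configuration with a warning).
#' @param taur_r Prospective time constant of representation units:
#'   `"tau_m"` (quasi-instantaneous preset), a number (0 = retrospective),
#'   or a vector per area.
#' @param sigma_L Local-coupling noise half-width.
#' @param b_noise Feedback-weight noise half-width (0 = exact transport).
#' @param eta Learning rate: scalar applied to every weight block, or a
#'   vector with one entry per block.
#' @param settle_steps Plasticity-free settling ticks per presented sample.
#' @param T_pres Presentation duration per sample, in time units.
#' @param plasticity_rule `"dendritic"` (the voltage-mismatch form
#'   `u_breve - (g_rep/g_tot) u_pred`) or `"error_compartment"`
#'   (`(g_err/g_tot) u_err`). The two are algebraically identical for
#'   `tau_r = tau_m`; for retrospective units (`tau_r < tau_m`) only the
#'   error-compartment form is free of the lag-transient term, letting
#'   error units compensate the membrane lag (see the methods vignette).
#' @param seed Optional integer seed used for all initialisation draws.
#' @return An object of class `"mc_network"`.
#' @export
#' @examples
#' g <- area_graph(c(4, 3, 2), mode = "classifier")
#' net <- mc_network(g, eta = 0.05, seed = 1)
#' net
mc_network <- function(graph, cond = conductances(), dt = 0.01,
                       act = "tanh", act_e = "linear",
                       taur_r = "tau_m", sigma_L = 0.3, b_noise = 0.5,
                       eta = 0.01, settle_steps = 10L, T_pres = 0.2,
                       plasticity_rule = c("dendritic", "error_compartment"),
                       seed = NULL) {
  plasticity_rule <- match.arg(plasticity_rule)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(graph, "mc_area_graph"), dt > 0,
            is.na(T_pres) || T_pres >= dt)
  nA <- length(graph$n_R)

  as_act_list <- function(a) {
    if (inherits(a, "mc_activation")) a <- list(a)
    if (is.character(a)) a <- lapply(a, activation_fn)
    if (length(a) == 1L) a <- rep(a, nA)
    stopifnot(length(a) == nA)
    a
  }
  act_r <- as_act_list(act)
  act_e <- as_act_list(act_e)
  act_r <- lapply(seq_len(nA), function(l) .act_expand(act_r[[l]], graph$n_R[l]))
  act_e <- lapply(seq_len(nA), function(l) .act_expand(act_e[[l]], graph$n_E[l]))
  if (any(vapply(act_e, function(a) a$name, "") != "linear"))
    warning("nonlinear error-unit activation: outside the reference configuration")

  loc <- lapply(seq_len(nA), function(l)
    init_local_weights(graph$n_R[l], graph$n_E[l], sigma_L))
  conn <- build_connectivity(graph, b_noise = b_noise)
  eta <- rep_len(eta, length(conn$W))
  for (i in seq_along(conn$W)) conn$W[[i]]$eta <- eta[i]

  tau_m_r <- cond$tau_m_r
  if (identical(taur_r, "tau_m")) taur_r <- tau_m_r
  taur_r <- rep_len(as.numeric(taur_r), nA)
  if (any(taur_r < 0)) stop("taur_r must be >= 0")
  taur_E <- ifelse(seq_len(nA) == graph$target_area,
                   cond$tau_m_E_output, cond$tau_m_E_hidden)

  net <- structure(
    list(graph = graph,
         n_R = graph$n_R, n_E = graph$n_E,
         input_area = graph$input_area, target_area = graph$target_area,
         cond = cond, dt = dt,
         taur_r = taur_r, taur_E = taur_E,
         act_r = act_r, act_e = act_e,
         L_RE = lapply(loc, `[[`, "L_RE"),
         L_ER = lapply(loc, `[[`, "L_ER"),
         W = conn$W, B = conn$B,
         sigma_L = sigma_L, b_noise = b_noise,
         settle_steps = as.integer(settle_steps), T_pres = T_pres,
         plasticity_rule = plasticity_rule, seed = seed),
    class = "mc_network")
  refresh_feedback_weights(net)
}

#' @export
print.mc_network <- function(x, ...) {
  g <- x$graph
  cat(sprintf("<mc_network: %d areas [%s], %s %s>\n",
              length(x$n_R), paste(x$n_R, collapse = "-"),
              g$hierarchy, g$mode))
  cat(sprintf("  error units [%s]; input area %d, target area %d\n",
              paste(x$n_E, collapse = "-"), x$input_area, x$target_area))
  cat(sprintf("  %d forward block(s), %d feedback block(s); dt = %g, T_pres = %g\n",
              length(x$W), length(x$B), x$dt, x$T_pres))
  cat(sprintf("  tau_m^r = %.4g; sigma_L = %g; feedback noise = %g\n",
              x$cond$tau_m_r, x$sigma_L, x$b_noise))
  invisible(x)
}

#' Ablate an inter-area projection
#'
#' Zeros the representation-projecting block from `src` to `tgt`, freezes
#' its learning rate (no regrowth of synapses between the two areas) and
#' clears the frozen noise of the mirrored feedback block so the error
#' route through the ablated projection vanishes as well. Ablating an
#' absent or already-ablated block is a no-op.
#'
#' @param net An [mc_network()] object.
#' @param src,tgt Source and target area indices of the projection.
#' @param freeze Disallow regrowth (forces the block's learning rate to 0).
#' @return The modified network.
#' @export
ablate_projection <- function(net, src, tgt, freeze = TRUE) {
  idx <- which(vapply(net$W, function(b) b$src == src && b$tgt == tgt, NA))
  if (length(idx) == 0L)
    stop(sprintf("no projection block from area %d to area %d", src, tgt))
  net$W[[idx]]$mat[] <- 0
  if (freeze) {
    net$W[[idx]]$eta <- 0
    net$W[[idx]]$plastic <- FALSE
  }
  bidx <- which(vapply(net$B, function(b) b$w_index == idx, NA))
  for (i in bidx) net$B[[i]]$Xi[] <- 0
  refresh_feedback_weights(net)
}

#' Apply per-neuron activation variability
#'
#' Draws per-neuron slopes from `N(1, sigma_act)` and offsets from
#' `N(0, sigma_act)` and installs them into the chosen populations, so
#' neuron `i` computes `phi(a_i * u + b_i)`. With linear error units this
#' turns error rates into `a_i * e + b_i`, i.e. offsets can flip error
#' signs.
#'
#' @param net An [mc_network()] object.
#' @param sigma_act Standard deviation of slopes and offsets (>= 0).
#' @param apply_to `"representation"`, `"error"` or `"both"`.
#' @return The modified network.
#' @export
apply_variability <- function(net, sigma_act,
                              apply_to = c("representation", "error", "both")) {
  apply_to <- match.arg(apply_to)
  stopifnot(sigma_act >= 0)
  if (sigma_act == 0) return(net)
  vary <- function(act, n) {
    act$slope <- stats::rnorm(n, 1, sigma_act)
    act$offset <- stats::rnorm(n, 0, sigma_act)
    act
  }
  for (l in seq_along(net$n_R)) {
    if (apply_to %in% c("representation", "both"))
      net$act_r[[l]] <- vary(net$act_r[[l]], net$n_R[l])
    if (apply_to %in% c("error", "both"))
      net$act_e[[l]] <- vary(net$act_e[[l]], net$n_E[l])
  }
  net
}

# --- packing helpers for the compiled core ---------------------------------

.pack_act <- function(act) {
  list(code = act_codes[[act$name]], beta = act$beta, scale = act$scale,
       shift = act$shift, slope = as.numeric(act$slope),
       offset = as.numeric(act$offset))
}

.pack_net <- function(net) {
  net$act_r_packed <- lapply(net$act_r, .pack_act)
  net$act_e_packed <- lapply(net$act_e, .pack_act)
  net$cond <- unclass(net$cond)
  net$rule_code <- if (identical(net$plasticity_rule, "error_compartment")) 1L else 0L
  net
}

# run items through the compiled core, returning updated net + state
.mc_run <- function(net, st, items, plasticity) {
  res <- .cpp_run(.pack_net(net), st, items, plasticity, net$settle_steps)
  for (i in seq_along(net$W)) net$W[[i]]$mat <- res$W[[i]]
  for (i in seq_along(net$B)) net$B[[i]]$mat <- res$B[[i]]
  list(net = net, state = res$state, outputs = res$outputs)
}

# single-item convenience wrapper used by mc_settle()
.mc_present_cpp <- function(net, st, input, target, active, n_ticks, plasticity) {
  item <- list(input = input,
               target = if (is.null(target)) numeric(0) else target,
               active_from = if (is.null(target)) -1L else 1L,
               T_ticks = as.integer(n_ticks))
  net0 <- net
  net0$settle_steps <- 0L
  res <- .mc_run(net0, st, list(item), plasticity)
  list(state = res$state, net = res$net, outputs = res$outputs)
}
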