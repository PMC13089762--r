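# ---------------------------------------------------------------------------
# Shipped experiment recipes: network builders carrying the reference
# parameter sets of each benchmark (conductances, time constants,
# activations, noise levels), with per-task tuned learning rates as the
# only free parameter group.
# ---------------------------------------------------------------------------

#' Microcircuit for the teacher-student (multi-area) benchmark
#'
#' Strict classifier hierarchy with the multi-area parameter set:
#' `g_l = 0.03, g_rep = 0.1, g_err = 0.06, g_den = 0.1, g_nudge = 0.06`,
#' `dt = 0.01`, presentation `T_pres = 0.2`, quasi-instantaneous
#' representation units, tanh activations, local noise `sigma_L = 0.3`
#' and feedback noise `U(-0.5, 0.5)`.
#'
#' @param arch Layer sizes (input first), e.g. `c(8, 4, 2, 1)`.
#' @param eta Learning rate for all weight blocks.
#' @param sigma_L,b_noise Local / feedback noise half-widths.
#' @param seed Optional initialisation seed.
#' @param ... Further arguments to [mc_network()].
#' @return An [mc_network()].
#' @export
ts_network <- function(arch, eta = 2, sigma_L = 0.3, b_noise = 0.5,
                       seed = NULL, ...) {
  g <- area_graph(arch, mode = "classifier", hierarchy = "strict")
  mc_network(g, cond = conductances(), dt = 0.01, act = "tanh",
             taur_r = "tau_m", sigma_L = sigma_L, b_noise = b_noise,
             eta = eta, settle_steps = 10L, T_pres = 0.2, seed = seed, ...)
}

#' Microcircuit for the delayed match-to-sample task
#'
#' Two hidden and one output representation neuron (plus the clamped
#' scalar input area), with slow membranes: the leak is raised to
#' `g_l = 0.3` so that `tau_m^r ~= 2.2` time units (~220 ms at the
#' 100 ms unit), and representation units are retrospective
#' (`tau_r = 0`), encoding short-term memory in the membrane. Hidden
#' units use a sharp softplus, the readout `20 tanh(x - 0.5)`.
#'
#' @param eta Learning rate.
#' @param sigma_L Local noise half-width.
#' @param seed Optional initialisation seed.
#' @return An [mc_network()].
#' @export
dms_network <- function(eta = 1, sigma_L = 0.3, seed = NULL) {
  g <- area_graph(c(1, 2, 1), n_E = c(0, 2, 1), mode = "classifier",
                  hierarchy = "strict")
  mc_network(
    g, cond = conductances(g_l = 0.3), dt = 0.01,
    act = list(activation_fn("linear"),
               activation_fn("softplus", beta = 10),
               activation_fn("scaled_tanh", scale = 20, shift = 0.5)),
    taur_r = 0, sigma_L = sigma_L, b_noise = 0.5, eta = eta,
    settle_steps = 10L, T_pres = NA,
    plasticity_rule = "error_compartment", seed = seed)
}

#' Microcircuit for the cart-pole distillation task
#'
#' Four input and one output representation unit (five error units in
#' total), weak nudging `g_err = 6e-4` to slow learning. The `"ideal"`
#' variant uses linear activations and exact one-to-one local coupling
#' (`sigma_L = 0`); the `"realistic"` variant uses tanh activations and
#' local-weight noise `sigma_L = 0.3`. (A noise half-width of 3 flips the
#' sign of the scalar output-area coupling in almost half of all draws and
#' makes the trained controller fall; see the methods vignette.)
#'
#' @param variant `"realistic"` or `"ideal"`.
#' @param eta Learning rate.
#' @param seed Optional initialisation seed.
#' @return An [mc_network()].
#' @export
cartpole_network <- function(variant = c("realistic", "ideal"), eta = 50,
                             seed = NULL) {
  variant <- match.arg(variant)
  g <- area_graph(c(4, 1), mode = "classifier", hierarchy = "strict")
  mc_network(
    g, cond = conductances(g_err = 6e-4), dt = 0.01,
    act = if (variant == "ideal") "linear" else "tanh",
    taur_r = "tau_m",
    sigma_L = if (variant == "ideal") 0 else 0.3,
    b_noise = 0.5, eta = eta, settle_steps = 10L, T_pres = 1, seed = seed)
}

#' Microcircuit for the Yin-Yang classification task
#'
#' Network `[4-30-3]` in the classifier configuration with reduced noise
#' (`sigma_L = 0.1`, feedback noise `U(-0.1, 0.1)`).
#'
#' @param eta Learning rate.
#' @param seed Optional initialisation seed.
#' @return An [mc_network()].
#' @export
yinyang_network <- function(eta = 5, seed = NULL) {
  g <- area_graph(c(4, 30, 3), mode = "classifier", hierarchy = "strict")
  mc_network(g, cond = conductances(), dt = 0.01, act = "tanh",
             taur_r = "tau_m", sigma_L = 0.1, b_noise = 0.1, eta = eta,
             settle_steps = 10L, T_pres = 0.2, seed = seed)
}

#' Microcircuit for the generative image task
#'
#' Generative configuration: the one-hot class latent is clamped at the
#' deepest area and the primary area (one unit per pixel) carries the
#' image target. Sigmoid activations match the pixel range; local noise
#' is scaled down to `sigma_L = 0.03` to keep all-to-all local coupling
#' stable.
#'
#' @param side Image side length (pixels).
#' @param hidden Hidden-area sizes, deepest last (e.g. `c(500, 500)` or a
#'   single size).
#' @param hierarchy `"strict"` or `"skip"` (skip connections between all
#'   areas in the flow direction).
#' @param eta Learning rate.
#' @param sigma_L Local noise half-width.
#' @param seed Optional initialisation seed.
#' @return An [mc_network()]; areas are ordered primary (pixels) first,
#'   then the hidden areas, then the 10-unit latent area.
#' @export
generative_network <- function(side = 28L, hidden = c(500L),
                               hierarchy = c("strict", "skip"),
                               eta = 3, sigma_L = 0.03, seed = NULL) {
  hierarchy <- match.arg(hierarchy)
  sizes <- c(side^2, hidden, 10L)
  g <- area_graph(sizes, mode = "generative", hierarchy = hierarchy,
                  names = c("V1", paste0("H", seq_along(hidden)), "latent"))
  mc_network(g, cond = conductances(), dt = 0.01, act = "sigmoid",
             taur_r = "tau_m", sigma_L = sigma_L, b_noise = 0.5, eta = eta,
             settle_steps = 10L, T_pres = 0.2, seed = seed)
}

#' Ideal backpropagation configuration
#'
#' Strict hierarchy with identity local coupling (`sigma_L = 0`),
#' noiseless weight transport (`B = W^T`), quasi-instantaneous units and
#' vanishing nudging (`g_err = 1e-4`): the configuration in which the
#' microcircuit's delta-rule updates recover the backpropagation
#' gradients of the equivalent layered network ([as_ann()]).
#'
#' @param arch Layer sizes (input first).
#' @param act Activation name or object.
#' @param g_err Nudging conductance (small).
#' @param eta Learning rate.
#' @param seed Optional initialisation seed.
#' @return An [mc_network()].
#' @export
ideal_bp_network <- function(arch, act = "tanh", g_err = 1e-4, eta = 1,
                             seed = NULL) {
  g <- area_graph(arch, mode = "classifier", hierarchy = "strict")
  mc_network(g, cond = conductances(g_err = g_err), dt = 0.01, act = act,
             taur_r = "tau_m", sigma_L = 0, b_noise = 0, eta = eta,
             settle_steps = 10L, T_pres = 0.2, seed = seed)
}
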