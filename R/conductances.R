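#' Compartment conductances and derived time constants
#'
#' Collects the membrane capacitance and the coupling conductances of the
#' two cell classes. Units follow the convention `C_m = 1`, so conductances
#' are inverse time units and the leak potential is fixed at 0.
#'
#' Derived quantities:
#' * total conductance of a representation soma, `g_tot = g_l + g_rep + g_err`
#' * representation membrane time constant `tau_m_r = C_m / g_tot`
#' * error-unit membrane time constants `tau_m_E = C_m / (g_l + g_den)`
#'   (hidden areas) and `C_m / (g_l + g_nudge)` (output area)
#'
#' @param g_l Somatic leak conductance.
#' @param g_rep Coupling of the prediction-receiving compartment.
#' @param g_err Coupling of the error-receiving compartment onto the
#'   representation soma (the "nudging" strength of errors; small values
#'   recover backpropagation-like learning, large values target-clamping).
#' @param g_den Coupling of the error-unit dendrite to its soma.
#' @param g_nudge Output-area nudging conductance.
#' @param C_m Membrane capacitance (must be positive).
#' @return An object of class `"mc_conductances"` with the derived fields
#'   `g_tot`, `tau_m_r`, `tau_m_E_hidden` and `tau_m_E_output`.
#' @export
#' @examples
#' co <- conductances()           # multi-area defaults
#' co$tau_m_r                     # 1 / 0.19 ~= 5.26 time units
conductances <- function(g_l = 0.03, g_rep = 0.1, g_err = 0.06,
                         g_den = 0.1, g_nudge = 0.06, C_m = 1) {
  g <- c(g_l = g_l, g_rep = g_rep, g_err = g_err,
         g_den = g_den, g_nudge = g_nudge)
  if (any(!is.finite(g)) || any(g < 0))
    stop("all conductances must be finite and >= 0")
  if (!is.finite(C_m) || C_m <= 0) stop("C_m must be positive")
  g_tot <- g_l + g_rep + g_err
  structure(
    list(g_l = g_l, g_rep = g_rep, g_err = g_err, g_den = g_den,
         g_nudge = g_nudge, C_m = C_m, E_l = 0,
         g_tot = g_tot,
         tau_m_r = C_m / g_tot,
         tau_m_E_hidden = C_m / (g_l + g_den),
         tau_m_E_output = C_m / (g_l + g_nudge)),
    class = "mc_conductances"
  )
}

#' @export
print.mc_conductances <- function(x, ...) {
  cat("<mc_conductances>\n")
  cat(sprintf("  g_l = %g, g_rep = %g, g_err = %g, g_den = %g, g_nudge = %g (C_m = %g)\n",
              x$g_l, x$g_rep, x$g_err, x$g_den, x$g_nudge, x$C_m))
  cat(sprintf("  g_tot = %g, tau_m^r = %.4g, tau_m^E = %.4g (hidden) / %.4g (output)\n",
              x$g_tot, x$tau_m_r, x$tau_m_E_hidden, x$tau_m_E_output))
  invisible(x)
}
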