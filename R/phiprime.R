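# ---------------------------------------------------------------------------
# Noise-driven local reconstruction of the activation derivative phi'(u)
# in error-unit dendrites: white noise on the presynaptic voltage, a
# first-order high-pass filter, rectified-linear gating and temporal
# averaging. For Gaussian noise of (post-filter) standard deviation s and
# phi' >= 0, E[relu(xi * phi')] = s * phi' / sqrt(2*pi), so the average
# rectified filtered rate is proportional to phi'(u).
# ---------------------------------------------------------------------------

#' First-order high-pass filter
#'
#' Subtracts an exponential moving average with time constant `tau_xi`
#' (in ticks): `l_t = l_{t-1} + (r_t - l_{t-1}) / tau_xi`,
#' `r_hat_t = r_t - l_t`. The accumulator is initialised at the first
#' sample, so a constant input is rejected from the start and a step
#' produces a transient of the step height decaying with `tau_xi`.
#'
#' @param r Numeric input sequence.
#' @param tau_xi Filter time constant in ticks (> 0).
#' @return Filtered sequence of the same length.
#' @export
high_pass_filter <- function(r, tau_xi) {
  stopifnot(tau_xi > 0)
  alpha <- 1 / tau_xi
  l <- r[1]
  out <- numeric(length(r))
  for (t in seq_along(r)) {
    l <- l + alpha * (r[t] - l)
    out[t] <- r[t] - l
  }
  out
}

#' Reconstruct the activation derivative from noisy rates
#'
#' Simulates `r_t = phi(u + xi_t)` with white noise
#' `xi_t ~ N(0, sigma_xi)` for `T_pres` ticks, high-pass filters the rate
#' trace, applies rectified-linear gating and averages over the window
#' (optionally over several presentations). The result is proportional to
#' `phi'(u)` for sufficiently smooth, monotone activations in the
#' small-noise regime `|u| >> |xi|`.
#'
#' @param u Signal voltage (scalar) encoded by the representation unit.
#' @param act An [activation_fn()].
#' @param sigma_xi Noise standard deviation.
#' @param tau_xi High-pass time constant in ticks.
#' @param T_pres Presentation window in ticks (warns when `<= tau_xi`).
#' @param n_pres Number of presentations averaged.
#' @param burn_in Ticks discarded from the start of each window while the
#'   high-pass accumulator settles (default `2 * tau_xi`); without it the
#'   filter's start-up transient biases the average.
#' @return Scalar estimate `mean(relu(r_hat))`, proportional to `phi'(u)`
#'   with constant approximately `sd(filtered noise) / sqrt(2*pi)`.
#' @export
reconstruct_phi_prime <- function(u, act, sigma_xi = 0.05, tau_xi = 10,
                                  T_pres = 100, n_pres = 20,
                                  burn_in = ceiling(2 * tau_xi)) {
  if (T_pres <= tau_xi)
    warning("T_pres <= tau_xi: derivative estimate is unreliable")
  stopifnot(burn_in < T_pres)
  est <- vapply(seq_len(n_pres), function(p) {
    xi <- stats::rnorm(T_pres, 0, sigma_xi)
    r <- phi(act, u + xi)
    h <- high_pass_filter(r, tau_xi)
    if (burn_in > 0) h <- h[-seq_len(burn_in)]
    mean(pmax(h, 0))
  }, 0)
  mean(est)
}

#' Sweep the derivative reconstruction over a voltage range
#'
#' Convenience wrapper producing, per activation function, the analytic
#' derivative and its dendritic reconstruction on a voltage grid; the
#' backing computation for the derivative-reconstruction demo.
#'
#' @param acts Named list of [activation_fn()] objects.
#' @param u_grid Voltages to probe.
#' @param ... Passed to [reconstruct_phi_prime()].
#' @return Data frame with columns `activation`, `u`, `analytic`,
#'   `estimate`.
#' @export
phi_prime_profile <- function(acts = list(tanh = activation_fn("tanh"),
                                          sigmoid = activation_fn("sigmoid"),
                                          softplus = activation_fn("softplus", beta = 1)),
                              u_grid = seq(-2, 2, by = 0.1), ...) {
  do.call(rbind, lapply(names(acts), function(nm) {
    est <- vapply(u_grid, reconstruct_phi_prime, 0, act = acts[[nm]], ...)
    data.frame(activation = nm, u = u_grid,
               analytic = phi_prime(acts[[nm]], u_grid), estimate = est)
  }))
}
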