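# ---------------------------------------------------------------------------
# Plasticity: always-on delta rule for representation weights, static noisy
# local couplings, and the approximate feedback-weight refresh (transpose of
# the forward weights plus frozen noise, standing in for fully dynamical
# phaseless alignment learning of the feedback projections).
# ---------------------------------------------------------------------------

#' Delta-rule weight increment
#'
#' The postsynaptic factor is the mismatch between the prospective somatic
#' voltage and the conductance-weighted dendritic prediction,
#' `u_breve - (g_rep / g_tot) * u_pred`; the presynaptic factor is the rate
#' vector that formed `u_pred` on the same tick. For `tau_r = tau_m` this is
#' algebraically identical to `(g_err / g_tot) * u_err * r_pre^T`, i.e. the
#' update is driven purely by the error-receiving compartment.
#'
#' @param u_breve Prospective somatic voltage of the postsynaptic area.
#' @param u_pred Prediction-compartment voltage of the same tick.
#' @param r_pre Presynaptic rate vector.
#' @param cond An [conductances()] object.
#' @param eta Learning rate of the weight block.
#' @param dt Tick length.
#' @param form `"dendritic"` uses the voltage-mismatch postsynaptic factor;
#'   `"error_compartment"` uses `(g_err / g_tot) * u_err` (requires
#'   `u_err`). Identical for `tau_r = tau_m`.
#' @param u_err Error-compartment voltage (for the error-compartment form).
#' @return The increment matrix `eta * dt * post %o% r_pre` (rows:
#'   postsynaptic neurons, columns: presynaptic neurons); empty blocks give
#'   empty matrices.
#' @export
delta_rule_update <- function(u_breve, u_pred, r_pre, cond, eta, dt,
                              form = c("dendritic", "error_compartment"),
                              u_err = NULL) {
  form <- match.arg(form)
  post <- if (form == "dendritic") {
    u_breve - (cond$g_rep / cond$g_tot) * u_pred
  } else {
    (cond$g_err / cond$g_tot) * u_err
  }
  eta * dt * tcrossprod(post, r_pre)
}

#' Padded identity matrix
#'
#' Rectangular "identity" coupling between populations of different sizes:
#' exactly `min(nrow, ncol)` ones on the leading diagonal positions, zeros
#' elsewhere. For example `padded_identity(2, 3)` is
#' `[[1,0,0],[0,1,0]]`.
#'
#' @param n_row,n_col Matrix dimensions.
#' @return A `n_row x n_col` matrix.
#' @export
padded_identity <- function(n_row, n_col) {
  m <- matrix(0, n_row, n_col)
  k <- min(n_row, n_col)
  if (k > 0L) m[cbind(seq_len(k), seq_len(k))] <- 1
  m
}

#' Initialise static local couplings with preferential targeting
#'
#' Local error-to-representation (`L^RE`, `n_R x n_E`) and
#' representation-to-error (`L^ER`, `n_E x n_R`) weights are padded
#' identities perturbed by elementwise uniform noise of half-width
#' `sigma_L`, modelling noisy preferential targeting between the two
#' populations. Local weights are static: they are sampled once and never
#' learned.
#'
#' @param n_R,n_E Population sizes.
#' @param sigma_L Noise half-width (>= 0).
#' @return List with matrices `L_RE` and `L_ER`.
#' @export
init_local_weights <- function(n_R, n_E, sigma_L) {
  if (!is.finite(sigma_L) || sigma_L < 0)
    stop("sigma_L must be a nonnegative number")
  noise <- function(nr, nc) {
    if (sigma_L == 0 || nr == 0L || nc == 0L) matrix(0, nr, nc)
    else matrix(stats::runif(nr * nc, -sigma_L, sigma_L), nr, nc)
  }
  list(L_RE = padded_identity(n_R, n_E) + noise(n_R, n_E),
       L_ER = padded_identity(n_E, n_R) + noise(n_E, n_R))
}

# padded transpose core of the feedback refresh:
# B_{l,m} = [1^ER_{m,m} W_{m,l} 1^RE_{l,l}]^T  (shape n_E(l) x n_E(m))
.padded_transpose <- function(W, n_E_tgt, n_E_src) {
  B <- matrix(0, n_E_tgt, n_E_src)
  k_src <- min(n_E_src, nrow(W))
  k_tgt <- min(n_E_tgt, ncol(W))
  if (k_src > 0L && k_tgt > 0L)
    B[seq_len(k_tgt), seq_len(k_src)] <- t(W[seq_len(k_src), seq_len(k_tgt), drop = FALSE])
  B
}

#' Refresh the error-projecting weights
#'
#' Sets every feedback block to the padded transpose of its forward
#' counterpart plus the frozen noise matrix sampled at network
#' initialisation: `B_{l,m} = [1^ER W_{m,l} 1^RE]^T + Xi_{l,m}`. Applied
#' after every tick during training; refreshing twice without a change in
#' `W` leaves `B` unchanged.
#'
#' @param net An [mc_network()] object.
#' @return The network with refreshed `B` blocks.
#' @export
refresh_feedback_weights <- function(net) {
  for (i in seq_along(net$B)) {
    b <- net$B[[i]]
    W <- net$W[[b$w_index]]$mat
    core <- .padded_transpose(W, net$n_E[b$tgt], net$n_E[b$src])
    if (!identical(dim(core), dim(b$Xi)))
      stop("internal error: padded transpose does not match feedback block shape")
    net$B[[i]]$mat <- core + b$Xi
  }
  net
}
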