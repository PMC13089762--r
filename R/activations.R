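#' Activation functions with per-neuron gain and offset
#'
#' Builds an activation object used by representation and error populations.
#' Each neuron `i` applies the nominal function to an affine-transformed
#' voltage, `phi_i(u) = f(a_i * u + b_i)`, where `a_i` is a dimensionless
#' per-neuron slope (gain) and `b_i` a per-neuron offset in voltage units.
#' With `slope = 1` and `offset = 0` the nominal form is recovered.
#'
#' Supported nominal forms:
#' \describe{
#'   \item{`linear`}{`f(x) = x`}
#'   \item{`tanh`}{`f(x) = tanh(x)`}
#'   \item{`sigmoid`}{`f(x) = 1 / (1 + exp(-x))`}
#'   \item{`softplus`}{`f(x) = log(1 + exp(beta * x)) / beta`}
#'   \item{`scaled_tanh`}{`f(x) = scale * tanh(x - shift)`, e.g. the smooth
#'     binary readout `20 * tanh(x - 0.5)` used for match/non-match decisions}
#'   \item{`relu`}{`f(x) = max(x, 0)`}
#' }
#'
#' @param name One of `"linear"`, `"tanh"`, `"sigmoid"`, `"softplus"`,
#'   `"scaled_tanh"`, `"relu"`.
#' @param beta Sharpness of the softplus (ignored otherwise).
#' @param scale,shift Parameters of `scaled_tanh` (ignored otherwise).
#' @param slope,offset Per-neuron gain and shift; scalars are recycled to the
#'   population size at evaluation time.
#' @return An object of class `"mc_activation"`.
#' @seealso [phi()], [phi_prime()], [apply_variability()]
#' @export
#' @examples
#' act <- activation_fn("tanh")
#' phi(act, c(-1, 0, 1))
#' phi_prime(act, 0)           # 1 - tanh(0)^2 = 1
activation_fn <- function(name = c("linear", "tanh", "sigmoid", "softplus",
                                   "scaled_tanh", "relu"),
                          beta = 1, scale = 1, shift = 0,
                          slope = 1, offset = 0) {
  name <- match.arg(name)
  if (beta <= 0) stop("softplus `beta` must be positive")
  structure(
    list(name = name, beta = beta, scale = scale, shift = shift,
         slope = slope, offset = offset),
    class = "mc_activation"
  )
}

act_codes <- c(linear = 0L, tanh = 1L, sigmoid = 2L, softplus = 3L,
               scaled_tanh = 4L, relu = 5L)

.act_affine <- function(act, u) {
  act$slope * u + act$offset
}

#' Evaluate an activation function
#'
#' @param act An [activation_fn()] object.
#' @param u Voltage vector.
#' @return Rate vector `phi(slope * u + offset)`.
#' @export
phi <- function(act, u) {
  x <- .act_affine(act, u)
  switch(act$name,
    linear      = x,
    tanh        = tanh(x),
    sigmoid     = 1 / (1 + exp(-x)),
    softplus    = .softplus(x, act$beta),
    scaled_tanh = act$scale * tanh(x - act$shift),
    relu        = pmax(x, 0)
  )
}

#' Evaluate the derivative of an activation function with respect to voltage
#'
#' Includes the per-neuron slope factor by the chain rule:
#' `d/du f(a*u + b) = a * f'(a*u + b)`.
#'
#' @inheritParams phi
#' @return Derivative vector.
#' @export
phi_prime <- function(act, u) {
  x <- .act_affine(act, u)
  d <- switch(act$name,
    linear      = rep_len(1, length(x)),
    tanh        = 1 - tanh(x)^2,
    sigmoid     = { s <- 1 / (1 + exp(-x)); s * (1 - s) },
    softplus    = 1 / (1 + exp(-act$beta * x)),
    scaled_tanh = act$scale * (1 - tanh(x - act$shift)^2),
    relu        = as.numeric(x > 0)
  )
  act$slope * d
}

# numerically safe softplus: log(1+exp(b x))/b without overflow
.softplus <- function(x, beta) {
  bx <- beta * x
  (pmax(bx, 0) + log1p(exp(-abs(bx)))) / beta
}

#' @export
print.mc_activation <- function(x, ...) {
  extra <- switch(x$name,
    softplus = sprintf(" (beta = %g)", x$beta),
    scaled_tanh = sprintf(" (scale = %g, shift = %g)", x$scale, x$shift),
    "")
  het <- if (length(x$slope) > 1L || length(x$offset) > 1L ||
             any(x$slope != 1) || any(x$offset != 0)) " [heterogeneous]" else ""
  cat(sprintf("<mc_activation: %s%s%s>\n", x$name, extra, het))
  invisible(x)
}

# expand slope/offset to population size n (used when packing for the C++ core)
.act_expand <- function(act, n) {
  act$slope <- rep_len(act$slope, n)
  act$offset <- rep_len(act$offset, n)
  act
}
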