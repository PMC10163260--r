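# Learnable Weibull activation, global average pooling and power
# normalisation: the aggregation head shared by the dual-stream and
# cell-level models. The activation dampens weak feature responses and
# equalises a tunable proportion of strong ones before pooling.

#' Elementwise Weibull activation
#'
#' Transforms a nonnegative feature tensor R elementwise into
#' \deqn{T_i = (R_i/\lambda)^{\zeta-1} \exp(-(R_i/\gamma)^\eta)}
#' with positive scale parameters \eqn{\lambda, \gamma} and shape
#' parameters \eqn{\zeta, \eta}; all four are learnable scalars in the
#' network layers built on this function.
#'
#' @param R nonnegative numeric array (feature tensor).
#' @param lambda,zeta,gamma,eta positive parameters.
#' @param eps if positive, inputs are clamped below at \code{eps} before
#'   the fractional powers (used by the training layers for gradient
#'   stability; the default 0 evaluates the formula exactly).
#' @return Array of the same shape as \code{R}.
#' @examples
#' weibullActivation(1, lambda = 1, zeta = 2, gamma = 1, eta = 1) # exp(-1)
#' @export
weibullActivation <- function(R, lambda = 1, zeta = 2, gamma = 1, eta = 1,
                              eps = 0) {
  if (any(c(lambda, zeta, gamma, eta) <= 0))
    .stopf("Weibull parameters must be strictly positive")
  if (any(R < 0))
    .stopf("negative input to the Weibull activation is undefined for non-integer shape")
  Rc <- if (eps > 0) pmax(R, eps) else R
  (Rc / lambda)^(zeta - 1) * exp(-(Rc / gamma)^eta)
}

#' Analytic gradients of the Weibull activation
#'
#' Elementwise partial derivatives of \code{\link{weibullActivation}} with
#' respect to the input and the four parameters, valid for inputs > 0.
#'
#' @inheritParams weibullActivation
#' @return A list with arrays \code{dR}, \code{dLambda}, \code{dZeta},
#'   \code{dGamma}, \code{dEta}, each the same shape as \code{R}.
#' @export
weibullGradients <- function(R, lambda = 1, zeta = 2, gamma = 1, eta = 1,
                             eps = 1e-8) {
  Rc <- pmax(R, eps)
  Tv <- (Rc / lambda)^(zeta - 1) * exp(-(Rc / gamma)^eta)
  pg <- (Rc / gamma)^eta
  list(
    dR = Tv * ((zeta - 1) / Rc - (eta / Rc) * pg),
    dLambda = Tv * (-(zeta - 1) / lambda),
    dZeta = Tv * log(Rc / lambda),
    dGamma = Tv * (eta * pg / gamma),
    dEta = Tv * (-pg * log(Rc / gamma)),
    value = Tv)
}

#' Global average pooling
#'
#' Averages a height x width x D feature tensor over its spatial
#' dimensions, producing the length-D global descriptor
#' \eqn{S_k = (WH)^{-1} \sum_{i}\sum_{j} T_{ijk}}.
#'
#' @param T numeric array of dimension H x W x D (a matrix is treated as
#'   H x W x 1).
#' @return Numeric vector of length D.
#' @export
globalAveragePool <- function(T) {
  if (is.matrix(T)) T <- array(T, dim = c(dim(T), 1L))
  if (length(dim(T)) != 3L) .stopf("expected an H x W x D tensor")
  apply(T, 3, mean)
}

#' Power normalisation
#'
#' Elementwise \eqn{\alpha s^\beta} on a nonnegative descriptor, balancing
#' the non-linear scaling introduced by the Weibull activation. Strictly
#' monotone increasing for \eqn{\alpha, \beta > 0}.
#'
#' @param S nonnegative numeric vector.
#' @param alpha,beta positive scaling parameters.
#' @return Numeric vector of the same length.
#' @export
powerNormalise <- function(S, alpha = 1, beta = 0.5) {
  if (alpha <= 0 || beta <= 0) .stopf("alpha and beta must be positive")
  if (any(S < 0)) .stopf("power normalisation requires nonnegative input")
  alpha * S^beta
}
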