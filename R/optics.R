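#' Effective reflection coefficient of a refractive boundary
#'
#' Empirical polynomial for the effective Fresnel reflection coefficient of
#' the air/sample boundary used by the diffusion-approximation reflectance
#' model: `Reff = 0.0636 n + 0.668 + 0.71 / n - 1.44 / n^2`.
#'
#' @param n Refractive index of the sample (>= 1). Vectorized.
#' @return Effective reflection coefficient (unitless).
#' @export
#' @examples
#' effective_reflection_coefficient(1.43)
effective_reflection_coefficient <- function(n) {
  if (any(!is.finite(n)) || any(n < 1)) {
    stop("refractive index must be finite and >= 1")
  }
  0.0636 * n + 0.668 + 0.71 / n - 1.44 / n^2
}

#' Proportionality constant of the diffusion boundary condition
#'
#' `A = (1 - Reff) / (2 (1 + Reff))`, the flux proportionality constant that
#' enters the spatially modulated diffuse reflectance model.
#'
#' @param r_eff Effective reflection coefficient in `[0, 1)`. Vectorized.
#' @return Proportionality constant A (unitless), in `(0, 0.5]`.
#' @export
proportionality_constant <- function(r_eff) {
  if (any(!is.finite(r_eff)) || any(r_eff < 0) || any(r_eff >= 1)) {
    stop("effective reflection coefficient must lie in [0, 1)")
  }
  (1 - r_eff) / (2 * (1 + r_eff))
}

#' Diffusion-approximation diffuse reflectance at a spatial frequency
#'
#' Forward model mapping the optical transport coefficients of a homogeneous
#' turbid medium and a projected spatial frequency to its diffuse
#' reflectance:
#' \deqn{R_d = \frac{3A\,\mu_s'/\mu_{tr}}
#'   {(\mu_{eff}'/\mu_{tr} + 1)(\mu_{eff}'/\mu_{tr} + 3A)}}
#' with \eqn{\mu_{tr} = \mu_a + \mu_s'} and, in the default `"squared"`
#' dialect, \eqn{\mu_{eff}' = (3\mu_a\mu_{tr} + K^2)^{1/2}}, `K = 2 pi fx`.
#' The `"printed"` dialect uses `K` un-squared inside the root; the two
#' agree identically at `fx = 0`.
#'
#' @param mu_a Absorption coefficient, mm^-1 (>= 0). Vectorized.
#' @param mu_s_prime Reduced scattering coefficient, mm^-1 (> 0). Vectorized.
#' @param fx Spatial frequency, mm^-1 (>= 0).
#' @param n Refractive index of the sample.
#' @param mueff_dialect `"squared"` or `"printed"` (see Details).
#' @return Diffuse reflectance Rd (unitless, in (0, 1] for physical inputs).
#' @export
#' @examples
#' diffuse_reflectance(0.0324, 1.726, fx = 0.2)
diffuse_reflectance <- function(mu_a, mu_s_prime, fx,
                                n = 1.43,
                                mueff_dialect = c("squared", "printed")) {
  mueff_dialect <- match.arg(mueff_dialect)
  if (any(!is.finite(mu_a)) || any(mu_a < 0)) {
    stop("mu_a must be finite and >= 0")
  }
  if (any(!is.finite(mu_s_prime)) || any(mu_s_prime <= 0)) {
    stop("mu_s_prime must be finite and > 0 (degenerate non-scattering medium)")
  }
  if (any(fx < 0)) stop("spatial frequency must be >= 0")
  a_const <- proportionality_constant(effective_reflection_coefficient(n))
  mu_tr <- mu_a + mu_s_prime
  k <- 2 * pi * fx
  k_term <- if (mueff_dialect == "squared") k^2 else k
  mu_eff <- sqrt(3 * mu_a * mu_tr + k_term)
  ratio <- mu_eff / mu_tr
  out <- 3 * a_const * (mu_s_prime / mu_tr) /
    ((ratio + 1) * (ratio + 3 * a_const))
  # preserve array shape of the widest input
  if (is.matrix(mu_a) || is.matrix(mu_s_prime)) {
    dims <- if (is.matrix(mu_a)) dim(mu_a) else dim(mu_s_prime)
    dim(out) <- dims
  }
  out
}
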