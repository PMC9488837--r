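#' Auxiliary scalars of the beta information matrix test
#'
#' Evaluates, at \eqn{\theta = (\mu, \phi)}, the scalar quantities that
#' appear throughout the test statistics and their analytic Jacobians:
#' \deqn{w = \psi'(\mu\phi) + \psi'((1-\mu)\phi), \quad
#'       c = \phi(\mu w - \psi'((1-\mu)\phi)), \quad
#'       m = \psi''(\mu\phi) - \psi''((1-\mu)\phi),}
#' the transformed-data means \eqn{\mu^*, \mu^\dagger}, and their partial
#' derivatives with respect to \eqn{\mu} and \eqn{\phi} (including
#' \eqn{\partial^2\mu^*/\partial\phi^2}).  Two identities hold exactly and
#' are useful as internal checks:
#' \eqn{\partial\mu^*/\partial\mu = \phi w} and
#' \eqn{\partial\mu^*/\partial\phi = c/\phi}.
#'
#' @param theta a [theta_mp()] object or numeric (mu, phi) pair.
#' @return A named list with components `mustar`, `mudag`, `w`, `c`, `m`,
#'   `dmustar_dmu`, `dmustar_dphi`, `d2mustar_dphi2`, `dmudag_dmu`,
#'   `dmudag_dphi`, `dw_dmu`, `dw_dphi`, `dc_dmu`, `dc_dphi`.
#' @examples
#' aux_quantities(theta_mp(0.5, 20))$m   # zero by symmetry at mu = 0.5
#' @export
aux_quantities <- function(theta) {
  th <- .as_theta(theta)
  mu <- th[["mu"]]; phi <- th[["phi"]]
  a <- mu * phi; b <- (1 - mu) * phi
  t1a <- trigamma(a); t1b <- trigamma(b)
  t2a <- psigamma(a, 2L); t2b <- psigamma(b, 2L)
  w <- t1a + t1b
  cc <- phi * (mu * w - t1b)
  m <- t2a - t2b
  dw_dphi <- mu * t2a + (1 - mu) * t2b
  d2mustar_dphi2 <- mu^2 * t2a - (1 - mu)^2 * t2b
  list(
    mustar = digamma(a) - digamma(b),
    mudag = digamma(b) - digamma(phi),
    w = w, c = cc, m = m,
    dmustar_dmu = phi * w,
    dmustar_dphi = cc / phi,
    d2mustar_dphi2 = d2mustar_dphi2,
    dmudag_dmu = -phi * t1b,
    dmudag_dphi = (1 - mu) * t1b - trigamma(phi),
    dw_dmu = phi * m,
    dw_dphi = dw_dphi,
    dc_dmu = phi * (w + phi * dw_dphi),
    dc_dphi = cc / phi + phi * d2mustar_dphi2
  )
}
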