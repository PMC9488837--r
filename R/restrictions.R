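#' Per-observation information-equality indicators
#'
#' Under a correctly specified model the expected Hessian and the negated
#' expected score outer product coincide (the information matrix
#' equality).  The indicator vector
#' \deqn{d(\theta; y_t) = \mathrm{vech}\left(
#'   \frac{\partial^2 \ell_t}{\partial\theta\partial\theta^\top} +
#'   \frac{\partial \ell_t}{\partial\theta}
#'   \frac{\partial \ell_t}{\partial\theta^\top}\right)}
#' stacks the three distinct entries of that (symmetric) discrepancy for a
#' single observation.  For the mean-precision beta model, writing
#' \eqn{z_t = y_t^* - \mu^*} and
#' \eqn{u_t = \mu z_t + (y_t^\dagger - \mu^\dagger)}:
#' \deqn{d_1 = \phi^2(z_t^2 - w), \quad
#'       d_2 = z_t - c + \phi z_t u_t, \quad
#'       d_3 = -\mu c/\phi - (1-\mu)\psi'((1-\mu)\phi) + \psi'(\phi) + u_t^2.}
#' Each has expectation zero at the true parameter value when the data are
#' beta distributed.
#'
#' @param y numeric vector of observations strictly inside (0, 1).
#' @param theta a [theta_mp()] object or numeric (mu, phi) pair.
#' @return An n x 3 matrix with columns `d1`, `d2`, `d3`.
#' @seealso [imt_restrictions()] for the sample average and its Jacobian.
#' @export
imt_dcontrib <- function(y, theta) {
  th <- .as_theta(theta); .check_unit_sample(y, min_n = 1L)
  mu <- th[["mu"]]; phi <- th[["phi"]]
  q <- aux_quantities(th)
  z <- qlogis(y) - q$mustar
  u <- mu * z + (log1p(-y) - q$mudag)
  cbind(d1 = phi^2 * (z^2 - q$w),
        d2 = z - q$c + phi * z * u,
        d3 = -mu * q$c / phi - (1 - mu) * trigamma((1 - mu) * phi) +
          trigamma(phi) + u^2)
}

#' Restriction vector, analytic Jacobian and building-block matrices
#'
#' Computes everything the information matrix test statistics need at a
#' given \eqn{\theta}: the per-observation indicators
#' ([imt_dcontrib()]), their sample average
#' \eqn{D_n(\theta) = n^{-1}\sum_t d(\theta; Y_t)}, the analytic Jacobian
#' \eqn{\nabla D_n = \partial D_n/\partial\theta^\top} (3 x 2), the
#' average Hessian \eqn{A_n}, the average score outer product \eqn{B_n},
#' the cross moment \eqn{L_n = -n^{-1}\sum_t d_t s_t^\top}, and the
#' per-observation scores.  With `q = 2` (the default) the third
#' restriction, which is numerically near-degenerate for the beta model,
#' is dropped: statistics then use the first two components of
#' \eqn{D_n} and the first two rows of \eqn{\nabla D_n} and \eqn{L_n}.
#'
#' @param y numeric vector of observations strictly inside (0, 1).
#' @param theta a [theta_mp()] object or numeric (mu, phi) pair.
#' @param q number of restrictions retained (1, 2 or 3), counted from the
#'   first component.
#' @return An object of class `"imt_restrictions"`: a list with elements
#'   `contribs` (n x 3), `Dn` (length-3), `gradDn` (3 x 2), `An`, `Bn`
#'   (2 x 2), `Ln` (3 x 2), `scores` (n x 2), `q`, `active` (indices of
#'   the retained components) and `n`.
#' @examples
#' y <- rbeta_mp(200, 0.3, 15)
#' rs <- imt_restrictions(y, beta_fit(y)$theta_hat)
#' rs$Dn
#' @export
imt_restrictions <- function(y, theta, q = 2L) {
  th <- .as_theta(theta); .check_unit_sample(y)
  if (!q %in% 1:3) stop("'q' must be 1, 2 or 3", call. = FALSE)
  mu <- th[["mu"]]; phi <- th[["phi"]]
  aq <- aux_quantities(th)
  n <- length(y)
  z <- qlogis(y) - aq$mustar
  u <- mu * z + (log1p(-y) - aq$mudag)
  t1b <- trigamma((1 - mu) * phi)
  t2b <- psigamma((1 - mu) * phi, 2L)

  d <- cbind(d1 = phi^2 * (z^2 - aq$w),
             d2 = z - aq$c + phi * z * u,
             d3 = -mu * aq$c / phi - (1 - mu) * t1b + trigamma(phi) + u^2)
  scores <- cbind(mu = phi * z, phi = u)

  # Analytic Jacobian of Dn: averages of the per-observation partials.
  zbar <- mean(z); ubar <- mean(u)
  zu_bar <- mean(z * u); z2_bar <- mean(z^2)
  # d z/d mu = -dmustar_dmu etc.; u = mu z + (ydag - mudag)
  du_dmu_t <- z - mu * aq$dmustar_dmu - aq$dmudag_dmu      # per-observation
  du_dphi <- -(mu * aq$dmustar_dphi + aq$dmudag_dphi)      # constant in t
  g11 <- phi^2 * (-aq$dw_dmu - 2 * zbar * aq$dmustar_dmu)
  g12 <- 2 * phi * (z2_bar - aq$w) +
    phi^2 * (-2 * zbar * aq$dmustar_dphi - aq$dw_dphi)
  g21 <- -aq$dmustar_dmu - aq$dc_dmu -
    phi * aq$dmustar_dmu * ubar + phi * mean(z * du_dmu_t)
  g22 <- -aq$dmustar_dphi - aq$dc_dphi + zu_bar -
    phi * aq$dmustar_dphi * ubar + phi * zbar * du_dphi
  g31 <- -aq$c / phi - (mu / phi) * aq$dc_dmu +
    (t1b + (1 - mu) * phi * t2b) + 2 * mean(u * du_dmu_t)
  g32 <- mu * aq$c / phi^2 - (mu / phi) * aq$dc_dphi -
    (1 - mu)^2 * t2b + psigamma(phi, 2L) + 2 * ubar * du_dphi
  gradDn <- matrix(c(g11, g12, g21, g22, g31, g32), nrow = 3L, byrow = TRUE,
                   dimnames = list(c("d1", "d2", "d3"), c("mu", "phi")))

  An <- matrix(c(-phi^2 * aq$w, zbar - aq$c,
                 zbar - aq$c,
                 -mu * aq$c / phi - (1 - mu) * t1b + trigamma(phi)),
               2L, 2L, dimnames = list(c("mu", "phi"), c("mu", "phi")))
  Bn <- crossprod(scores) / n
  Ln <- -crossprod(d, scores) / n

  structure(list(contribs = d,
                 Dn = colMeans(d),
                 gradDn = gradDn,
                 An = An, Bn = Bn, Ln = Ln,
                 scores = scores,
                 q = as.integer(q),
                 active = seq_len(q),
                 n = n),
            class = "imt_restrictions")
}

#' @export
print.imt_restrictions <- function(x, ...) {
  cat(sprintf("Information-equality restrictions (n = %d, q = %d active of 3)\n",
              x$n, x$q))
  cat("  Dn:", format(x$Dn, digits = 4), "\n")
  invisible(x)
}
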