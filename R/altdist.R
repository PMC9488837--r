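#' Kumaraswamy distribution, median-precision parametrization
#'
#' The two-shape Kumaraswamy law on (0, 1) reparametrized so that `omega`
#' is the distribution median and `phi` a precision-type shape: with
#' shape parameters \eqn{a = \phi} and
#' \eqn{b = \log(0.5)/\log(1 - \omega^\phi)} the cdf is
#' \eqn{F(y) = 1 - (1 - y^a)^b} and \eqn{F(\omega) = 0.5} exactly.
#' Draws are generated by cdf inversion.
#'
#' @param y,u evaluation points / probabilities.
#' @param n number of draws.
#' @param omega median, in (0, 1).
#' @param phi precision-type shape, positive.
#' @param log logical; return log density?
#' @return Numeric vector (density, cdf, quantiles or draws).
#' @examples
#' median(rkumaraswamy(1e4, 0.2, 7.5))   # close to 0.2
#' @export
rkumaraswamy <- function(n, omega, phi) {
  qkumaraswamy(runif(n), omega, phi)
}

#' @rdname rkumaraswamy
#' @export
dkumaraswamy <- function(y, omega, phi, log = FALSE) {
  .check_med_par(omega, phi)
  a <- phi; b <- log(0.5) / log1p(-omega^phi)
  ld <- ifelse(y > 0 & y < 1,
               log(a) + log(b) + (a - 1) * log(y) + (b - 1) * log1p(-y^a),
               -Inf)
  if (log) ld else exp(ld)
}

#' @rdname rkumaraswamy
#' @export
pkumaraswamy <- function(y, omega, phi) {
  .check_med_par(omega, phi)
  b <- log(0.5) / log1p(-omega^phi)
  pmin(pmax(1 - (1 - pmin(pmax(y, 0), 1)^phi)^b, 0), 1)
}

#' @rdname rkumaraswamy
#' @export
qkumaraswamy <- function(u, omega, phi) {
  .check_med_par(omega, phi)
  b <- log(0.5) / log1p(-omega^phi)
  (1 - (1 - u)^(1 / b))^(1 / phi)
}

.check_med_par <- function(omega, phi) {
  if (!is.numeric(omega) || omega <= 0 || omega >= 1)
    stop("'omega' (median) must lie strictly inside (0, 1)", call. = FALSE)
  if (!is.numeric(phi) || phi <= 0)
    stop("'phi' must be positive", call. = FALSE)
  invisible(NULL)
}

#' Unit Weibull distribution, median parametrization
#'
#' The unit Weibull law on (0, 1) indexed by its median `omega` and shape
#' `phi`, with cdf \eqn{F(y) = 0.5^{(\log y / \log\omega)^\phi}} for
#' \eqn{y \in (0, 1)}; this is the 0.5-quantile parametrization of the
#' log-transformed Weibull law.  Draws are generated by cdf inversion.
#'
#' @inheritParams rkumaraswamy
#' @return Numeric vector (density, cdf, quantiles or draws).
#' @examples
#' median(runitweibull(1e4, 0.75, 5))    # close to 0.75
#' @export
runitweibull <- function(n, omega, phi) {
  qunitweibull(runif(n), omega, phi)
}

#' @rdname runitweibull
#' @export
dunitweibull <- function(y, omega, phi, log = FALSE) {
  .check_med_par(omega, phi)
  lw <- log(omega)
  r <- log(y) / lw
  ld <- ifelse(y > 0 & y < 1,
               log(0.5) * r^phi + log(phi) + log(log(0.5) / lw) +
                 (phi - 1) * log(r) - log(y),
               -Inf)
  if (log) ld else exp(ld)
}

#' @rdname runitweibull
#' @export
punitweibull <- function(y, omega, phi) {
  .check_med_par(omega, phi)
  out <- ifelse(y <= 0, 0, ifelse(y >= 1, 1,
                                  0.5^((log(pmin(pmax(y, 1e-300), 1)) / log(omega))^phi)))
  out
}

#' @rdname runitweibull
#' @export
qunitweibull <- function(u, omega, phi) {
  .check_med_par(omega, phi)
  exp(log(omega) * (log(u) / log(0.5))^(1 / phi))
}

#' Simplex distribution
#'
#' The simplex law on (0, 1) with mean `mu` and dispersion `sigma`,
#' density
#' \deqn{f(y;\mu,\sigma^2) = \{2\pi\sigma^2 [y(1-y)]^3\}^{-1/2}
#'   \exp\{-d(y,\mu)/(2\sigma^2)\},}
#' \eqn{d(y,\mu) = (y-\mu)^2 / [y(1-y)\mu^2(1-\mu)^2]}.  The dispersion
#' argument follows the convention in which `sigma` enters the density
#' through its square, so `S(mu, sigma)` has density dispersion
#' `sigma^2`.  No closed-form sampler exists; `rsimplex` inverts a
#' quadrature-tabulated cdf on a logit-spaced grid, which reproduces the
#' analytic density to interpolation accuracy.
#'
#' @param y evaluation points in (0, 1).
#' @param n number of draws.
#' @param mu mean, in (0, 1).
#' @param sigma dispersion parameter, positive.
#' @param log logical; return log density?
#' @param grid_size number of grid nodes for the tabulated inverse cdf.
#' @return Numeric vector of densities or draws.
#' @examples
#' mean(rsimplex(1e4, 0.75, 2))          # close to 0.75
#' @export
dsimplex <- function(y, mu, sigma, log = FALSE) {
  .check_simplex_par(mu, sigma)
  s2 <- sigma^2
  dd <- (y - mu)^2 / (y * (1 - y) * mu^2 * (1 - mu)^2)
  ld <- -0.5 * log(2 * pi * s2) - 1.5 * log(y * (1 - y)) - dd / (2 * s2)
  if (log) ld else exp(ld)
}

#' @rdname dsimplex
#' @export
rsimplex <- function(n, mu, sigma, grid_size = 4096L) {
  .check_simplex_par(mu, sigma)
  grid <- plogis(seq(-36, 36, length.out = grid_size))
  f <- dsimplex(grid, mu, sigma)
  # trapezoid cdf over the uneven grid, normalized for inversion
  dy <- diff(grid)
  cdf <- c(0, cumsum((f[-1L] + f[-grid_size]) / 2 * dy))
  cdf <- cdf / cdf[grid_size]
  keep <- c(TRUE, diff(cdf) > 0)   # approx() needs strictly increasing x
  stats::approx(cdf[keep], grid[keep], xout = runif(n), rule = 2)$y
}

.check_simplex_par <- function(mu, sigma) {
  if (!is.numeric(mu) || mu <= 0 || mu >= 1)
    stop("'mu' must lie strictly inside (0, 1)", call. = FALSE)
  if (!is.numeric(sigma) || sigma <= 0)
    stop("'sigma' must be positive", call. = FALSE)
  invisible(NULL)
}

#' Beta draws with a logit mean regression
#'
#' Data-generating process with a neglected regression structure:
#' covariates \eqn{x_t} are drawn from the log-normal law
#' \eqn{LN(0, 0.5)}, each mean follows
#' \eqn{\log(\mu_t/(1-\mu_t)) = \beta_1 + \beta_2 x_t}, and the response
#' is beta with mean \eqn{\mu_t} and common precision `phi`.  Fitting the
#' constant-mean beta model to such data is a misspecification the
#' information matrix tests should detect.
#'
#' @param n number of draws.
#' @param beta1,beta2 intercept and slope on the logit scale.
#' @param phi common precision.
#' @param sdlog standard deviation of the log covariate.
#' @return Numeric vector of `n` responses in (0, 1); the covariates are
#'   attached as attribute `"x"`.
#' @export
rbeta_regression <- function(n, beta1 = -0.25, beta2 = 0.5, phi = 120,
                             sdlog = 0.5) {
  if (phi <= 0) stop("'phi' must be positive", call. = FALSE)
  x <- rlnorm(n, meanlog = 0, sdlog = sdlog)
  mu_t <- plogis(beta1 + beta2 * x)
  y <- rbeta(n, shape1 = mu_t * phi, shape2 = (1 - mu_t) * phi)
  attr(y, "x") <- x
  y
}

#' Zero-inflated beta draws and the boundary replacement rule
#'
#' `rbeta_inflated` draws from the mixture that puts probability `lam` on
#' the exact value 0 and otherwise draws from the beta law with mean `mu`
#' and precision `phi`.  `replace_inflated` applies the standard boundary
#' adjustment used before fitting a continuous unit-interval law:
#' \eqn{y \mapsto [y(n-1) + 0.5]/n} at the boundaries, i.e. zeros become
#' \eqn{0.5/n} and ones become \eqn{(n - 0.5)/n}; interior values are
#' untouched.
#'
#' @param n number of draws / sample size entering the replacement rule.
#' @param mu,phi beta mean and precision of the continuous component.
#' @param lam inflation probability \eqn{P(Y = 0)}, in [0, 1).
#' @param y numeric vector possibly containing exact zeros or ones.
#' @return `rbeta_inflated`: numeric vector in [0, 1).
#'   `replace_inflated`: numeric vector strictly inside (0, 1).
#' @examples
#' y <- rbeta_inflated(100, 0.5, 20, 0.025)
#' y2 <- replace_inflated(y, length(y))
#' all(y2 > 0 & y2 < 1)
#' @export
rbeta_inflated <- function(n, mu, phi, lam) {
  if (lam < 0 || lam >= 1) stop("'lam' must lie in [0, 1)", call. = FALSE)
  y <- rbeta_mp(n, mu, phi)
  zero <- rbinom(n, 1L, lam) == 1L
  y[zero] <- 0
  y
}

#' @rdname rbeta_inflated
#' @export
replace_inflated <- function(y, n = length(y)) {
  if (any(y < 0 | y > 1)) stop("'y' must lie in [0, 1]", call. = FALSE)
  y[y == 0] <- 0.5 / n
  y[y == 1] <- (n - 0.5) / n
  y
}

#' Specification of a data-generating process
#'
#' A light container pairing a family tag with its parameters, used by
#' the simulation harness.  `sample_dgp` dispatches to the corresponding
#' sampler.  Families and parameters: `beta` (`mu`, `phi`),
#' `kumaraswamy` / `unit_weibull` (`omega`, `phi`), `simplex`
#' (`mu`, `sigma`), `beta_regression` (`beta1`, `beta2`, `phi`,
#' optionally `sdlog`), `inflated_beta` (`mu`, `phi`, `lam`; draws are
#' boundary-replaced with [replace_inflated()] so the fitted sample is
#' strictly interior).
#'
#' @param family family tag (see Details).
#' @param ... named family-specific parameters.
#' @param spec a `dgp_spec` object.
#' @param n sample size.
#' @return `dgp_spec`: an object of class `"dgp_spec"`. `sample_dgp`: a
#'   numeric vector of `n` draws strictly inside (0, 1).
#' @examples
#' sp <- dgp_spec("kumaraswamy", omega = 0.2, phi = 7.5)
#' y <- sample_dgp(sp, 100)
#' @export
dgp_spec <- function(family = c("beta", "kumaraswamy", "unit_weibull",
                                "simplex", "beta_regression", "inflated_beta"),
                     ...) {
  family <- match.arg(family)
  params <- list(...)
  needed <- switch(family,
                   beta = c("mu", "phi"),
                   kumaraswamy = c("omega", "phi"),
                   unit_weibull = c("omega", "phi"),
                   simplex = c("mu", "sigma"),
                   beta_regression = c("beta1", "beta2", "phi"),
                   inflated_beta = c("mu", "phi", "lam"))
  missing <- setdiff(needed, names(params))
  if (length(missing))
    stop("missing parameters for family '", family, "': ",
         paste(missing, collapse = ", "), call. = FALSE)
  structure(list(family = family, params = params), class = "dgp_spec")
}

#' @rdname dgp_spec
#' @export
sample_dgp <- function(spec, n) {
  stopifnot(inherits(spec, "dgp_spec"))
  p <- spec$params
  switch(spec$family,
         beta = rbeta_mp(n, p$mu, p$phi),
         kumaraswamy = rkumaraswamy(n, p$omega, p$phi),
         unit_weibull = runitweibull(n, p$omega, p$phi),
         simplex = rsimplex(n, p$mu, p$sigma),
         beta_regression = as.numeric(rbeta_regression(
           n, p$beta1, p$beta2, p$phi,
           sdlog = if (is.null(p$sdlog)) 0.5 else p$sdlog)),
         inflated_beta = replace_inflated(
           rbeta_inflated(n, p$mu, p$phi, p$lam), n))
}

#' @export
print.dgp_spec <- function(x, ...) {
  cat(sprintf("DGP: %s(%s)\n", x$family,
              paste(sprintf("%s = %g", names(x$params),
                            unlist(x$params)), collapse = ", ")))
  invisible(x)
}
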