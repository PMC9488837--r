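#' Covariance estimators for the scaled restriction vector
#'
#' Three consistent estimators of the covariance of
#' \eqn{\sqrt{n}\,D_n(\hat\theta)} under correct specification, each
#' restricted to the `q` active components of the restriction set.
#'
#' `imt_vn1` is White's estimator: with
#' \eqn{r_t = d_t - \nabla D_n A_n^{-1} s_t} (scores \eqn{s_t}, average
#' Hessian \eqn{A_n}),
#' \eqn{V_{n1} = n^{-1}\sum_t r_t r_t^\top}.  It requires the analytic
#' Jacobian \eqn{\nabla D_n} (third-order log-likelihood derivatives).
#'
#' `imt_vn2` is the Chesher-Lancaster estimator, which avoids third-order
#' derivatives by exploiting \eqn{\nabla D = -E(d\, s^\top)} under the
#' null: with \eqn{r_t = d_t + L_n B_n^{-1} s_t},
#' \eqn{V_{n2} = n^{-1}\sum_t r_t r_t^\top}.
#'
#' `imt_boot_cov` is the parametric-bootstrap estimator of the *exact*
#' (finite-n) covariance: draw `B` samples of size n from the fitted beta
#' law, refit each, collect \eqn{D_n(\hat\theta^*_b; Y^*_b)}, and return
#' \deqn{\hat V_{n3,B} = \frac{n}{B-1}\sum_b (D^*_b - \bar D)(D^*_b - \bar D)^\top.}
#' A bootstrap refit that fails to converge is replaced by a fresh
#' resample (at most `10 * B` attempts in total), so the estimator is
#' always based on exactly `B` replicates.
#'
#' @param rs an [imt_restrictions()] object evaluated at the fit.
#' @param y numeric sample in (0, 1) (for `imt_boot_cov`).
#' @param theta_hat fitted [theta_mp()] parameters.
#' @param B number of bootstrap resamples (at least `q + 2`).
#' @param q number of active restrictions for the bootstrap estimator.
#' @param seed optional integer seed for reproducible resampling.
#' @param cond_limit condition numbers above this raise an error: a
#'   near-singular covariance means the retained restrictions are
#'   numerically degenerate and the quadratic form is meaningless.
#' @return An object of class `"imt_cov"`: list with `matrix` (q x q),
#'   `method` (`"vn1"`, `"vn2"` or `"bootstrap"`), `B` (bootstrap only),
#'   `condition`, and for the bootstrap `n_redraws` (failed refits that
#'   were redrawn).
#' @examples
#' y <- rbeta_mp(300, 0.4, 25)
#' fit <- beta_fit(y)
#' rs <- imt_restrictions(y, fit$theta_hat)
#' imt_vn1(rs)$matrix
#' imt_vn2(rs)$matrix
#' @export
imt_vn1 <- function(rs, cond_limit = 1e12) {
  stopifnot(inherits(rs, "imt_restrictions"))
  Ainv <- tryCatch(solve(rs$An), error = function(e)
    stop("average Hessian An is singular; cannot form Vn1", call. = FALSE))
  act <- rs$active
  M <- rs$gradDn[act, , drop = FALSE] %*% Ainv
  r <- rs$contribs[, act, drop = FALSE] - rs$scores %*% t(M)
  .new_imt_cov(crossprod(r) / rs$n, "vn1", cond_limit = cond_limit)
}

#' @rdname imt_vn1
#' @export
imt_vn2 <- function(rs, cond_limit = 1e12) {
  stopifnot(inherits(rs, "imt_restrictions"))
  Binv <- tryCatch(solve(rs$Bn), error = function(e)
    stop("score outer-product matrix Bn is singular; cannot form Vn2",
         call. = FALSE))
  act <- rs$active
  M <- rs$Ln[act, , drop = FALSE] %*% Binv
  r <- rs$contribs[, act, drop = FALSE] + rs$scores %*% t(M)
  .new_imt_cov(crossprod(r) / rs$n, "vn2", cond_limit = cond_limit)
}

#' @rdname imt_vn1
#' @export
imt_boot_cov <- function(y, theta_hat, B = 500L, q = 2L, seed = NULL,
                         cond_limit = 1e12) {
  .check_unit_sample(y)
  th <- .as_theta(theta_hat)
  if (B < q + 2L) stop("'B' must be at least q + 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- length(y)
  act <- seq_len(q)
  Dstar <- matrix(NA_real_, B, q)
  redraws <- 0L
  b <- 1L
  attempts <- 0L
  while (b <= B) {
    attempts <- attempts + 1L
    if (attempts > 10L * B)
      stop("too many failed bootstrap refits (", redraws, " redraws)",
           call. = FALSE)
    ystar <- rbeta_mp(n, th[["mu"]], th[["phi"]])
    fit <- tryCatch(beta_fit(ystar, se = FALSE), error = function(e) NULL)
    if (is.null(fit) || !fit$converged) { redraws <- redraws + 1L; next }
    Dstar[b, ] <- colMeans(imt_dcontrib(ystar, fit$theta_hat))[act]
    b <- b + 1L
  }
  Dc <- sweep(Dstar, 2L, colMeans(Dstar))
  V <- n / (B - 1) * crossprod(Dc)
  out <- .new_imt_cov(V, "bootstrap", B = B, cond_limit = cond_limit)
  out$n_redraws <- redraws
  out
}

.new_imt_cov <- function(V, method, B = NULL, cond_limit = 1e12) {
  V <- (V + t(V)) / 2
  kap <- kappa(V, exact = TRUE)
  if (!is.finite(kap) || kap > cond_limit)
    stop(sprintf(
      "near-singular covariance estimate (method %s, condition number %.3g); consider dropping restrictions (smaller q)",
      method, kap), call. = FALSE)
  structure(list(matrix = V, method = method, B = B, condition = kap),
            class = "imt_cov")
}

#' @export
print.imt_cov <- function(x, ...) {
  cat(sprintf("Restriction covariance estimate [%s%s], condition number %.3g\n",
              x$method, if (!is.null(x$B)) sprintf(", B = %d", x$B) else "",
              x$condition))
  print(x$matrix, digits = 4)
  invisible(x)
}

#' Information matrix quadratic form
#'
#' The test statistic core \eqn{n D_n^\top V^{-1} D_n} over the active
#' restriction components.
#'
#' @param rs an [imt_restrictions()] object.
#' @param cov an [imt_vn1()], [imt_vn2()] or [imt_boot_cov()] estimate.
#' @param n sample size (defaults to the one recorded in `rs`).
#' @return Nonnegative scalar.
#' @export
imt_statistic <- function(rs, cov, n = rs$n) {
  stopifnot(inherits(rs, "imt_restrictions"), inherits(cov, "imt_cov"))
  D <- rs$Dn[rs$active]
  if (length(D) != nrow(cov$matrix))
    stop("dimension mismatch between restrictions and covariance", call. = FALSE)
  drop(n * crossprod(D, solve(cov$matrix, D)))
}
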