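#' Information matrix misspecification tests for the beta model
#'
#' Tests the null hypothesis that an i.i.d. sample on (0, 1) follows the
#' beta law with constant mean and precision, by checking the information
#' matrix equality \eqn{A(\theta_0) + B(\theta_0) = 0} through the
#' restriction vector \eqn{D_n(\hat\theta)}.  Five variants are offered;
#' all use the quadratic form \eqn{\zeta = n D_n^\top V^{-1} D_n} over the
#' `q` active restrictions and differ in the covariance estimate \eqn{V}
#' and the reference distribution:
#'
#' * `"zeta1"` - White's covariance [imt_vn1()], asymptotic
#'   \eqn{\chi^2_q} critical values.
#' * `"zeta2"` - Chesher-Lancaster covariance [imt_vn2()], asymptotic
#'   \eqn{\chi^2_q} critical values.
#' * `"zeta3"` - parametric-bootstrap covariance [imt_boot_cov()] of the
#'   exact finite-n covariance; reference Hotelling
#'   \eqn{T^2_{q, B-1}}, evaluated through its scaled-F representation
#'   \eqn{\zeta_3 (B-q)/(q(B-1)) \sim F_{q, B-q}}.
#' * `"zeta1B"`, `"zeta2B"` - the zeta1 / zeta2 statistic compared against
#'   parametric-bootstrap critical values: each of `B` resamples from the
#'   fitted law is refitted and its own statistic (with the same
#'   covariance estimator, at the resample's own MLE) recomputed; the
#'   null is rejected at level \eqn{\alpha} when the observed statistic
#'   exceeds the empirical \eqn{1-\alpha} quantile of the replicates.
#'
#' The asymptotic variants are markedly liberal in small samples, so the
#' bootstrap variants are the recommended choice unless n is in the
#' thousands.
#'
#' @param y numeric vector of observations strictly inside (0, 1).
#' @param variant one of `"zeta1"`, `"zeta2"`, `"zeta3"`, `"zeta1B"`,
#'   `"zeta2B"`.
#' @param q number of information-equality restrictions tested (default 2:
#'   the third component is numerically near-degenerate for the beta
#'   model and dropping it avoids near-singular covariance estimates).
#' @param B bootstrap resamples (used by `zeta3`, `zeta1B`, `zeta2B`).
#' @param seed optional integer seed for the bootstrap.
#' @param fit optional pre-computed [beta_fit()] of `y` to reuse.
#' @return An object of class `"imt_test"`: list with `name`,
#'   `statistic`, `q`, `reference` (`"chisq_q"`, `"hotelling_q_Bminus1"`
#'   or `"bootstrap_empirical"`), `p_value`, `B`, `boot_stats` (bootstrap
#'   replicate statistics, `NULL` otherwise), `n_redraws`, `theta_hat`,
#'   `n`, `seed`.  For the bootstrap-critical-value variants `p_value` is
#'   the plus-one empirical p-value \eqn{(1 + \#\{\zeta^* \ge \zeta\})/(B+1)};
#'   the level-\eqn{\alpha} decision of [imt_reject()] uses the empirical
#'   quantile rule.
#' @examples
#' y <- rbeta_mp(100, 0.5, 20)
#' imtest(y, "zeta1")
#' imtest(y, "zeta1B", B = 99, seed = 1)
#' @export
imtest <- function(y, variant = c("zeta1", "zeta2", "zeta3", "zeta1B", "zeta2B"),
                   q = 2L, B = 500L, seed = NULL, fit = NULL) {
  variant <- match.arg(variant)
  .check_unit_sample(y)
  if (is.null(fit)) fit <- beta_fit(y, se = FALSE)
  if (!fit$converged)
    stop("maximum likelihood fit did not converge; cannot test", call. = FALSE)
  th <- fit$theta_hat
  rs <- imt_restrictions(y, th, q = q)
  n <- length(y)
  if (!is.null(seed)) set.seed(seed)

  out <- list(name = variant, q = as.integer(q), B = NULL, boot_stats = NULL,
              n_redraws = 0L, theta_hat = th, n = n, seed = seed)

  if (variant %in% c("zeta1", "zeta2")) {
    V <- if (variant == "zeta1") imt_vn1(rs) else imt_vn2(rs)
    out$statistic <- imt_statistic(rs, V)
    out$reference <- "chisq_q"
    out$p_value <- pchisq(out$statistic, df = q, lower.tail = FALSE)
  } else if (variant == "zeta3") {
    V <- imt_boot_cov(y, th, B = B, q = q)
    out$statistic <- imt_statistic(rs, V)
    out$reference <- "hotelling_q_Bminus1"
    out$B <- as.integer(B)
    out$n_redraws <- V$n_redraws
    out$p_value <- .hotelling_pvalue(out$statistic, q, B)
  } else {
    which_v <- if (variant == "zeta1B") "vn1" else "vn2"
    V <- if (which_v == "vn1") imt_vn1(rs) else imt_vn2(rs)
    out$statistic <- imt_statistic(rs, V)
    bs <- .boot_crit_stats(y, th, B = B, q = q,
                           vn1 = which_v == "vn1", vn2 = which_v == "vn2")
    stars <- if (which_v == "vn1") bs$zeta1 else bs$zeta2
    out$reference <- "bootstrap_empirical"
    out$B <- as.integer(B)
    out$boot_stats <- stars
    out$n_redraws <- bs$n_redraws
    out$p_value <- (1 + sum(stars >= out$statistic)) / (B + 1)
  }
  class(out) <- "imt_test"
  out
}

# Upper-tail p-value of Hotelling's T^2 with q and B-1 degrees of freedom
# through the exact scaled-F representation.
.hotelling_pvalue <- function(stat, q, B) {
  pf(stat * (B - q) / (q * (B - 1)), df1 = q, df2 = B - q, lower.tail = FALSE)
}

# Parametric-bootstrap replicate statistics for the critical-value
# procedure: B resamples from the fitted law, each refitted, each scored
# with its own covariance estimate (Vn1 and/or Vn2) at its own MLE.
# Failed refits (or singular covariance estimates) are redrawn, capped at
# 10 * B attempts, so exactly B replicates are returned.
.boot_crit_stats <- function(y, theta_hat, B, q = 2L, vn1 = TRUE, vn2 = TRUE) {
  th <- .as_theta(theta_hat)
  n <- length(y)
  z1 <- if (vn1) numeric(B) else NULL
  z2 <- if (vn2) numeric(B) else NULL
  redraws <- 0L; b <- 1L; attempts <- 0L
  while (b <= B) {
    attempts <- attempts + 1L
    if (attempts > 10L * B)
      stop("too many failed bootstrap refits (", redraws, " redraws)",
           call. = FALSE)
    ystar <- rbeta_mp(n, th[["mu"]], th[["phi"]])
    res <- tryCatch({
      fit <- beta_fit(ystar, se = FALSE)
      if (!fit$converged) stop("refit did not converge")
      rs <- imt_restrictions(ystar, fit$theta_hat, q = q)
      c(if (vn1) imt_statistic(rs, imt_vn1(rs)) else NA_real_,
        if (vn2) imt_statistic(rs, imt_vn2(rs)) else NA_real_)
    }, error = function(e) NULL)
    if (is.null(res)) { redraws <- redraws + 1L; next }
    if (vn1) z1[b] <- res[1L]
    if (vn2) z2[b] <- res[2L]
    b <- b + 1L
  }
  list(zeta1 = z1, zeta2 = z2, n_redraws = redraws)
}

#' Level-alpha decision for an information matrix test
#'
#' For the asymptotic and Hotelling variants this is `p_value < alpha`.
#' For the bootstrap-critical-value variants the decision follows the
#' empirical quantile rule: reject when the observed statistic exceeds
#' the \eqn{\lceil (1-\alpha) B \rceil}-th order statistic of the `B`
#' bootstrap replicates (equivalent to comparing the empirical bootstrap
#' p-value with \eqn{\alpha}).
#'
#' @param x an [imtest()] result.
#' @param alpha significance level in (0, 1).
#' @return Logical: reject the null of correct beta specification?
#' @export
imt_reject <- function(x, alpha = 0.05) {
  stopifnot(inherits(x, "imt_test"), alpha > 0, alpha < 1)
  if (x$reference == "bootstrap_empirical") {
    crit <- sort(x$boot_stats)[ceiling((1 - alpha) * x$B)]
    x$statistic > crit
  } else {
    x$p_value < alpha
  }
}

#' @export
print.imt_test <- function(x, ...) {
  ref <- switch(x$reference,
                chisq_q = sprintf("chi-squared, %d df", x$q),
                hotelling_q_Bminus1 = sprintf("Hotelling T^2(%d, %d)", x$q, x$B - 1L),
                bootstrap_empirical = sprintf("parametric bootstrap, B = %d", x$B))
  cat(sprintf("Information matrix test (%s) for beta specification\n", x$name))
  cat(sprintf("  statistic = %.4f, q = %d, reference: %s\n", x$statistic, x$q, ref))
  cat(sprintf("  p-value = %.4f\n", x$p_value))
  if (x$n_redraws > 0L)
    cat(sprintf("  (%d failed bootstrap refits were redrawn)\n", x$n_redraws))
  invisible(x)
}

#' Flatten a test result to a one-row data frame
#'
#' @param x an [imtest()] result.
#' @param ... unused.
#' @return A one-row data frame with columns `name`, `statistic`, `q`,
#'   `B`, `p_value`, `n`, `seed`.
#' @export
as.data.frame.imt_test <- function(x, ...) {
  data.frame(name = x$name, statistic = x$statistic, q = x$q,
             B = if (is.null(x$B)) NA_integer_ else x$B,
             p_value = x$p_value, n = x$n,
             seed = if (is.null(x$seed)) NA_integer_ else x$seed)
}
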