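#' Configuration of a Monte Carlo size or power experiment
#'
#' Bundles everything one cell block of the simulation study needs: the
#' data-generating process, the sample-size and significance-level grids,
#' the replication counts and the master seed.  Per-replication seeds are
#' derived from the master seed up front (a counter scheme), so results
#' do not depend on execution order.
#'
#' @param dgp a [dgp_spec()]; the beta family for size experiments, any
#'   other family (or beta with regression / inflation) for power.
#' @param n_grid integer vector of sample sizes.
#' @param alpha_grid significance levels in (0, 1).
#' @param reps Monte Carlo replications per cell (at least 100 for any
#'   reported rate).
#' @param boot_B bootstrap replications for the bootstrap-based tests.
#' @param tests subset of `c("zeta1", "zeta1B", "zeta2", "zeta2B",
#'   "zeta3")`.
#' @param seed master integer seed.
#' @param mode `"size"` or `"power"`.
#' @param q number of restrictions tested.
#' @return An object of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(dgp_spec("beta", mu = 0.2, phi = 40), n_grid = 50,
#'                   reps = 200, tests = c("zeta1", "zeta2"), seed = 1)
#' @export
sim_config <- function(dgp, n_grid, alpha_grid = c(0.10, 0.05, 0.01),
                       reps = 5000L, boot_B = 500L,
                       tests = c("zeta1", "zeta1B", "zeta2", "zeta2B", "zeta3"),
                       seed = 1L, mode = c("size", "power"), q = 2L) {
  mode <- match.arg(mode)
  stopifnot(inherits(dgp, "dgp_spec"))
  tests <- match.arg(tests, c("zeta1", "zeta1B", "zeta2", "zeta2B", "zeta3"),
                     several.ok = TRUE)
  if (reps < 100L) stop("'reps' must be at least 100", call. = FALSE)
  if (any(alpha_grid <= 0 | alpha_grid >= 1))
    stop("'alpha_grid' values must lie in (0, 1)", call. = FALSE)
  if (mode == "size" && dgp$family != "beta")
    stop("size experiments require a beta data-generating process",
         call. = FALSE)
  structure(list(dgp = dgp, n_grid = as.integer(n_grid),
                 alpha_grid = alpha_grid, reps = as.integer(reps),
                 boot_B = as.integer(boot_B), tests = tests,
                 seed = as.integer(seed), mode = mode, q = as.integer(q)),
            class = "sim_config")
}

# Per-replication seeds: drawn once from the master seed so replications
# are independent of scheduling. Kept below 2^31.
.rep_seeds <- function(master, reps, n_cells) {
  set.seed(master)
  matrix(sample.int(2147483646L, reps * n_cells), nrow = reps)
}

# One Monte Carlo replication: generate, fit, compute the requested
# statistics / p-values / bootstrap critical values. Returns NULL on a
# failed replication (non-convergent fit or singular covariance).
.mc_rep <- function(config, n, rep_seed) {
  set.seed(rep_seed)
  y <- sample_dgp(config$dgp, n)
  sub_seeds <- sample.int(2147483646L, 2L)  # separate bootstrap streams
  tests <- config$tests
  q <- config$q
  out <- tryCatch({
    fit <- beta_fit(y, se = FALSE)
    if (!fit$converged) stop("no convergence")
    rs <- imt_restrictions(y, fit$theta_hat, q = q)
    res <- list()
    need1 <- any(c("zeta1", "zeta1B") %in% tests)
    need2 <- any(c("zeta2", "zeta2B") %in% tests)
    if (need1) res$zeta1 <- imt_statistic(rs, imt_vn1(rs))
    if (need2) res$zeta2 <- imt_statistic(rs, imt_vn2(rs))
    if (any(c("zeta1B", "zeta2B") %in% tests)) {
      set.seed(sub_seeds[1L])
      bs <- .boot_crit_stats(y, fit$theta_hat, B = config$boot_B, q = q,
                             vn1 = "zeta1B" %in% tests,
                             vn2 = "zeta2B" %in% tests)
      if ("zeta1B" %in% tests) res$boot1 <- sort(bs$zeta1)
      if ("zeta2B" %in% tests) res$boot2 <- sort(bs$zeta2)
    }
    if ("zeta3" %in% tests) {
      set.seed(sub_seeds[2L])
      V3 <- imt_boot_cov(y, fit$theta_hat, B = config$boot_B, q = q)
      res$zeta3 <- imt_statistic(rs, V3)
      res$p3 <- .hotelling_pvalue(res$zeta3, q, config$boot_B)
    }
    res
  }, error = function(e) NULL)
  out
}

#' Run a size (null rejection rate) experiment
#'
#' For each sample size in the configuration, draws `reps` beta samples,
#' fits the beta model and applies the requested tests at every level of
#' the alpha grid.  Asymptotic variants are compared with chi-squared
#' critical values, `zeta3` with its Hotelling reference, and the
#' bootstrap-critical-value variants with the empirical
#' \eqn{1-\alpha} quantile of their own bootstrap replicates.  Failed
#' replications (non-convergent fits, singular covariance estimates) are
#' counted and excluded; rates are computed over the completed ones.  The
#' per-replication statistics (and p-values where a continuous reference
#' exists) are archived for critical-value extraction and curve
#' construction.
#'
#' @param config a [sim_config()].
#' @return An object of class `"imt_sim"`: list with `rates` (data frame
#'   with columns `test`, `n`, `alpha`, `dgp`, `rate`, `mc_se`, `reps`),
#'   `stats` (per-n matrix of archived statistics), `pvalues` (per-n
#'   matrix for tests with a continuous reference), `failures` (per-n
#'   failed replication count) and `config`.
#' @examples
#' \donttest{
#' cfg <- sim_config(dgp_spec("beta", mu = 0.2, phi = 40), n_grid = 100,
#'                   reps = 200, tests = c("zeta1", "zeta2"), seed = 7)
#' sz <- run_size(cfg)
#' subset(sz$rates, alpha == 0.10)
#' }
#' @export
run_size <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$mode != "size") stop("configuration is not in size mode", call. = FALSE)
  .run_mc(config, crit = NULL)
}

#' Run a power (non-null rejection rate) experiment
#'
#' Identical mechanics to [run_size()] but the data come from the
#' configured (non-beta) alternative.  The asymptotic `zeta1` / `zeta2`
#' statistics are compared against *empirical* critical values from a
#' matching null experiment (size-adjusted power), supplied through
#' `critical_values`; the bootstrap-based variants carry their own
#' reference and need no adjustment.  If `critical_values` is missing
#' and `zeta1` or `zeta2` are requested, a null archive is simulated at
#' the pseudo-true beta parameters, obtained by fitting the beta law to
#' one large sample from the alternative (see
#' [pseudo_true_beta()]).
#'
#' @param config a [sim_config()] in power mode.
#' @param critical_values optional data frame from
#'   [empirical_critical_values()] with columns `test`, `n`, `alpha`,
#'   `crit`.
#' @return An `"imt_sim"` object (see [run_size()]).
#' @export
run_power <- function(config, critical_values = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$mode != "power") stop("configuration is not in power mode", call. = FALSE)
  asym <- intersect(c("zeta1", "zeta2"), config$tests)
  if (length(asym) && is.null(critical_values)) {
    th0 <- pseudo_true_beta(config$dgp, seed = config$seed + 1L)
    null_cfg <- sim_config(dgp_spec("beta", mu = th0[["mu"]], phi = th0[["phi"]]),
                           n_grid = config$n_grid,
                           alpha_grid = config$alpha_grid,
                           reps = config$reps, boot_B = config$boot_B,
                           tests = asym, seed = config$seed + 2L,
                           mode = "size", q = config$q)
    critical_values <- empirical_critical_values(run_size(null_cfg),
                                                 config$alpha_grid)
  }
  .run_mc(config, crit = critical_values)
}

.run_mc <- function(config, crit = NULL) {
  tests <- config$tests
  alphas <- config$alpha_grid
  n_grid <- config$n_grid
  seeds <- .rep_seeds(config$seed, config$reps, length(n_grid))
  dgp_label <- config$dgp$family
  arch_tests <- intersect(c("zeta1", "zeta2", "zeta3"), tests)
  rows <- list(); stats <- list(); pvals <- list(); failures <- integer(0)

  for (j in seq_along(n_grid)) {
    n <- n_grid[j]
    stat_mat <- matrix(NA_real_, config$reps, length(arch_tests),
                       dimnames = list(NULL, arch_tests))
    p_mat <- stat_mat
    rej <- array(0L, dim = c(length(tests), length(alphas)),
                 dimnames = list(tests, NULL))
    done <- 0L
    for (r in seq_len(config$reps)) {
      res <- .mc_rep(config, n, seeds[r, j])
      if (is.null(res)) next
      done <- done + 1L
      for (tt in tests) {
        reject <- switch(tt,
          zeta1 = res$zeta1 > qchisq(1 - alphas, df = config$q),
          zeta2 = res$zeta2 > qchisq(1 - alphas, df = config$q),
          zeta3 = res$p3 < alphas,
          zeta1B = res$zeta1 > res$boot1[ceiling((1 - alphas) * config$boot_B)],
          zeta2B = res$zeta2 > res$boot2[ceiling((1 - alphas) * config$boot_B)])
        if (tt %in% c("zeta1", "zeta2") && !is.null(crit)) {
          cr <- crit[crit$test == tt & crit$n == n, ]
          cr <- cr[match(alphas, cr$alpha), "crit"]
          if (anyNA(cr))
            stop("missing empirical critical values for ", tt, " at n = ", n,
                 call. = FALSE)
          reject <- res[[tt]] > cr
        }
        rej[tt, ] <- rej[tt, ] + reject
      }
      if ("zeta1" %in% arch_tests) stat_mat[r, "zeta1"] <- res$zeta1
      if ("zeta2" %in% arch_tests) stat_mat[r, "zeta2"] <- res$zeta2
      if ("zeta3" %in% arch_tests) stat_mat[r, "zeta3"] <- res$zeta3
      if ("zeta1" %in% arch_tests)
        p_mat[r, "zeta1"] <- pchisq(res$zeta1, config$q, lower.tail = FALSE)
      if ("zeta2" %in% arch_tests)
        p_mat[r, "zeta2"] <- pchisq(res$zeta2, config$q, lower.tail = FALSE)
      if ("zeta3" %in% arch_tests) p_mat[r, "zeta3"] <- res$p3
    }
    rate <- rej / done
    for (tt in tests) for (k in seq_along(alphas)) {
      rows[[length(rows) + 1L]] <- data.frame(
        test = tt, n = n, alpha = alphas[k], dgp = dgp_label,
        rate = rate[tt, k],
        mc_se = sqrt(rate[tt, k] * (1 - rate[tt, k]) / done),
        reps = done)
    }
    stats[[as.character(n)]] <- stat_mat
    pvals[[as.character(n)]] <- p_mat
    failures[as.character(n)] <- config$reps - done
  }
  structure(list(rates = do.call(rbind, rows), stats = stats,
                 pvalues = pvals, failures = failures, config = config),
            class = "imt_sim")
}

#' @export
print.imt_sim <- function(x, ...) {
  cat(sprintf("Monte Carlo %s experiment: %s, reps = %d, B = %d\n",
              x$config$mode, format(x$config$dgp$family), x$config$reps,
              x$config$boot_B))
  print(x$rates, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Pseudo-true beta parameters of an alternative law
#'
#' The probability limit of the beta MLE when the data actually follow
#' the given alternative: approximated by fitting the beta model to one
#' large simulated sample.
#'
#' @param dgp a [dgp_spec()].
#' @param n_big size of the approximating sample.
#' @param seed integer seed.
#' @return A [theta_mp()] object.
#' @export
pseudo_true_beta <- function(dgp, n_big = 1e6, seed = 1L) {
  set.seed(seed)
  y <- sample_dgp(dgp, n_big)
  beta_fit(y, se = FALSE)$theta_hat
}

#' Empirical critical values from an archived null experiment
#'
#' Extracts, for each archived test and sample size, the empirical
#' \eqn{1-\alpha} quantile of the null statistics, computed as the
#' \eqn{\lceil (1-\alpha) R \rceil}-th order statistic.
#'
#' @param sim an [run_size()] result.
#' @param alpha_grid significance levels.
#' @param tests which archived tests to extract (default: all archived).
#' @return Data frame with columns `test`, `n`, `alpha`, `crit`.
#' @export
empirical_critical_values <- function(sim, alpha_grid = c(0.10, 0.05, 0.01),
                                      tests = NULL) {
  stopifnot(inherits(sim, "imt_sim"))
  rows <- list()
  for (nm in names(sim$stats)) {
    mat <- sim$stats[[nm]]
    use <- if (is.null(tests)) colnames(mat) else intersect(tests, colnames(mat))
    for (tt in use) {
      s <- sort(mat[, tt])   # drops NA (failed reps)
      if (!length(s)) stop("empty statistic archive for ", tt, call. = FALSE)
      idx <- ceiling((1 - alpha_grid) * length(s))
      if (any(idx < 1L))
        stop("archive too small for the requested significance levels",
             call. = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        test = tt, n = as.integer(nm), alpha = alpha_grid, crit = s[idx])
    }
  }
  do.call(rbind, rows)
}

#' P-value and size-power curve data
#'
#' Builds plot-ready series from archived experiments.  The p-value plot
#' relates each test's empirical size (share of null p-values below
#' \eqn{\alpha}) to the nominal size over a dense \eqn{\alpha} grid; a
#' well-calibrated test tracks the 45-degree line.  The size-power plot
#' evaluates, for each \eqn{\alpha}, the empirical power at the
#' *empirical* critical value extracted from the matching null archive,
#' so the comparison between tests is freed from their size distortions.
#'
#' @param size_sim a [run_size()] result.
#' @param power_sim optional [run_power()] result over the same
#'   `n_grid`, tests and replication counts.
#' @param alpha_grid dense grid of nominal sizes in (0, 1).
#' @return An object of class `"imt_curves"`: list with `pvalue_plot`
#'   (data frame `test`, `n`, `alpha`, `empirical_size`) and, when a
#'   power archive is given, `size_power_plot` (data frame `test`, `n`,
#'   `alpha`, `power`).
#' @export
curve_data <- function(size_sim, power_sim = NULL,
                       alpha_grid = seq(0.01, 0.99, by = 0.01)) {
  stopifnot(inherits(size_sim, "imt_sim"))
  pv_rows <- list(); sp_rows <- list()
  for (nm in names(size_sim$pvalues)) {
    pmat <- size_sim$pvalues[[nm]]
    for (tt in colnames(pmat)) {
      p <- pmat[, tt]; p <- p[!is.na(p)]
      pv_rows[[length(pv_rows) + 1L]] <- data.frame(
        test = tt, n = as.integer(nm), alpha = alpha_grid,
        empirical_size = vapply(alpha_grid, function(a) mean(p < a), 0))
    }
  }
  if (!is.null(power_sim)) {
    stopifnot(inherits(power_sim, "imt_sim"))
    if (!identical(names(size_sim$stats), names(power_sim$stats)))
      stop("size and power archives cover different sample sizes", call. = FALSE)
    for (nm in names(size_sim$stats)) {
      s0 <- size_sim$stats[[nm]]; s1 <- power_sim$stats[[nm]]
      common <- intersect(colnames(s0), colnames(s1))
      for (tt in common) {
        null_stats <- sort(s0[, tt])
        alt_stats <- s1[, tt]; alt_stats <- alt_stats[!is.na(alt_stats)]
        idx <- ceiling((1 - alpha_grid) * length(null_stats))
        crit <- null_stats[pmax(idx, 1L)]
        sp_rows[[length(sp_rows) + 1L]] <- data.frame(
          test = tt, n = as.integer(nm), alpha = alpha_grid,
          power = vapply(crit, function(cv) mean(alt_stats > cv), 0))
      }
    }
  }
  structure(list(pvalue_plot = do.call(rbind, pv_rows),
                 size_power_plot = if (length(sp_rows)) do.call(rbind, sp_rows)),
            class = "imt_curves")
}
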