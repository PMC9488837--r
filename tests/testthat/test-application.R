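write_rates_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  path
}

test_that("read_rates validates, rescales and applies the boundary rule", {
  set.seed(501)
  y <- rbeta_mp(50, 0.1, 30)
  p <- write_rates_csv(data.frame(rate = y))
  d <- read_rates(p)
  expect_s3_class(d, "rate_dataset")
  expect_equal(d$n, 50)
  expect_equal(d$values, y)
  # per-hundred rescaling
  p2 <- write_rates_csv(data.frame(rate = c(20.01, 9.03)))
  d2 <- read_rates(p2, per_hundred = TRUE)
  expect_equal(d2$values, c(0.2001, 0.0903))
  # boundary rejection and replacement
  p3 <- write_rates_csv(data.frame(rate = c(0, 0.5, 0.2)))
  expect_error(read_rates(p3), "boundary")
  d3 <- read_rates(p3, replace_boundary = TRUE)
  expect_equal(d3$values, c(0.5 / 3, 0.5, 0.2))
  expect_equal(d3$n_replaced, 1L)
  # cluster column
  p4 <- write_rates_csv(data.frame(rate = y, region = rep(c("a", "b"), 25)))
  d4 <- read_rates(p4, cluster_col = "region")
  expect_equal(nlevels(d4$cluster), 2)
  expect_error(read_rates(p4, rate_col = "nope"), "no column")
  p5 <- write_rates_csv(data.frame(rate = numeric(0)))
  expect_error(read_rates(p5), "empty")
})

test_that("clustered sandwich: singleton clusters reduce to the robust sandwich", {
  set.seed(502)
  y <- rbeta_mp(120, 0.3, 25)
  th <- beta_fit(y, se = FALSE)$theta_hat
  V_singleton <- clustered_vcov(y, th, cluster = seq_along(y))
  # naive-loop transcription of the per-observation sandwich
  sc <- beta_score(y, th)
  meat <- matrix(0, 2, 2)
  for (t in seq_len(length(y))) meat <- meat + tcrossprod(sc[t, ])
  H <- matrix(0, 2, 2)
  hs <- c(1e-5, 1e-4 * th[["phi"]])   # parameter-scaled steps
  for (i in 1:2) for (j in 1:2) {
    e1 <- numeric(2); e1[i] <- hs[i]; e2 <- numeric(2); e2[j] <- hs[j]
    th_v <- c(th[["mu"]], th[["phi"]])
    H[i, j] <- (beta_loglik(y, th_v + e1 + e2) - beta_loglik(y, th_v + e1 - e2) -
                  beta_loglik(y, th_v - e1 + e2) + beta_loglik(y, th_v - e1 - e2)) /
      (4 * hs[i] * hs[j])
  }
  V_naive <- solve(H) %*% meat %*% solve(H)
  expect_equal(unname(V_singleton), V_naive, tolerance = 1e-4)
  expect_equal(V_singleton, t(V_singleton))
  expect_true(all(eigen(V_singleton, symmetric = TRUE)$values > 0))
})

test_that("clustered sandwich scales as the algebra dictates under duplication", {
  set.seed(503)
  y <- rbeta_mp(40, 0.4, 15)
  cl <- rep(1:8, each = 5)
  th <- beta_fit(y, se = FALSE)$theta_hat
  V1 <- clustered_vcov(y, th, cl)
  # duplicating every observation within its cluster doubles scores and
  # Hessian: meat x4, bread x(1/2) each side -> covariance unchanged... no:
  # A^-1 (4 meat) A^-1 with A doubled gives V1 / 1 = 4/(2*2) V1 = V1
  V2 <- clustered_vcov(c(y, y), th, c(cl, cl))
  expect_equal(V2, V1, tolerance = 1e-10)
  # G/(G-1) correction is a pure scalar factor
  V3 <- clustered_vcov(y, th, cl, df_correction = TRUE)
  expect_equal(V3, V1 * 8 / 7)
  expect_error(clustered_vcov(y, th, rep(1, 40)), "two clusters")
})

test_that("information criteria formulas and orderings", {
  ic <- info_criteria(0, 2, 100)
  expect_equal(unname(ic["AIC"]), 4)
  expect_equal(unname(ic["BIC"]), 2 * log(100))
  expect_equal(unname(ic["AICc"]), 4 + 2 * 2 * 3 / 97)
  expect_equal(unname(ic["HQIC"]), 4 * log(log(100)))
  expect_gt(ic["AICc"], ic["AIC"])
  # equal k: every criterion orders by log-likelihood
  ic1 <- info_criteria(-10, 2, 60); ic2 <- info_criteria(-12, 2, 60)
  expect_true(all(ic1 < ic2))
  expect_equal(unname(ic2 - ic1), rep(4, 4))
  expect_error(info_criteria(0, 2, 3), "AICc")
})

test_that("alternative-law fits recover their own parameters", {
  set.seed(504)
  y <- rkumaraswamy(4000, 0.5, 15)
  f <- fit_alternative(y, "kumaraswamy")
  expect_true(f$converged)
  expect_equal(unname(f$par[["omega"]]), 0.5, tolerance = 0.05)
  expect_equal(unname(f$par[["phi"]]), 15, tolerance = 0.10 * 15)
  yu <- runitweibull(4000, 0.25, 4)
  fu <- fit_alternative(yu, "unit_weibull")
  expect_equal(unname(fu$par[["omega"]]), 0.25, tolerance = 0.05)
  ys <- rsimplex(4000, 0.75, 2)
  fs <- fit_alternative(ys, "simplex")
  expect_equal(unname(fs$par[["mu"]]), 0.75, tolerance = 0.05)
  expect_equal(unname(fs$par[["sigma"]]), 2, tolerance = 0.2 * 2)
})

test_that("beta log-likelihood dominates the alternatives on beta data", {
  set.seed(505)
  wins <- vapply(1:40, function(k) {
    y <- rbeta_mp(800, 0.3, 25)
    lb <- beta_fit(y, se = FALSE)$loglik
    c(kw = lb >= fit_alternative(y, "kumaraswamy")$loglik,
      uw = lb >= fit_alternative(y, "unit_weibull")$loglik,
      sx = lb >= fit_alternative(y, "simplex")$loglik)
  }, logical(3))
  # Kumaraswamy and unit Weibull are essentially always beaten; the
  # simplex is flexible enough to out-fit the beta in a minority of runs
  expect_gte(mean(wins["kw", ]), 0.95)
  expect_gte(mean(wins["uw", ]), 0.95)
  expect_gte(mean(wins["sx", ]), 0.70)
})

test_that("analyze_rates assembles a coherent report that round-trips", {
  d <- synthetic_state_rates("period1", seed = 7)
  rep <- analyze_rates(d, B = 99, seed = 11)
  expect_s3_class(rep, "beta_rates_analysis")
  # small n: asymptotic variants skipped, bootstrap ones present
  expect_setequal(names(rep$tests), c("zeta1B", "zeta2B", "zeta3"))
  expect_true(rep$skipped_asymptotic)
  # clustered SEs used since the fixture carries regions
  expect_equal(rep$fit$se_method, "clustered")
  # criteria table: all families on the same sample, equal k, so AIC
  # differences are -2x log-likelihood differences
  expect_setequal(rep$criteria$family,
                  c("beta", "kumaraswamy", "unit_weibull", "simplex"))
  dl <- rep$criteria$loglik - rep$criteria$loglik[1]
  expect_equal(rep$criteria$AIC - rep$criteria$AIC[1], -2 * dl)
  # density grid covers all fitted families and is finite
  expect_true(all(is.finite(as.matrix(rep$density_grid))))
  # serialization round-trip
  out <- write_analysis(rep, tempfile("report"))
  js <- jsonlite::read_json(out[["json"]])
  expect_equal(js$mu_hat, unname(rep$fit$theta_hat[["mu"]]))
  expect_equal(js$tests$zeta3$p_value, rep$tests$zeta3$p_value)
  back <- read.csv(out[["criteria"]])
  expect_equal(back$AIC, rep$criteria$AIC)
  # determinism under the same seed
  rep2 <- analyze_rates(d, B = 99, seed = 11)
  expect_equal(rep2$tests$zeta1B$p_value, rep$tests$zeta1B$p_value)
})

test_that("well-specified fixture rarely rejects; two-regime mixture rejects often", {
  seeds <- 1:60
  p1 <- vapply(seeds, function(s) {
    d <- synthetic_state_rates("period1", seed = s)
    tt <- imtest(d$values, "zeta3", B = 99, seed = s + 1000)
    tt$p_value
  }, 0)
  expect_gte(mean(p1 > 0.05), 0.85)
  # the pooled two-regime sample trips the bootstrap tests well above the
  # 5% level; zeta1B is the sensitive variant at this sample size (zeta3
  # has little power against near-symmetric overdispersion in small n)
  rej2 <- vapply(seeds, function(s) {
    d <- synthetic_state_rates("period2", n = 100, seed = s)
    tt <- imtest(d$values, "zeta1B", B = 99, seed = s + 2000)
    tt$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej2), 0.10)
  rej3 <- vapply(seeds[1:30], function(s) {
    d <- synthetic_state_rates("period2", n = 500, seed = s)
    tt <- imtest(d$values, "zeta3", B = 99, seed = s + 3000)
    tt$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej3), 0.10)
})

test_that("bootstrap p-values are close to uniform on a well-specified fixture", {
  pvals <- vapply(1:200, function(s) {
    set.seed(s)
    y <- rbeta_mp(50, 0.09, 40)
    imtest(y, "zeta1B", B = 49, seed = s + 5000)$p_value
  }, 0)
  ks_dist <- max(abs(sort(pvals) - seq_along(pvals) / length(pvals)))
  expect_lt(ks_dist, 0.1)
})
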