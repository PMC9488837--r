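test_that("auxiliary scalars satisfy their printed identities and match finite differences", {
  # symmetry at mu = 0.5 kills the tetragamma difference
  expect_equal(aux_quantities(c(0.5, 17))$m, 0)
  ths <- random_thetas(8, seed = 201)
  for (i in seq_len(nrow(ths))) {
    mu <- ths$mu[i]; phi <- ths$phi[i]
    aq <- aux_quantities(c(mu, phi))
    # exact internal identities
    expect_equal(aq$dmustar_dmu, phi * aq$w)
    expect_equal(aq$dmustar_dphi * phi, aq$c)
    # every partial against a central finite difference of its parent
    fd <- function(f, wrt) {
      h <- 1e-6 * max(1, if (wrt == "mu") 1 else phi)
      if (wrt == "mu")
        (f(mu + h, phi) - f(mu - h, phi)) / (2 * h)
      else
        (f(mu, phi + h) - f(mu, phi - h)) / (2 * h)
    }
    g_mustar <- function(m, p) aux_quantities(c(m, p))$mustar
    g_mudag <- function(m, p) aux_quantities(c(m, p))$mudag
    g_w <- function(m, p) aux_quantities(c(m, p))$w
    g_c <- function(m, p) aux_quantities(c(m, p))$c
    g_dms_dphi <- function(m, p) aux_quantities(c(m, p))$dmustar_dphi
    expect_equal(aq$dmustar_dmu, fd(g_mustar, "mu"), tolerance = 1e-6)
    expect_equal(aq$dmustar_dphi, fd(g_mustar, "phi"), tolerance = 1e-6)
    expect_equal(aq$dmudag_dmu, fd(g_mudag, "mu"), tolerance = 1e-6)
    expect_equal(aq$dmudag_dphi, fd(g_mudag, "phi"), tolerance = 1e-6)
    expect_equal(aq$dw_dmu, fd(g_w, "mu"), tolerance = 1e-5)
    expect_equal(aq$dw_dphi, fd(g_w, "phi"), tolerance = 1e-5)
    expect_equal(aq$dc_dmu, fd(g_c, "mu"), tolerance = 1e-5)
    expect_equal(aq$dc_dphi, fd(g_c, "phi"), tolerance = 1e-5)
    expect_equal(aq$d2mustar_dphi2, fd(g_dms_dphi, "phi"), tolerance = 1e-5)
    expect_gt(aq$w, 0)
  }
})

test_that("indicator vector matches Hessian-plus-outer-product numerics and is mean zero", {
  ths <- random_thetas(8, seed = 202)
  set.seed(202)
  for (i in seq_len(nrow(ths))) {
    mu <- ths$mu[i]; phi <- ths$phi[i]
    y <- rbeta_mp(1, mu, phi)
    d <- drop(imt_dcontrib(y, c(mu, phi)))
    H <- fd_hessian(function(p) dbeta_mp(y, p[1], p[2], log = TRUE),
                    c(mu, phi), h = 1e-4 * max(1, phi / 10))
    s <- drop(beta_score(y, c(mu, phi)))
    dnum <- c(H[1, 1] + s[1]^2, H[1, 2] + s[1] * s[2], H[2, 2] + s[2]^2)
    expect_equal(d, dnum, tolerance = 1e-4, ignore_attr = TRUE)
  }
  # information equality at the truth: quadrature mean of each component is 0
  for (th in list(c(0.2, 40), c(0.5, 20))) {
    for (l in 1:3) {
      m <- beta_expect(function(v) imt_dcontrib(v, th)[, l], th[1], th[2])
      # d1 has magnitude phi^2 w ~ thousands; compare on relative scale
      scale <- max(1, abs(imt_dcontrib(0.3, th)[, l]))
      expect_lt(abs(m) / scale, 1e-6)
    }
  }
})

test_that("restriction set: Dn is the contrib average, Jacobian matches numerics, order-invariant", {
  ths <- random_thetas(6, seed = 203)
  set.seed(203)
  for (i in seq_len(nrow(ths))) {
    mu <- ths$mu[i]; phi <- ths$phi[i]
    y <- rbeta_mp(60, mu, phi)
    rs <- imt_restrictions(y, c(mu, phi), q = 3)
    expect_equal(rs$Dn, colMeans(rs$contribs))
    Jn <- fd_jacobian(function(p)
      colMeans(imt_dcontrib(y, theta_mp(p[1], p[2]))), c(mu, phi),
      h = 1e-6 * max(1, phi))
    expect_equal(unname(rs$gradDn), unname(Jn), tolerance = 1e-5,
                 ignore_attr = TRUE)
    # exchangeability
    perm <- sample(length(y))
    rs2 <- imt_restrictions(y[perm], c(mu, phi), q = 3)
    expect_equal(rs2$Dn, rs$Dn)
    expect_equal(rs2$gradDn, rs$gradDn)
  }
  expect_error(imt_restrictions(rbeta_mp(20, 0.3, 5), c(0.3, 5), q = 4), "q")
})

test_that("Dn at the MLE of a large well-specified sample is near zero", {
  set.seed(204)
  n <- 20000
  y <- rbeta_mp(n, 0.3, 25)
  fit <- beta_fit(y, se = FALSE)
  rs <- imt_restrictions(y, fit$theta_hat, q = 2)
  # compare against the Monte Carlo SE of each component mean
  for (l in 1:2) {
    se_l <- sd(rs$contribs[, l]) / sqrt(n)
    expect_lt(abs(rs$Dn[l]), 4 * se_l)
  }
})

test_that("all building-block matrices equal their naive per-observation transcription", {
  ths <- random_thetas(50, seed = 205)
  set.seed(205)
  for (i in seq_len(nrow(ths))) {
    mu <- ths$mu[i]; phi <- ths$phi[i]
    y <- rbeta_mp(25, mu, phi)
    rs <- imt_restrictions(y, c(mu, phi), q = 2)
    nb <- naive_blocks(y, mu, phi, q = 2)
    expect_equal(unname(rs$An), nb$An, tolerance = 1e-12)
    expect_equal(unname(rs$Bn), nb$Bn, tolerance = 1e-12)
    expect_equal(unname(rs$Ln), nb$Ln, tolerance = 1e-12)
    expect_equal(unname(rs$Dn), nb$Dn, tolerance = 1e-12)
    v1 <- imt_vn1(rs); v2 <- imt_vn2(rs)
    # Vn1 goes through the analytic Jacobian; the oracle differentiates
    # numerically, so agreement is to numerical-differentiation accuracy
    expect_equal(unname(v1$matrix), nb$Vn1, tolerance = 1e-6)
    expect_equal(unname(v2$matrix), nb$Vn2, tolerance = 1e-12)
    # symmetry and positive semi-definiteness
    for (V in list(v1$matrix, v2$matrix)) {
      expect_equal(V, t(V))
      expect_true(all(eigen(V, symmetric = TRUE)$values > -1e-10))
    }
  }
})

test_that("vn1 and vn2 agree at the MLE of a large well-specified sample", {
  set.seed(206)
  y <- rbeta_mp(20000, 0.4, 30)
  fit <- beta_fit(y, se = FALSE)
  rs <- imt_restrictions(y, fit$theta_hat)
  V1 <- imt_vn1(rs)$matrix
  V2 <- imt_vn2(rs)$matrix
  expect_equal(V1, V2, tolerance = 0.15)
})

test_that("bootstrap covariance is symmetric PSD, deterministic, and stabilizes in B", {
  set.seed(207)
  y <- rbeta_mp(100, 0.5, 20)
  th <- beta_fit(y, se = FALSE)$theta_hat
  V <- imt_boot_cov(y, th, B = 199, seed = 31)
  expect_equal(V$matrix, t(V$matrix))
  expect_true(all(eigen(V$matrix, symmetric = TRUE)$values > 0))
  V2 <- imt_boot_cov(y, th, B = 199, seed = 31)
  expect_identical(V$matrix, V2$matrix)
  # the d1 component has heavy tails (fourth moments of a logistic-type
  # transform), so individual trace comparisons are occasionally noisy;
  # the typical (median) discrepancy between B = 2000 and B = 4000 over a
  # fixed grid of bootstrap seeds is what must be small
  tr_diff <- vapply(31:37, function(s) {
    Va <- imt_boot_cov(y, th, B = 2000, seed = s)
    Vb <- imt_boot_cov(y, th, B = 4000, seed = s)
    abs(sum(diag(Va$matrix)) - sum(diag(Vb$matrix))) / sum(diag(Vb$matrix))
  }, 0)
  expect_lt(median(tr_diff), 0.10)
  expect_error(imt_boot_cov(y, th, B = 3), "at least")
})

test_that("quadratic form reduces to hand arithmetic and is nonnegative", {
  set.seed(208)
  y <- rbeta_mp(40, 0.3, 12)
  rs <- imt_restrictions(y, c(0.3, 12))
  # hand-checkable case: Dn = (0.1, 0), V = I, n = 100 -> 1.0
  rs_fake <- rs
  rs_fake$Dn <- c(0.1, 0, 0)
  V_id <- structure(list(matrix = diag(2), method = "vn1", B = NULL,
                         condition = 1), class = "imt_cov")
  expect_equal(imt_statistic(rs_fake, V_id, n = 100), 1.0)
  rs_fake$Dn <- c(0, 0, 0)
  expect_equal(imt_statistic(rs_fake, V_id, n = 100), 0)
  # PD covariance keeps the form nonnegative on real data
  expect_gte(imt_statistic(rs, imt_vn1(rs)), 0)
})

test_that("asymptotic tests: tail monotonicity and order invariance", {
  set.seed(209)
  y <- rbeta_mp(150, 0.4, 25)
  t1 <- imtest(y, "zeta1")
  expect_true(t1$p_value >= 0 && t1$p_value <= 1)
  expect_equal(t1$p_value, pchisq(t1$statistic, 2, lower.tail = FALSE))
  # decreasing in the statistic for fixed q
  expect_gt(pchisq(t1$statistic, 2, lower.tail = FALSE),
            pchisq(t1$statistic + 1, 2, lower.tail = FALSE))
  t1p <- imtest(y[sample(length(y))], "zeta1")
  expect_equal(t1p$statistic, t1$statistic)
  expect_equal(t1p$p_value, t1$p_value)
  t2 <- imtest(y, "zeta2")
  expect_equal(t2$p_value, pchisq(t2$statistic, 2, lower.tail = FALSE))
})

test_that("zeta3: Hotelling and scaled-F formulations give identical p-values", {
  set.seed(210)
  y <- rbeta_mp(80, 0.6, 15)
  t3 <- imtest(y, "zeta3", B = 149, seed = 5)
  B <- t3$B; q <- t3$q
  pF <- pf(t3$statistic * (B - q) / (q * (B - 1)), q, B - q, lower.tail = FALSE)
  expect_equal(t3$p_value, pF)
  # fixed seed reproducibility
  t3b <- imtest(y, "zeta3", B = 149, seed = 5)
  expect_equal(t3b$statistic, t3$statistic)
  expect_equal(t3b$p_value, t3$p_value)
})

test_that("bootstrap critical values: p-value/quantile duality and reproducibility", {
  set.seed(211)
  y <- rbeta_mp(60, 0.35, 18)
  tb <- imtest(y, "zeta1B", B = 99, seed = 13)
  expect_length(tb$boot_stats, 99)
  # decisions from the empirical-quantile rule match p-value thresholding
  for (alpha in c(0.01, 0.05, 0.10, 0.25, 0.5)) {
    crit <- sort(tb$boot_stats)[ceiling((1 - alpha) * tb$B)]
    p_emp <- mean(tb$boot_stats >= tb$statistic)
    expect_equal(tb$statistic > crit, p_emp < alpha)
    expect_equal(imt_reject(tb, alpha), tb$statistic > crit)
  }
  tb2 <- imtest(y, "zeta1B", B = 99, seed = 13)
  expect_equal(tb2$boot_stats, tb$boot_stats)
  expect_equal(tb2$p_value, tb$p_value)
  # plus-one convention
  expect_equal(tb$p_value,
               (1 + sum(tb$boot_stats >= tb$statistic)) / (tb$B + 1))
})

test_that("statistics diverge under a Kumaraswamy alternative as n grows", {
  set.seed(212)
  med_stat <- function(n, reps = 40) {
    median(replicate(reps, {
      y <- rkumaraswamy(n, 0.2, 7.5)
      fit <- beta_fit(y, se = FALSE)
      rs <- imt_restrictions(y, fit$theta_hat)
      imt_statistic(rs, imt_vn1(rs))
    }))
  }
  expect_gt(med_stat(1000), med_stat(100))
})
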