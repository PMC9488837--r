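# Independent oracles used across the suite: finite differences,
# quadrature expectations, and literal per-observation transcriptions of
# the test-statistic building blocks.

fd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, 0)
}

fd_hessian <- function(f, x, h = 1e-4) {
  k <- length(x)
  H <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ei <- numeric(k); ei[i] <- h
    ej <- numeric(k); ej[j] <- h
    H[i, j] <- (f(x + ei + ej) - f(x + ei - ej) -
                  f(x - ei + ej) + f(x - ei - ej)) / (4 * h^2)
  }
  (H + t(H)) / 2
}

fd_jacobian <- function(f, x, h = 1e-6) {
  cols <- lapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  })
  do.call(cbind, cols)
}

# E[g(Y)] under the beta(mu, phi) law by adaptive quadrature.
beta_expect <- function(g, mu, phi, rel.tol = 1e-10) {
  integrate(function(y) vapply(y, function(v) g(v) * dbeta_mp(v, mu, phi), 0),
            0, 1, rel.tol = rel.tol, subdivisions = 500L)$value
}

# Literal, slow transcriptions of the printed building blocks, computed
# observation by observation. Deliberately independent of the package's
# vectorized implementations.
naive_blocks <- function(y, mu, phi, q = 2L) {
  n <- length(y)
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  mudag <- digamma((1 - mu) * phi) - digamma(phi)
  w <- trigamma(mu * phi) + trigamma((1 - mu) * phi)
  cc <- phi * (mu * w - trigamma((1 - mu) * phi))
  An <- matrix(0, 2, 2); Bn <- matrix(0, 2, 2)
  d <- matrix(0, n, 3); s <- matrix(0, n, 2)
  for (t in seq_len(n)) {
    ys <- log(y[t] / (1 - y[t])); yd <- log(1 - y[t])
    s[t, ] <- c(phi * (ys - mustar), mu * (ys - mustar) + (yd - mudag))
    At <- matrix(c(-phi^2 * w,
                   (ys - mustar) - cc,
                   (ys - mustar) - cc,
                   -(mu * cc) / phi - (1 - mu) * trigamma((1 - mu) * phi) +
                     trigamma(phi)), 2, 2)
    An <- An + At / n
    Bn <- Bn + tcrossprod(s[t, ]) / n
    d[t, ] <- c(phi^2 * ((ys - mustar)^2 - w),
                (ys - mustar) - cc +
                  phi * (ys - mustar) * (mu * (ys - mustar) + (yd - mudag)),
                -(mu * cc) / phi - (1 - mu) * trigamma((1 - mu) * phi) +
                  trigamma(phi) + (mu * (ys - mustar) + (yd - mudag))^2)
  }
  Ln <- matrix(0, 3, 2)
  for (t in seq_len(n)) Ln <- Ln - d[t, ] %*% t(s[t, ]) / n
  Dn <- colMeans(d)
  act <- seq_len(q)
  gradDn <- fd_jacobian(function(p) {
    colMeans(naive_dcontrib(y, p[1], p[2]))
  }, c(mu, phi))
  Vn1 <- matrix(0, q, q)
  M1 <- gradDn[act, , drop = FALSE] %*% solve(An)
  for (t in seq_len(n)) {
    r <- d[t, act] - M1 %*% s[t, ]
    Vn1 <- Vn1 + tcrossprod(r) / n
  }
  Vn2 <- matrix(0, q, q)
  M2 <- Ln[act, , drop = FALSE] %*% solve(Bn)
  for (t in seq_len(n)) {
    r <- d[t, act] + M2 %*% s[t, ]
    Vn2 <- Vn2 + tcrossprod(r) / n
  }
  list(An = An, Bn = Bn, Ln = Ln, Dn = Dn, Vn1 = Vn1, Vn2 = Vn2, d = d, s = s)
}

naive_dcontrib <- function(y, mu, phi) {
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  mudag <- digamma((1 - mu) * phi) - digamma(phi)
  w <- trigamma(mu * phi) + trigamma((1 - mu) * phi)
  cc <- phi * (mu * w - trigamma((1 - mu) * phi))
  t(vapply(y, function(v) {
    ys <- log(v / (1 - v)); yd <- log(1 - v)
    c(phi^2 * ((ys - mustar)^2 - w),
      (ys - mustar) - cc +
        phi * (ys - mustar) * (mu * (ys - mustar) + (yd - mudag)),
      -(mu * cc) / phi - (1 - mu) * trigamma((1 - mu) * phi) +
        trigamma(phi) + (mu * (ys - mustar) + (yd - mudag))^2)
  }, numeric(3)))
}

# random interior parameter draws for property-style loops
random_thetas <- function(k, seed = 1) {
  set.seed(seed)
  data.frame(mu = runif(k, 0.1, 0.9), phi = exp(runif(k, log(2), log(120))))
}
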