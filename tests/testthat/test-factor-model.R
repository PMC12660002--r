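test_that("marginal moments match closed form and simulation", {
  ## zero loadings: covariance is purely diagonal
  p0 <- fa_params(c(0, 0), matrix(0, 2, 1), matrix(1), c(2, 3))
  mm <- fa_marginal_moments(p0)
  expect_equal(mm$cov, diag(c(2, 3)))
  ## scalar case: lambda^2 phi + psi = 1.5
  p1 <- fa_params(0, matrix(1), matrix(1), 0.5)
  expect_equal(fa_marginal_moments(p1)$cov[1, 1], 1.5)
  ## MC oracle: sample covariance of simulated draws within 4 MC SEs
  pars <- small_params()
  mm <- fa_marginal_moments(pars)
  n <- 2e5
  x <- fa_simulate(pars, n, seed = 101)
  Shat <- cov(x)
  se <- sqrt((outer(diag(mm$cov), diag(mm$cov)) + mm$cov^2) / n)
  expect_true(all(abs(Shat - mm$cov) < 4 * se))
  expect_true(all(abs(colMeans(x) - mm$mean) < 4 * sqrt(diag(mm$cov) / n)))
})

test_that("invalid parameters are rejected", {
  expect_error(fa_params(c(0, 0), matrix(0, 2, 1), matrix(-1), c(1, 1)),
               "positive definite")
  expect_error(fa_params(c(0, 0), matrix(0, 2, 1), matrix(1), c(1, 0)),
               "strictly positive")
  expect_error(fa_params(0, matrix(1), matrix(c(1, 2, 3, 1), 2), 0.5))
})

test_that("log-likelihood matches a dense per-row oracle", {
  ## density at the mean with identity covariance: -log(2*pi)
  p0 <- fa_params(c(0.5, -0.5), matrix(0, 2, 1), matrix(1), c(1, 1))
  expect_equal(fa_loglik(p0, matrix(c(0.5, -0.5), 1)), -log(2 * pi))
  pars <- small_params()
  x <- fa_simulate(pars, 50, seed = 7)
  expect_equal(fa_loglik(pars, x), oracle_loglik(pars, x), tolerance = 1e-10)
  ## relabeling invariance: permuting MVs with matching parameter rows
  perm <- c(3, 1, 5, 2, 4)
  pperm <- fa_params(pars$nu[perm], pars$Lambda[perm, , drop = FALSE],
                     pars$Phi, pars$Psi[perm])
  expect_equal(fa_loglik(pperm, x[, perm]), fa_loglik(pars, x))
})

test_that("theta packing round-trips under both identifications", {
  spec <- small_spec()
  pars <- small_params()
  expect_equal(fa_unpack(fa_pack(pars, spec), spec), pars)
  ## anchor-loading: first loading per factor fixed at one
  pat <- cbind(c(1, 1, 1, 0, 0, 0), c(0, 0, 0, 1, 1, 1))
  spec2 <- fa_model_spec(6, 2, pat, identification = "anchor_loading")
  Lam <- pat * 0
  Lam[1:3, 1] <- c(1, 0.8, 0.6); Lam[4:6, 2] <- c(1, 0.7, 0.9)
  pars2 <- fa_params(rep(0, 6), Lam, matrix(c(0.9, 0.3, 0.3, 1.2), 2),
                     rep(0.5, 6), spec2)
  th <- fa_pack(pars2, spec2)
  expect_length(th, spec2$npar)
  expect_equal(fa_unpack(th, spec2), pars2)
})

test_that("scores match finite differences and have zero mean", {
  spec <- small_spec()
  pars <- small_params()
  x1 <- fa_simulate(pars, 1, seed = 3)
  th <- fa_pack(pars, spec)
  sc <- fa_score(pars, x1, spec)[1, ]
  fd <- fd_grad(function(t) fa_loglik(fa_unpack(t, spec), x1), th)
  expect_equal(sc, fd, tolerance = 1e-6, ignore_attr = TRUE)
  ## zero-mean score property at the generating parameters
  y <- fa_simulate(pars, 2e4, seed = 8)
  scm <- fa_score(pars, y, spec)
  se <- apply(scm, 2, sd) / sqrt(nrow(y))
  expect_true(all(abs(colMeans(scm)) < 4 * se))
})

test_that("expected information satisfies its defining identities", {
  spec <- small_spec()
  pars <- small_params()
  info <- fa_information(pars, spec)
  expect_equal(info, t(info), tolerance = 1e-12)
  expect_gt(min(eigen(info, symmetric = TRUE, only.values = TRUE)$values), 0)
  ## information identity: covariance of simulated scores
  info_mc <- fa_information(pars, spec, method = "mc", R = 4e4, seed = 21)
  expect_lt(norm(info_mc - info, "F") / norm(info, "F"), 0.05)
  ## equals minus the Hessian of the population expected log-likelihood
  th <- fa_pack(pars, spec)
  H <- fd_hessian(expected_loglik_fn(th, spec), th, h = 1e-4)
  expect_equal(-H, info, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("information of the two-factor design is positive definite", {
  cfg <- study1_config(100)
  info <- fa_information(true_params(cfg), analysis_spec(cfg))
  expect_lt(max(abs(info - t(info))), 1e-12)
  expect_gt(min(eigen(info, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("ML fitting recovers generating parameters and is start-stable", {
  spec <- small_spec()
  pars <- small_params()
  x <- fa_simulate(pars, 5e4, seed = 11)
  fit <- fa_fit(x, spec)
  expect_true(fit$converged)
  expect_lt(max(abs(coef(fit) - fa_pack(pars, spec))), 0.03)
  expect_lt(fit$grad_max, 1e-5)
  expect_true(all(fit$params$Psi > 0))
  ## first-order condition: summed per-observation scores vanish
  total_score <- colSums(fa_score(fit$params, x, spec))
  expect_lt(max(abs(total_score)), 1e-4)
  ## random restarts land on the same optimum
  x2 <- fa_simulate(pars, 1000, seed = 12)
  base <- fa_fit(x2, spec)
  set.seed(99)
  for (k in 1:5) {
    st <- pars
    st$nu <- st$nu + rnorm(5, sd = 0.3)
    st$Lambda <- st$Lambda + matrix(rnorm(5, sd = 0.2), 5, 1)
    st$Psi <- st$Psi * exp(rnorm(5, sd = 0.3))
    alt <- fa_fit(x2, spec, start = st)
    expect_lt(abs(alt$loglik - base$loglik), 1e-6)
  }
})

test_that("estimation errors shrink at the root-n rate", {
  spec <- small_spec()
  pars <- small_params()
  th0 <- fa_pack(pars, spec)
  err <- vapply(c(1e3, 1e4, 1e5), function(n) {
    fit <- fa_fit(fa_simulate(pars, n, seed = n + 5), spec)
    sqrt(mean((coef(fit) - th0)^2))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  ## error ratio across a 100-fold n increase is near 1/10
  expect_lt(err[3] / err[1], 0.4)
})

test_that("degenerate and unidentified inputs fail loudly", {
  pars <- small_params()
  x <- fa_simulate(pars, 200, seed = 13)
  expect_error(fa_fit(cbind(x, x[, 5]), fa_model_spec(6, 1)), "singular")
  ## two indicators on one factor are not identified
  p2 <- fa_params(c(0, 0), matrix(c(0.7, 0.7), 2, 1), matrix(1), c(0.5, 0.5))
  x2 <- fa_simulate(p2, 300, seed = 14)
  expect_error(suppressWarnings(fa_fit(x2, fa_model_spec(2, 1))),
               "identif")
  expect_warning(fa_fit(x[1:10, ], small_spec()), "sample size")
})

test_that("posterior density obeys Bayes' theorem and normalizes", {
  pars <- small_params()
  x <- fa_simulate(pars, 4, seed = 15)
  etas <- matrix(seq(-2, 2, length.out = 9), ncol = 1)
  dens <- fa_posterior_density(pars, x, etas)
  ## Bayes quotient: f(x | eta) f(eta) / f(x), all from independent formulas
  mm <- fa_marginal_moments(pars)
  for (i in 1:4) for (q in 1:9) {
    eta <- etas[q, ]
    mu_cond <- pars$nu + pars$Lambda %*% eta
    f_x_eta <- prod(dnorm(x[i, ], mu_cond, sqrt(pars$Psi)))
    f_eta <- dnorm(eta, 0, sqrt(pars$Phi[1, 1]))
    f_x <- exp(grfa:::dmvn_log(x[i, , drop = FALSE], mm$mean, mm$cov))
    expect_equal(dens[i, q], f_x_eta * f_eta / f_x, tolerance = 1e-10)
  }
  ## normalization over a wide quadrature grid
  grid <- matrix(seq(-8, 8, by = 0.01), ncol = 1)
  dq <- fa_posterior_density(pars, x[1, , drop = FALSE], grid)
  expect_equal(sum(dq) * 0.01, 1, tolerance = 1e-6)
  ## no-information case: posterior equals the prior for any x
  p0 <- fa_params(pars$nu, matrix(0, 5, 1), matrix(1), pars$Psi)
  d0 <- fa_posterior_density(p0, x, etas)
  prior <- dnorm(etas[, 1])
  for (i in 1:4) expect_equal(d0[i, ], prior, tolerance = 1e-12)
  ## posterior covariance is dominated by the prior covariance
  V <- fa_posterior_moments(pars)$cov
  expect_gte(min(eigen(pars$Phi - V, symmetric = TRUE,
                       only.values = TRUE)$values), -1e-12)
})

test_that("simulation is seed-reproducible and respects independence", {
  pars <- small_params()
  expect_identical(fa_simulate(pars, 100, seed = 4),
                   fa_simulate(pars, 100, seed = 4))
  ## zero loadings: columns empirically uncorrelated
  p0 <- fa_params(c(0, 0), matrix(0, 2, 1), matrix(1), c(1, 1))
  x <- fa_simulate(p0, 1e6, seed = 5)
  expect_lt(max(abs(cor(x)[1, 2])), 0.01)
})
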