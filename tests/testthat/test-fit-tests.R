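test_that("evaluation grids are evenly spaced with exact endpoints", {
  g <- make_grid(1, 31, -3, 3, 11)
  expect_equal(nrow(g$points), 31)
  expect_equal(unique(round(diff(g$points[, 1]), 10)), 0.2)
  expect_equal(range(g$points[, 1]), c(-3, 3))
  expect_length(g$subgrid, 11)
  g2 <- make_grid(2, 7, -3, 3)
  expect_equal(nrow(g2$points), 49)
  expect_length(g2$subgrid, 49)
  expect_equal(make_grid(1, 2, 0, 1)$points[, 1], c(0, 1))
  expect_error(make_grid(4, 3), "d > 3")
  ## default one-dimensional subgrid spans [-2, 2]
  gd <- grfa:::default_grid(1)
  expect_equal(range(gd$points[gd$subgrid, 1]), c(-2, 2))
  expect_length(gd$subgrid, 11)
})

test_that("zero-loading fit gives identically zero density residuals", {
  m <- 4
  p0 <- fa_params(rep(0, m), matrix(0, m, 1), matrix(1), rep(1, m))
  fit0 <- fa_fit_known(p0, fa_model_spec(m, 1), n = 50)
  x <- fa_simulate(p0, 50, seed = 40)
  g <- make_grid(1, 7, -2, 2)
  des <- design_lv_density(g)
  mc <- mc_moments(des, fit0, R = 500, seed = 41)
  res <- residual_acm(des, x, fit0, mc)
  ## posterior equals prior for every row, so residuals vanish exactly
  expect_equal(res$r, rep(0, 7), tolerance = 1e-14, ignore_attr = TRUE)
})

test_that("MC expectation of the posterior-density summary recovers the model latent density", {
  pars <- small_params()
  fit <- fa_fit_known(pars, small_spec(), n = 100)
  g <- make_grid(1, 7, -2.5, 2.5)
  des <- design_lv_density(g)
  for (R in c(1e4, 1e5)) {
    mc <- mc_moments(des, fit, R = R, seed = R + 1)
    target <- dnorm(g$points[, 1])
    se <- sqrt(diag(mc$Sigma) / R)
    expect_true(all(abs(mc$Ehat - target) < 4 * se + 1e-12))
  }
})

test_that("population ratio summaries recover the conditional moments", {
  pars <- small_params()
  fit <- fa_fit_known(pars, small_spec(), n = 100)
  g <- make_grid(1, 7, -2, 2)
  Q <- 7; j <- 2
  R <- 1e5
  ## conditional mean: ratio of MC means -> nu_j + lambda_j eta
  des_a <- design_mv_linearity(g, j)
  mc <- mc_moments(des_a, fit, R = R, seed = 51)
  ratio <- mc$Ehat[1:Q] / mc$Ehat[Q + 1:Q]
  target <- pars$nu[j] + pars$Lambda[j, 1] * g$points[, 1]
  se <- vapply(1:Q, function(q) {
    Eb <- mc$Ehat[Q + q]
    va <- mc$Sigma[q, q]; vb <- mc$Sigma[Q + q, Q + q]
    cab <- mc$Sigma[q, Q + q]
    sqrt((va + ratio[q]^2 * vb - 2 * ratio[q] * cab) / R) / Eb
  }, numeric(1))
  expect_true(all(abs(ratio - target) < 4 * se))
  ## conditional variance: ratio -> psi_j at every grid value
  des_v <- design_mv_homoscedasticity(g, j)
  mcv <- mc_moments(des_v, fit, R = R, seed = 52)
  ratio_v <- mcv$Ehat[1:Q] / mcv$Ehat[Q + 1:Q]
  se_v <- vapply(1:Q, function(q) {
    Eb <- mcv$Ehat[Q + q]
    va <- mcv$Sigma[q, q]; vb <- mcv$Sigma[Q + q, Q + q]
    cab <- mcv$Sigma[q, Q + q]
    sqrt((va + ratio_v[q]^2 * vb - 2 * ratio_v[q] * cab) / R) / Eb
  }, numeric(1))
  expect_true(all(abs(ratio_v - pars$Psi[j]) < 4 * se_v))
})

test_that("turnkey tests produce coherent reports on a correct model", {
  pars <- small_params()
  spec <- small_spec()
  x <- fa_simulate(pars, 600, seed = 60)
  fit <- fa_fit(x, spec)
  rep1 <- lv_density_test(fit, x, R = 3000, seed = 61)
  expect_s3_class(rep1, "gof_report")
  expect_equal(nrow(rep1$table), 31)
  expect_true(all(rep1$table$p >= 0 & rep1$table$p <= 1, na.rm = TRUE))
  expect_equal(rep1$overall$s, 2)
  expect_gte(rep1$overall$T, 0)
  ## model-implied side of the density test is the normal latent density
  expect_equal(rep1$table$model_implied, dnorm(rep1$table$eta1))
  rep2 <- mv_linearity_test(fit, x, j = 1, R = 3000, seed = 62)
  expect_equal(rep2$table$model_implied,
               fit$params$nu[1] + fit$params$Lambda[1, 1] * rep2$table$eta1)
  rep3 <- mv_homoscedasticity_test(fit, x, j = 1, R = 3000, seed = 63)
  expect_equal(rep3$table$model_implied, rep(fit$params$Psi[1], 31))
  ## usable rows carry z and p; unusable rows carry neither
  for (rp in list(rep1, rep2, rep3)) {
    expect_true(all(is.finite(rp$table$z[rp$table$usable])))
    expect_true(all(is.na(rp$table$z[!rp$table$usable])))
  }
})

test_that("direct conditional-mean summaries share the linearity numerator", {
  pars <- small_params()
  spec <- small_spec()
  x <- fa_simulate(pars, 400, seed = 70)
  fit <- fa_fit(x, spec)
  g <- make_grid(1, 11, -2, 2)
  r_lin <- grfa:::run_gof_test(fit, x, "mv_linearity", j = 2, grid = g,
                               R = 2000, seed = 71)
  r_dir <- grfa:::run_gof_test(fit, x, "mv_direct_mean", j = 2, grid = g,
                               R = 2000, seed = 71)
  expect_equal(r_dir$residual$ebar, r_lin$residual$ebar[1:11],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("unstable ratio denominators are flagged and excluded", {
  pars <- small_params()
  spec <- small_spec()
  x <- fa_simulate(pars, 400, seed = 80)
  fit <- fa_fit(x, spec)
  ## grid reaching far into the tails: model density < 1e-4 of its maximum
  g_wide <- make_grid(1, 13, -6, 6, 5, sub_lo = -2, sub_hi = 2)
  rp <- mv_linearity_test(fit, x, j = 1, grid = g_wide, R = 2000, seed = 81)
  expect_true(any(!rp$table$usable))
  expect_true(all(!rp$table$usable[abs(rp$table$eta1) > 5]))
  expect_true(all(is.na(rp$table$z[!rp$table$usable])))
  ## a subgrid containing such points refuses the overall statistic
  g_bad <- make_grid(1, 13, -6, 6)
  expect_error(mv_linearity_test(fit, x, j = 1, grid = g_bad, R = 2000,
                                 seed = 82), "unusable")
})

test_that("reports are written as TSV and JSON and plots render", {
  pars <- small_params()
  x <- fa_simulate(pars, 300, seed = 90)
  fit <- fa_fit(x, small_spec())
  rp <- lv_density_test(fit, x, R = 2000, seed = 91)
  tsv <- tempfile(fileext = ".tsv"); json <- tempfile(fileext = ".json")
  write_gof_report(rp, tsv = tsv, json = json)
  tab <- read.delim(tsv)
  expect_equal(nrow(tab), nrow(rp$table))
  expect_equal(tab$z, rp$table$z, tolerance = 1e-6)
  js <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(js$T, rp$overall$T)
  expect_equal(js$options$n, 300)
  ## plot data: band half-width equals the normal critical value times se
  grDevices::pdf(NULL)
  pd <- plot(rp)
  grDevices::dev.off()
  ok <- is.finite(pd$lower)
  expect_equal(pd$upper[ok] - pd$empirical[ok],
               qnorm(0.975) * rp$table$se[ok], tolerance = 1e-9)
})
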