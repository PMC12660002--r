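test_that("two-factor generator matches its stated latent moments", {
  cfg <- study1_config(2e5)
  sim <- gen_study1(cfg, seed = 1)
  ## latent correlation near 0.2 (SE of a correlation ~ (1 - rho^2)/sqrt(n))
  expect_lt(abs(cor(sim$eta)[1, 2] - 0.2), 4 * (1 - 0.04) / sqrt(2e5))
  ## communalities cycle 0.3/0.5/0.7: loadings and uniquenesses
  expect_equal(sim$params$Lambda[1:3, 1], sqrt(c(0.3, 0.5, 0.7)))
  expect_equal(sim$params$Psi[1:3], c(0.7, 0.5, 0.3))
  expect_equal(colSums(sim$params$Lambda != 0), c(10, 10),
               ignore_attr = TRUE)
  ## marginal moments of the manifest variables
  mm <- fa_marginal_moments(sim$params)
  expect_lt(max(abs(colMeans(sim$data))), 4 * sqrt(1 / 2e5) * 1.1)
  expect_lt(max(abs(cov(sim$data) - mm$cov)), 0.02)
})

test_that("latent mixture is moment-matched and bimodal by construction", {
  cfg <- study1_config(2e5, misspecified = TRUE)
  ## within-component latent correlation is negative
  expect_lt(cfg$mixture$cov[1, 2], 0)
  sim <- gen_study1(cfg, seed = 2)
  expect_lt(max(abs(colMeans(sim$eta))), 4 / sqrt(2e5))
  expect_lt(max(abs(cov(sim$eta) - cfg$Phi)), 0.012)
  ## invalid overrides are refused
  expect_error(study1_config(100, misspecified = TRUE,
                             mixture = list(weights = c(0.5, 0.5),
                                            means = rbind(c(1, 1), c(-1, -1)),
                                            cov = diag(2))),
               "moment constraint")
  expect_error(study1_config(100, misspecified = TRUE,
                             mixture = list(weights = c(0.5, 0.5),
                                            means = rbind(c(0.7, 0.7),
                                                          c(-0.7, -0.7)),
                                            cov = matrix(c(1, 2, 2, 1), 2))),
               "positive definite")
})

test_that("one-factor generator honors the four conditional-moment kinds", {
  ## correctly specified data nest the linear normal factor model
  cfg <- study2_config(2e5)
  expect_true(all(cfg$kinds == "LMCV"))
  sim <- gen_study2(cfg, seed = 3)
  mm <- fa_marginal_moments(sim$params)
  expect_equal(diag(mm$cov), rep(1, 10), ignore_attr = TRUE)
  expect_lt(max(abs(cov(sim$data) - mm$cov)), 0.02)
  ## quadratic mean shifts the marginal mean by beta2 (E[eta^2] = 1)
  cfgm <- study2_config(2e5, misspecified = TRUE)
  expect_equal(cfgm$kinds[8:10], c("QMCV", "LMLV", "QMLV"))
  simm <- gen_study2(cfgm, seed = 4)
  expect_lt(abs(mean(simm$data[, 8]) - cfgm$beta2), 4 * sd(simm$data[, 8]) /
              sqrt(2e5))
  ## log-linear variance: Var(x) = lambda^2 + exp(beta3 + beta4^2 / 2)
  target_var <- cfgm$lambda^2 + exp(cfgm$beta3 + cfgm$beta4^2 / 2)
  v <- var(simm$data[, 9])
  se_v <- sqrt((mean((simm$data[, 9] - mean(simm$data[, 9]))^4) - v^2) / 2e5)
  expect_lt(abs(v - target_var), 5 * se_v)
  ## conditional variance must be positive on [-4, 4]
  expect_error(study2_config(100, lambda = 1.2), "lambda")
})

test_that("generators are seed-reproducible and round-trip manifests", {
  cfg <- study1_config(50, misspecified = TRUE)
  s1 <- gen_study1(cfg, seed = 9)
  s2 <- gen_study1(cfg, seed = 9)
  expect_identical(s1$data, s2$data)
  path <- tempfile(fileext = ".json")
  write_sim_manifest(s1, path)
  s3 <- gen_from_manifest(path)
  expect_equal(s3$data, s1$data)
  cfg2 <- study2_config(40, misspecified = TRUE)
  t1 <- gen_study2(cfg2, seed = 10)
  path2 <- tempfile(fileext = ".json")
  write_sim_manifest(t1, path2)
  t2 <- gen_from_manifest(path2)
  expect_equal(t2$data, t1$data)
})

test_that("rate tables are well-formed and chunking-invariant", {
  cfg <- study2_config(150)
  full <- replicate_rates(cfg, tests = "mv_linearity", mvs = 2, reps = 10,
                          R = 700, seed = 100)
  expect_s3_class(full, "rates_table")
  r <- full$results[[1]]
  expect_true(r$overall_rate >= 0 && r$overall_rate <= 1)
  expect_equal(r$n_reps, 10)
  expect_equal(full$failures, 0)
  expect_length(full$band, 2)
  ## two chunks with offsets reproduce the single run exactly
  c1 <- replicate_rates(cfg, tests = "mv_linearity", mvs = 2, reps = 5,
                        R = 700, seed = 100, rep_offset = 0)
  c2 <- replicate_rates(cfg, tests = "mv_linearity", mvs = 2, reps = 5,
                        R = 700, seed = 100, rep_offset = 5)
  combined <- (c1$results[[1]]$overall_rate * c1$results[[1]]$n_reps +
                 c2$results[[1]]$overall_rate * c2$results[[1]]$n_reps) /
    (c1$results[[1]]$n_reps + c2$results[[1]]$n_reps)
  expect_equal(combined, r$overall_rate)
  expect_equal((c1$results[[1]]$pointwise_rates +
                  c2$results[[1]]$pointwise_rates) / 2,
               r$pointwise_rates)
})
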