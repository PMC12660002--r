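#' Configuration for the two-factor simulation design
#'
#' A two-dimensional independent-cluster model with 20 MVs (two clusters of
#' 10), zero intercepts, communalities cycling over `communalities`
#' (loading = sqrt of communality on the cluster factor, error variance = 1 -
#' communality), and latent correlation `correlation`. Under
#' `misspecified = TRUE` the latent vector is drawn from a two-component
#' normal mixture constrained to have mean zero and exactly the same
#' covariance matrix as the correct condition (so mean/covariance diagnostics
#' cannot see the difference); the default mixture has equal weights,
#' component means at +/-(0.7, 0.7), and within-component covariance
#' `[[0.51, -0.29], [-0.29, 0.51]]`, giving negatively correlated latent
#' variables within each subgroup.
#'
#' @param n Sample size.
#' @param misspecified Draw latent variables from the mixture?
#' @param correlation Latent correlation of the correct condition.
#' @param communalities Values cycled across MVs.
#' @param m Number of MVs (split into two equal clusters).
#' @param mixture List with `weights` (length 2), `means` (2 x 2 matrix, one
#'   row per component), `cov` (shared 2 x 2 within-component covariance).
#'   Overrides are validated against the exact moment constraint.
#' @return Object of class `"study1_config"`.
#' @export
study1_config <- function(n, misspecified = FALSE, correlation = 0.2,
                          communalities = c(0.3, 0.5, 0.7), m = 20,
                          mixture = NULL) {
  stopifnot(is_count(n), m %% 2 == 0)
  Phi <- matrix(c(1, correlation, correlation, 1), 2, 2)
  mixture <- mixture %||% list(
    weights = c(0.5, 0.5),
    means = rbind(c(0.7, 0.7), c(-0.7, -0.7)),
    cov = matrix(c(0.51, -0.29, -0.29, 0.51), 2, 2))
  w <- mixture$weights; mu <- mixture$means; V <- mixture$cov
  stopifnot(length(w) == 2, abs(sum(w) - 1) < 1e-12,
            all(dim(mu) == c(2, 2)), all(dim(V) == c(2, 2)))
  if (min(eigen(V, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("mixture component covariance is not positive definite",
         call. = FALSE)
  mix_mean <- as.numeric(w %*% mu)
  mix_cov <- V + w[1] * tcrossprod(mu[1, ]) + w[2] * tcrossprod(mu[2, ]) -
    tcrossprod(mix_mean)
  if (max(abs(mix_mean)) > 1e-10 || max(abs(mix_cov - Phi)) > 1e-10)
    stop("mixture does not satisfy the exact moment constraint (mean 0, ",
         "covariance equal to the correct condition)", call. = FALSE)
  comm <- rep_len(communalities, m)
  Lambda <- matrix(0, m, 2)
  half <- m / 2
  Lambda[seq_len(half), 1] <- sqrt(comm[seq_len(half)])
  Lambda[half + seq_len(half), 2] <- sqrt(comm[half + seq_len(half)])
  structure(list(n = as.integer(n), misspecified = isTRUE(misspecified),
                 Phi = Phi, Lambda = Lambda, Psi = 1 - comm,
                 mixture = mixture, m = as.integer(m)),
            class = "study1_config")
}

#' Analysis model and generating parameters of a simulation design
#'
#' `analysis_spec()` returns the [fa_model_spec()] that the replication
#' harness always fits (the linear normal factor model with the design's
#' loading pattern); `true_params()` returns the generating [fa_params()]
#' (for the misspecified conditions, the normal-model parameters sharing the
#' generating first two moments).
#'
#' @param config A [study1_config()] or [study2_config()].
#' @return An [fa_model_spec()] / [fa_params()].
#' @export
analysis_spec <- function(config) UseMethod("analysis_spec")

#' @export
analysis_spec.study1_config <- function(config)
  fa_model_spec(config$m, 2, pattern = 1 * (config$Lambda != 0),
                identification = "unit_factor_variance")

#' @rdname analysis_spec
#' @export
true_params <- function(config) UseMethod("true_params")

#' @export
true_params.study1_config <- function(config)
  fa_params(numeric(config$m), config$Lambda, config$Phi, config$Psi)

#' Generate data from the two-factor design
#'
#' @param config A [study1_config()].
#' @param seed Integer seed (reproducible).
#' @return List with `data` (`n x m` matrix), `eta` (`n x 2` latent draws),
#'   `params` ([true_params()]), `config`, `seed`.
#' @export
gen_study1 <- function(config, seed = NULL) {
  stopifnot(inherits(config, "study1_config"))
  n <- config$n
  out <- with_seed(seed, {
    if (config$misspecified) {
      w <- config$mixture$weights
      comp <- stats::rbinom(n, 1, w[2]) + 1L
      eta <- rmvn(n, numeric(2), config$mixture$cov) +
        config$mixture$means[comp, , drop = FALSE]
    } else {
      eta <- rmvn(n, numeric(2), config$Phi)
    }
    eps <- matrix(stats::rnorm(n * config$m), n, config$m) *
      rep(sqrt(config$Psi), each = n)
    list(eta = eta, x = eta %*% t(config$Lambda) + eps)
  })
  list(data = out$x, eta = out$eta, params = true_params(config),
       config = config, seed = seed)
}

#' Configuration for the one-factor MV-level design
#'
#' A linear normal one-factor model with `m = 10` MVs, standard-normal latent
#' variable, zero intercepts, loading `lambda` and error variance
#' `1 - lambda^2`. Each MV has a conditional-moment kind from Table
#' `{LMCV, QMCV, LMLV, QMLV}` crossing linear vs quadratic mean (quadratic
#' adds `beta2 * eta^2`) with constant vs log-linear variance
#' (`exp(beta3 + beta4 * eta)`). The correct condition uses LMCV throughout;
#' the misspecified condition makes MVs 8-10 QMCV, LMLV, and QMLV.
#'
#' @param n Sample size.
#' @param misspecified Use the misspecified kinds for MVs 8-10?
#' @param m Number of MVs.
#' @param lambda Base loading.
#' @param beta2 Quadratic mean coefficient.
#' @param beta3,beta4 Log-linear variance intercept and slope.
#' @param kinds Optional explicit character vector of kinds per MV.
#' @return Object of class `"study2_config"`.
#' @export
study2_config <- function(n, misspecified = FALSE, m = 10,
                          lambda = sqrt(0.5), beta2 = 0.1,
                          beta3 = log(0.5), beta4 = 0.5, kinds = NULL) {
  stopifnot(is_count(n), m >= 3, lambda^2 < 1)
  kinds <- kinds %||% {
    k <- rep("LMCV", m)
    if (misspecified) k[(m - 2):m] <- c("QMCV", "LMLV", "QMLV")
    k
  }
  stopifnot(length(kinds) == m,
            all(kinds %in% c("LMCV", "QMCV", "LMLV", "QMLV")))
  ## conditional variance must stay positive on eta in [-4, 4]
  psi <- 1 - lambda^2
  if (psi <= 0 || any(!is.finite(exp(beta3 + beta4 * c(-4, 4)))))
    stop("conditional variance not positive and finite on [-4, 4]",
         call. = FALSE)
  structure(list(n = as.integer(n), misspecified = isTRUE(misspecified),
                 m = as.integer(m), lambda = lambda, psi = psi,
                 beta2 = beta2, beta3 = beta3, beta4 = beta4, kinds = kinds),
            class = "study2_config")
}

#' @export
analysis_spec.study2_config <- function(config)
  fa_model_spec(config$m, 1, identification = "unit_factor_variance")

#' @export
true_params.study2_config <- function(config)
  fa_params(numeric(config$m), matrix(config$lambda, config$m, 1),
            matrix(1), rep(config$psi, config$m))

#' Generate data from the one-factor MV-level design
#'
#' @param config A [study2_config()].
#' @param seed Integer seed.
#' @return List with `data`, `eta`, `params` (base linear-normal parameters),
#'   `kinds`, `config`, `seed`.
#' @export
gen_study2 <- function(config, seed = NULL) {
  stopifnot(inherits(config, "study2_config"))
  n <- config$n; m <- config$m
  out <- with_seed(seed, {
    eta <- stats::rnorm(n)
    x <- matrix(0, n, m)
    for (j in seq_len(m)) {
      kind <- config$kinds[j]
      mu <- config$lambda * eta
      if (kind %in% c("QMCV", "QMLV")) mu <- mu + config$beta2 * eta^2
      v <- if (kind %in% c("LMLV", "QMLV"))
        exp(config$beta3 + config$beta4 * eta) else rep(config$psi, n)
      x[, j] <- mu + sqrt(v) * stats::rnorm(n)
    }
    list(eta = eta, x = x)
  })
  list(data = out$x, eta = out$eta, params = true_params(config),
       kinds = config$kinds, config = config, seed = seed)
}

#' Empirical rejection rates across simulation replications
#'
#' For each replication: generate data from the design, fit the analysis
#' model (always the linear normal factor model, never the generating
#' mixture/quadratic truth), run the requested fit tests, and record
#' rejections at level `alpha`. Replication `r` under master seed `seed` uses
#' data seed `seed + 2r` and MC seed `seed + 2r + 1`, so rate tables are
#' invariant to chunking replications across runs. Convergence failures are
#' excluded and tallied; a cell with more than 5% failures is flagged.
#'
#' @param config A [study1_config()] or [study2_config()] (its `n` is the
#'   per-replication sample size).
#' @param tests Character vector among `"lv_density"`, `"mv_linearity"`,
#'   `"mv_homoscedasticity"`, `"mv_direct_mean"`.
#' @param mvs MV indices for the MV-level tests.
#' @param reps Number of replications (>= 50 advised for stable rates).
#' @param s,R,alpha,grid Options passed to the tests.
#' @param seed Master seed.
#' @param rep_offset Index offset for the replication counter, so a run of
#'   `reps = 100` equals two chunked runs with `reps = 50` and
#'   `rep_offset = 0, 50` (parallel chunking yields identical rates).
#' @return Object of class `"rates_table"`: per test (x MV) the overall
#'   rejection proportion, per-grid-point pointwise rejection proportions,
#'   the replication count, failures, and the normal-approximation MC band
#'   around `alpha`.
#' @export
replicate_rates <- function(config, tests = "lv_density", mvs = NULL,
                            reps = 500, s = 2, R = 5000, alpha = 0.05,
                            grid = NULL, seed = 1L, rep_offset = 0L) {
  stopifnot(reps >= 1)
  spec <- analysis_spec(config)
  grid <- grid %||% default_grid(spec$d)
  gen <- if (inherits(config, "study1_config")) gen_study1 else gen_study2
  jobs <- list()
  for (tt in tests) {
    if (tt == "lv_density") jobs[[length(jobs) + 1L]] <- list(type = tt, j = NULL)
    else for (j in (mvs %||% stop("'mvs' needed for MV-level tests")))
      jobs[[length(jobs) + 1L]] <- list(type = tt, j = j)
  }
  job_name <- vapply(jobs, function(jb)
    paste0(jb$type, if (!is.null(jb$j)) paste0(".mv", jb$j)), character(1))
  Q <- nrow(grid$points)
  overall_rej <- matrix(NA, reps, length(jobs),
                        dimnames = list(NULL, job_name))
  point_rej <- array(NA, c(reps, Q, length(jobs)),
                     dimnames = list(NULL, NULL, job_name))
  failures <- 0L
  crit <- stats::qnorm(1 - alpha / 2)
  for (r in seq_len(reps) + rep_offset) {
    ri <- r - rep_offset
    sim <- gen(config, seed = seed + 2L * r)
    fit <- tryCatch(suppressWarnings(fa_fit(sim$data, spec)),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      failures <- failures + 1L
      next
    }
    draws <- fa_simulate(fit$params, R, seed = seed + 2L * r + 1L)
    scores <- fa_score(fit$params, draws, spec)
    for (b in seq_along(jobs)) {
      rep_b <- tryCatch(
        run_gof_test(fit, sim$data, jobs[[b]]$type, j = jobs[[b]]$j,
                     grid = grid, s = s, R = R, draws = draws,
                     scores = scores, alpha = alpha),
        error = function(e) NULL)
      if (is.null(rep_b)) next
      overall_rej[ri, b] <- rep_b$overall$p < alpha
      point_rej[ri, , b] <- ifelse(rep_b$table$usable,
                                  abs(rep_b$table$z) > crit, NA)
    }
  }
  used <- reps - failures
  band <- alpha + c(-1, 1) * crit * sqrt(alpha * (1 - alpha) / max(used, 1))
  res <- lapply(seq_along(jobs), function(b) list(
    test = jobs[[b]]$type, mv = jobs[[b]]$j,
    overall_rate = mean(overall_rej[, b], na.rm = TRUE),
    pointwise_rates = colMeans(point_rej[, , b, drop = FALSE][, , 1],
                               na.rm = TRUE),
    n_reps = sum(!is.na(overall_rej[, b]))))
  names(res) <- job_name
  structure(list(results = res, reps = reps, failures = failures,
                 flagged = failures > 0.05 * reps, band = band,
                 alpha = alpha, grid = grid, config = config,
                 options = list(s = s, R = R, seed = seed)),
            class = "rates_table")
}

#' @export
print.rates_table <- function(x, ...) {
  cat("Empirical rejection rates (", x$reps, "replications,", x$failures,
      "convergence failures", if (x$flagged) "- FLAGGED", ")\n")
  cat("  MC band around alpha:", sprintf("[%.3f, %.3f]", x$band[1],
                                         x$band[2]), "\n")
  for (nm in names(x$results)) {
    r <- x$results[[nm]]
    cat(sprintf("  %-28s overall %.3f (n=%d)\n", nm, r$overall_rate,
                r$n_reps))
  }
  invisible(x)
}

#' Save or replay a simulation manifest
#'
#' `write_sim_manifest()` stores the configuration, seed, and generating
#' parameters of a [gen_study1()]/[gen_study2()] result as JSON;
#' `gen_from_manifest()` regenerates the identical dataset from the file.
#'
#' @param sim Result of [gen_study1()] or [gen_study2()].
#' @param path JSON path.
#' @return `write_sim_manifest()` invisibly returns `path`;
#'   `gen_from_manifest()` returns the regenerated simulation list.
#' @export
write_sim_manifest <- function(sim, path) {
  cfg <- sim$config
  man <- list(study = class(cfg)[1], seed = sim$seed,
              config = unclass(cfg),
              params = list(nu = sim$params$nu,
                            Lambda = sim$params$Lambda,
                            Phi = sim$params$Phi, Psi = sim$params$Psi))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_sim_manifest
#' @export
gen_from_manifest <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (man$study == "study1_config") {
    cfg <- study1_config(n = man$config$n,
                         misspecified = man$config$misspecified,
                         correlation = man$config$Phi[1, 2],
                         communalities = 1 - man$config$Psi,
                         m = man$config$m,
                         mixture = list(
                           weights = man$config$mixture$weights,
                           means = man$config$mixture$means,
                           cov = man$config$mixture$cov))
    gen_study1(cfg, seed = man$seed)
  } else {
    cfg <- study2_config(n = man$config$n,
                         misspecified = man$config$misspecified,
                         m = man$config$m, lambda = man$config$lambda,
                         beta2 = man$config$beta2, beta3 = man$config$beta3,
                         beta4 = man$config$beta4, kinds = man$config$kinds)
    gen_study2(cfg, seed = man$seed)
  }
}
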