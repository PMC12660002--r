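## Unconstrained reparameterization used during optimization: intercepts and
## free loadings raw; psi on the log scale (precluding Heywood cases by
## construction); Phi via atanh-correlations under unit factor variances, or a
## log-Cholesky factor under anchor-loading identification.

u_from_theta <- function(theta, spec) {
  ti <- theta_index(spec)
  u <- theta
  if (length(ti$phi)) {
    if (spec$identification == "unit_factor_variance") {
      u[ti$phi] <- atanh(theta[ti$phi])
    } else {
      Phi <- fa_unpack(theta, spec)$Phi
      L <- t(chol(Phi))
      diag(L) <- log(diag(L))
      u[ti$phi] <- L[lower.tri(L, diag = TRUE)]
    }
  }
  u[ti$psi] <- log(theta[ti$psi])
  u
}

theta_from_u <- function(u, spec) {
  ti <- theta_index(spec)
  theta <- u
  if (length(ti$phi)) {
    if (spec$identification == "unit_factor_variance") {
      theta[ti$phi] <- tanh(u[ti$phi])
    } else {
      d <- spec$d
      L <- matrix(0, d, d)
      L[lower.tri(L, diag = TRUE)] <- u[ti$phi]
      diag(L) <- exp(diag(L))
      Phi <- L %*% t(L)
      theta[ti$phi] <- Phi[ti$phi_pos]
    }
  }
  theta[ti$psi] <- exp(u[ti$psi])
  theta
}

## Jacobian d theta / d u (p x p); diagonal except the anchor-loading Phi block.
jac_theta_u <- function(u, spec) {
  ti <- theta_index(spec)
  J <- diag(1, ti$p)
  if (length(ti$phi)) {
    if (spec$identification == "unit_factor_variance") {
      rho <- tanh(u[ti$phi])
      J[cbind(ti$phi, ti$phi)] <- 1 - rho^2
    } else {
      d <- spec$d
      low <- lower.tri(matrix(0, d, d), diag = TRUE)
      L <- matrix(0, d, d)
      L[low] <- u[ti$phi]
      diag(L) <- exp(diag(L))
      nphi <- length(ti$phi)
      Jb <- matrix(0, nphi, nphi)
      pos <- which(low)
      for (b in seq_len(nphi)) {
        E <- matrix(0, d, d)
        E[pos[b]] <- 1
        rc <- arrayInd(pos[b], c(d, d))
        if (rc[1] == rc[2]) E[pos[b]] <- L[pos[b]]   # log-diagonal chain rule
        dPhi <- E %*% t(L) + L %*% t(E)
        Jb[, b] <- dPhi[ti$phi_pos]
      }
      J[ti$phi, ti$phi] <- Jb
    }
  }
  J[cbind(ti$psi, ti$psi)] <- theta_from_u(u, spec)[ti$psi]
  J
}

## Deterministic principal-component starting values.
start_values <- function(xbar, S, spec) {
  m <- spec$m; d <- spec$d
  Lambda <- matrix(0, m, d)
  for (k in seq_len(d)) {
    jk <- which(spec$pattern[, k] == 1)
    sub <- S[jk, jk, drop = FALSE]
    e <- eigen((sub + t(sub)) / 2, symmetric = TRUE)
    v <- e$vectors[, 1]
    if (sum(v) < 0) v <- -v
    Lambda[jk, k] <- v * sqrt(max(e$values[1], 1e-3))
  }
  Psi <- pmax(diag(S) / 2, 1e-3)
  Phi <- diag(1, d)
  if (spec$identification == "anchor_loading") {
    for (k in seq_len(d)) {
      a <- Lambda[spec$anchor[k], k]
      if (abs(a) < 1e-6) a <- sign(a + .Machine$double.eps) * 1e-6
      Lambda[, k] <- Lambda[, k] / a
      Phi[k, k] <- a^2
    }
    for (k in seq_len(d)) Lambda[spec$anchor[k], k] <- 1
  }
  Lambda[spec$pattern == 0] <- 0
  fa_params(nu = xbar, Lambda = Lambda, Phi = Phi, Psi = Psi, spec = spec)
}

#' Fit a linear normal factor model by maximum likelihood
#'
#' Quasi-Newton optimization on an unconstrained reparameterization (log error
#' variances; atanh-correlations or a log-Cholesky factor for the factor
#' covariance), followed by Fisher-scoring polish. Sufficient statistics are
#' used throughout, so cost is independent of `n` after one pass over the
#' data. Positivity and positive definiteness are enforced by construction, so
#' Heywood cases cannot occur.
#'
#' @param data Numeric `n x m` matrix or data frame, no missing values.
#' @param spec An [fa_model_spec()].
#' @param start Optional [fa_params()] starting values; defaults to a
#'   deterministic principal-component start.
#' @param control List of options: `grad_tol` (max absolute total-score
#'   gradient at convergence, default `1e-5`), `maxit` (BFGS iterations,
#'   default 500), `scoring_maxit` (default 50).
#' @return Object of class `"fa_fit"`: the spec, estimated [fa_params()],
#'   packed `theta`, `loglik`, per-observation expected information `info`,
#'   sample size `n`, convergence flags, and sample moments `xbar`, `S`.
#' @export
#' @examples
#' spec <- fa_model_spec(4, 1)
#' truth <- fa_params(rep(0, 4), matrix(0.8, 4, 1), matrix(1), rep(0.36, 4))
#' x <- fa_simulate(truth, 500, seed = 1)
#' fit <- fa_fit(x, spec)
#' coef(fit)[1:4]
fa_fit <- function(data, spec, start = NULL, control = list()) {
  x <- as.matrix(data)
  storage.mode(x) <- "double"
  if (any(!is.finite(x)))
    stop("data contain missing or non-finite values", call. = FALSE)
  if (ncol(x) != spec$m) stop("data have ", ncol(x), " columns; spec has m = ",
                              spec$m, call. = FALSE)
  n <- nrow(x)
  ctrl <- utils::modifyList(list(grad_tol = 1e-5, maxit = 500L,
                                 scoring_maxit = 50L), control)
  if (n <= spec$npar)
    warning("sample size (", n, ") does not exceed the number of free ",
            "parameters (", spec$npar, ")", call. = FALSE)
  xbar <- colMeans(x)
  xc <- sweep(x, 2L, xbar)
  S <- crossprod(xc) / n
  ev_S <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev_S) < 1e-10 * max(ev_S))
    stop("sample covariance matrix is (near-)singular; the model is not ",
         "identified from these data (e.g., duplicated manifest variables)",
         call. = FALSE)

  if (is.null(start)) start <- start_values(xbar, S, spec)
  u0 <- u_from_theta(fa_pack(start, spec), spec)

  negll <- function(u) {
    th <- theta_from_u(u, spec)
    par <- tryCatch(fa_unpack(th, spec), error = function(e) NULL)
    if (is.null(par)) return(1e10)
    ll <- loglik_suffstat(par, spec, xbar, S, n)$loglik
    if (!is.finite(ll)) 1e10 else -ll
  }
  neggr <- function(u) {
    th <- theta_from_u(u, spec)
    par <- tryCatch(fa_unpack(th, spec), error = function(e) NULL)
    if (is.null(par)) return(numeric(length(u)))
    ls <- loglik_suffstat(par, spec, xbar, S, n)
    if (is.null(ls$grad)) return(numeric(length(u)))
    -as.numeric(crossprod(jac_theta_u(u, spec), ls$grad))
  }
  opt <- stats::optim(u0, negll, neggr, method = "BFGS",
                      control = list(maxit = ctrl$maxit, reltol = 1e-14))
  u <- opt$par
  ## Fisher-scoring polish to drive the gradient below tolerance
  iter <- 0L
  repeat {
    th <- theta_from_u(u, spec)
    par <- fa_unpack(th, spec)
    ls <- loglik_suffstat(par, spec, xbar, S, n)
    J <- jac_theta_u(u, spec)
    g_u <- as.numeric(crossprod(J, ls$grad))
    gmax <- max(abs(g_u))
    if (gmax < ctrl$grad_tol || iter >= ctrl$scoring_maxit) break
    I_nat <- fa_information(par, spec)
    I_u <- crossprod(J, I_nat %*% J) * n
    step <- tryCatch(solve(I_u + diag(1e-8 * max(diag(I_u)), length(u)), g_u),
                     error = function(e) NULL)
    if (is.null(step)) break
    ok <- FALSE
    for (h in 0:12) {
      u_try <- u + step / 2^h
      ll_try <- -negll(u_try)
      if (is.finite(ll_try) && ll_try >= ls$loglik - 1e-10) {
        u <- u_try; ok <- TRUE; break
      }
    }
    if (!ok) break
    iter <- iter + 1L
  }

  th <- theta_from_u(u, spec)
  par <- fa_unpack(th, spec)
  ls <- loglik_suffstat(par, spec, xbar, S, n)
  g_u <- as.numeric(crossprod(jac_theta_u(u, spec), ls$grad))
  info <- fa_information(par, spec)
  ev <- eigen(info, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10 * max(ev))
    stop("expected information is rank deficient: the model specification ",
         "is not identified", call. = FALSE)
  flags <- list(grad_ok = max(abs(g_u)) < ctrl$grad_tol,
                info_pd = min(ev) > 0,
                psi_positive = all(par$Psi > 0))
  fit <- structure(list(spec = spec, params = par, theta = fa_pack(par, spec),
                        loglik = ls$loglik, info = info, n = n,
                        converged = all(unlist(flags)), flags = flags,
                        grad_max = max(abs(g_u)), scoring_iter = iter,
                        xbar = xbar, S = S, fixed_theta = FALSE,
                        call = match.call()),
                   class = "fa_fit")
  if (!fit$converged)
    warning("fit did not satisfy all convergence criteria (max|gradient| = ",
            format(fit$grad_max), ")", call. = FALSE)
  fit
}

#' Wrap known parameters as a fitted model
#'
#' Builds an `"fa_fit"` object around fixed (known) parameter values, for use
#' in population-level checks and fixed-parameter residual diagnostics. The
#' sampling-variability correction in the residual covariance is skipped for
#' such objects.
#'
#' @param params An [fa_params()] object.
#' @param spec The matching [fa_model_spec()].
#' @param n Nominal sample size associated with the object.
#' @return An `"fa_fit"` object with `fixed_theta = TRUE`.
#' @export
fa_fit_known <- function(params, spec, n = 1L) {
  info <- tryCatch(fa_information(params, spec), error = function(e) NULL)
  structure(list(spec = spec, params = params,
                 theta = fa_pack(params, spec),
                 loglik = NA_real_, info = info, n = n, converged = TRUE,
                 flags = list(grad_ok = NA, info_pd = NA, psi_positive = TRUE),
                 grad_max = NA_real_, scoring_iter = 0L,
                 xbar = NULL, S = NULL, fixed_theta = TRUE,
                 call = match.call()),
            class = "fa_fit")
}

#' @export
print.fa_fit <- function(x, ...) {
  cat("Linear normal factor model",
      if (x$fixed_theta) "(fixed parameters)" else "(ML fit)", "\n")
  cat("  m =", x$spec$m, " d =", x$spec$d, " n =", x$n,
      " free parameters =", x$spec$npar, "\n")
  if (!x$fixed_theta) {
    cat("  log-likelihood:", format(x$loglik), "\n")
    cat("  converged:", x$converged,
        " max|gradient| =", format(x$grad_max), "\n")
  }
  invisible(x)
}

#' @export
summary.fa_fit <- function(object, ...) {
  se <- rep(NA_real_, length(object$theta))
  if (!is.null(object$info) && !object$fixed_theta)
    se <- sqrt(diag(solve(object$info)) / object$n)
  tab <- data.frame(estimate = object$theta, se = se,
                    row.names = names(object$theta))
  out <- list(fit = object, table = tab)
  class(out) <- "summary.fa_fit"
  out
}

#' @export
print.summary.fa_fit <- function(x, ...) {
  print(x$fit)
  cat("\nParameter estimates:\n")
  print(round(x$table, 4))
  invisible(x)
}

#' @export
coef.fa_fit <- function(object, ...) object$theta

#' @export
logLik.fa_fit <- function(object, ...) {
  structure(object$loglik, df = object$spec$npar, nobs = object$n,
            class = "logLik")
}

#' @export
vcov.fa_fit <- function(object, ...) {
  if (is.null(object$info)) stop("no information matrix available")
  solve(object$info) / object$n
}

#' @export
simulate.fa_fit <- function(object, nsim = 1, seed = NULL, n = object$n, ...) {
  out <- with_seed(seed, replicate(nsim, fa_simulate(object$params, n),
                                   simplify = FALSE))
  if (nsim == 1) out[[1]] else out
}

#' @export
predict.fa_fit <- function(object, newdata, ...) {
  fa_posterior_moments(object$params, as.matrix(newdata))$mean
}
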