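#' Log-likelihood of a factor model
#'
#' Sum over rows of the multivariate normal log-density with the model-implied
#' marginal moments ([fa_marginal_moments()]).
#'
#' @param params An [fa_params()] object.
#' @param data Numeric `n x m` matrix (or data frame) of manifest variables.
#' @return Scalar log-likelihood.
#' @export
fa_loglik <- function(params, data) {
  x <- as.matrix(data)
  if (any(!is.finite(x))) stop("data must be finite", call. = FALSE)
  mm <- fa_marginal_moments(params)
  sum(dmvn_log(x, mm$mean, mm$cov))
}

#' Per-observation score vectors
#'
#' Gradient of each row's log-density with respect to the packed parameter
#' vector (ordering documented in [fa_pack()]).
#'
#' @inheritParams fa_loglik
#' @param spec The [fa_model_spec()] describing which parameters are free.
#' @return `n x p` matrix of scores; `colSums()` of it is the sample score.
#' @export
fa_score <- function(params, data, spec) {
  x <- as.matrix(data)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  mm <- fa_marginal_moments(params)
  Sinv <- chol2inv(chol(mm$cov))
  dv <- param_derivs(params, spec)
  ti <- dv$ti
  n <- nrow(x)
  Z <- sweep(x, 2L, mm$mean) %*% Sinv           # rows: Sigma^{-1}(x_i - mu)
  sc <- matrix(0, n, ti$p)
  if (spec$mean_structure) sc[, ti$nu] <- Z
  ## covariance-side parameters: s_a = (z' dSigma_a z - tr(Sinv dSigma_a)) / 2
  if (length(ti$lambda)) {
    ZW <- Z %*% dv$LamPhi                       # n x d
    SW <- Sinv %*% dv$LamPhi                    # m x d
    j <- dv$lam_rc[, 1]; k <- dv$lam_rc[, 2]
    sc[, ti$lambda] <- Z[, j, drop = FALSE] * ZW[, k, drop = FALSE] -
      rep(SW[cbind(j, k)], each = n)
  }
  if (length(ti$phi)) {
    ZL <- Z %*% params$Lambda                   # n x d
    LSL <- t(params$Lambda) %*% Sinv %*% params$Lambda
    k <- dv$phi_rc[, 1]; l <- dv$phi_rc[, 2]
    diagf <- ifelse(k == l, 0.5, 1)
    sc[, ti$phi] <- sweep(ZL[, k, drop = FALSE] * ZL[, l, drop = FALSE],
                          2L, LSL[cbind(k, l)]) *
      rep(diagf, each = n)
  }
  sc[, ti$psi] <- 0.5 * sweep(Z^2, 2L, diag(Sinv))
  colnames(sc) <- theta_names(spec)
  sc
}

#' Expected per-observation Fisher information
#'
#' Analytic expected information for the normal marginal model:
#' `I_ab = dmu_a' Sigma^{-1} dmu_b + tr(Sigma^{-1} dSigma_a Sigma^{-1}
#' dSigma_b) / 2`, evaluated with exact parameter-derivative arrays. An MC
#' alternative (`method = "mc"`) estimates the same matrix as the covariance
#' of simulated scores, which is used as an independent identity check.
#'
#' @inheritParams fa_score
#' @param method `"analytic"` (default) or `"mc"`.
#' @param R Number of MC draws when `method = "mc"`.
#' @param seed Seed for the MC draws.
#' @return Symmetric positive-definite `p x p` matrix (per observation).
#' @export
fa_information <- function(params, spec, method = c("analytic", "mc"),
                           R = 1e5, seed = NULL) {
  method <- match.arg(method)
  if (method == "mc") {
    y <- fa_simulate(params, R, seed = seed)
    sc <- fa_score(params, y, spec)
    return(stats::cov(sc) * (R - 1) / R)
  }
  mm <- fa_marginal_moments(params)
  Sinv <- chol2inv(chol(mm$cov))
  dv <- param_derivs(params, spec)
  ti <- dv$ti
  info <- matrix(0, ti$p, ti$p)
  if (spec$mean_structure) info[ti$nu, ti$nu] <- Sinv
  cov_idx <- c(ti$lambda, ti$phi, ti$psi)
  ## dense dSigma for the covariance-side block (p_c small relative to m^2)
  m <- spec$m
  dS <- lapply(cov_idx, function(a) {
    D <- matrix(0, m, m)
    if (a %in% ti$lambda) {
      pos <- match(a, ti$lambda)
      j <- dv$lam_rc[pos, 1]; k <- dv$lam_rc[pos, 2]
      w <- dv$LamPhi[, k]
      D[j, ] <- D[j, ] + w
      D[, j] <- D[, j] + w
    } else if (a %in% ti$phi) {
      pos <- match(a, ti$phi)
      k <- dv$phi_rc[pos, 1]; l <- dv$phi_rc[pos, 2]
      lk <- params$Lambda[, k]; ll <- params$Lambda[, l]
      D <- if (k == l) tcrossprod(lk) else tcrossprod(lk, ll) + tcrossprod(ll, lk)
    } else {
      j <- match(a, ti$psi)
      D[j, j] <- 1
    }
    D
  })
  B <- lapply(dS, function(D) Sinv %*% D)
  nc <- length(cov_idx)
  Vb <- vapply(B, as.numeric, numeric(m * m))        # columns vec(B_a)
  Vbt <- vapply(B, function(b) as.numeric(t(b)), numeric(m * m))
  info[cov_idx, cov_idx] <- 0.5 * crossprod(Vb, Vbt)
  info <- (info + t(info)) / 2
  dimnames(info) <- list(theta_names(spec), theta_names(spec))
  info
}

## Log-likelihood and total-score gradient from sufficient statistics
## (xbar, S = ML covariance about xbar). Used by the fitter so that cost does
## not grow with n. A = Sinv M Sinv - Sinv with M = S + delta delta'.
loglik_suffstat <- function(params, spec, xbar, S, n) {
  mm <- fa_marginal_moments(params)
  ch <- tryCatch(chol(mm$cov), error = function(e) NULL)
  if (is.null(ch)) return(list(loglik = -Inf, grad = NULL))
  Sinv <- chol2inv(ch)
  m <- spec$m
  delta <- xbar - mm$mean
  M <- S + tcrossprod(delta)
  ll <- -0.5 * n * (m * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(Sinv * M))
  A <- Sinv %*% M %*% Sinv - Sinv
  dv <- param_derivs(params, spec)
  g <- 0.5 * n * contract_dsigma((A + t(A)) / 2, params, dv)
  if (spec$mean_structure) g[dv$ti$nu] <- n * as.numeric(Sinv %*% delta)
  list(loglik = ll, grad = g)
}
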