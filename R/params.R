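#' Construct a factor-model parameter set
#'
#' Bundles intercepts `nu`, loadings `Lambda`, factor covariance `Phi`, and
#' error variances `Psi` after validating positive definiteness and the
#' loading pattern implied by `spec` (when given).
#'
#' @param nu Length-`m` intercept vector.
#' @param Lambda `m x d` loading matrix.
#' @param Phi `d x d` symmetric positive-definite factor covariance.
#' @param Psi Length-`m` vector of strictly positive error variances.
#' @param spec Optional [fa_model_spec()]; when given, loadings outside the
#'   pattern must be zero and identification constraints are checked.
#' @return An object of class `"fa_params"`.
#' @export
fa_params <- function(nu, Lambda, Phi, Psi, spec = NULL) {
  Lambda <- as.matrix(Lambda)
  Phi <- as.matrix(Phi)
  m <- length(nu); d <- ncol(Lambda)
  stopifnot(nrow(Lambda) == m, nrow(Phi) == d, ncol(Phi) == d,
            length(Psi) == m)
  if (any(!is.finite(nu)) || any(!is.finite(Lambda)) ||
      any(!is.finite(Phi)) || any(!is.finite(Psi)))
    stop("non-finite parameter values", call. = FALSE)
  if (max(abs(Phi - t(Phi))) > 1e-10)
    stop("'Phi' must be symmetric", call. = FALSE)
  if (min(eigen(Phi, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("'Phi' must be positive definite", call. = FALSE)
  if (any(Psi <= 0))
    stop("'Psi' must be strictly positive", call. = FALSE)
  if (!is.null(spec)) {
    stopifnot(spec$m == m, spec$d == d)
    if (any(Lambda[spec$pattern == 0] != 0))
      stop("loadings outside the pattern must be zero", call. = FALSE)
    if (spec$identification == "unit_factor_variance" &&
        max(abs(diag(Phi) - 1)) > 1e-10)
      stop("diag(Phi) must equal 1 under unit_factor_variance", call. = FALSE)
  }
  structure(list(nu = as.numeric(nu), Lambda = Lambda, Phi = Phi,
                 Psi = as.numeric(Psi)),
            class = "fa_params")
}

#' @export
print.fa_params <- function(x, ...) {
  cat("Factor model parameters (m =", length(x$nu),
      ", d =", ncol(x$Lambda), ")\n")
  cat("nu:\n"); print(round(x$nu, 4))
  cat("Lambda:\n"); print(round(x$Lambda, 4))
  cat("Phi:\n"); print(round(x$Phi, 4))
  cat("Psi:\n"); print(round(x$Psi, 4))
  invisible(x)
}

#' Pack parameters into the free-parameter vector
#'
#' The packed ordering is fixed and documented: intercepts `nu` (when the mean
#' structure is on), free loadings column-major, free lower-triangle entries of
#' `Phi` column-major (excluding the diagonal under unit factor variances),
#' then all `m` error variances. Scores, the expected information, and the
#' residual asymptotic covariance all use this ordering.
#'
#' @param params An [fa_params()] object.
#' @param spec An [fa_model_spec()].
#' @return Numeric vector `theta` of length `spec$npar`.
#' @export
fa_pack <- function(params, spec) {
  ti <- theta_index(spec)
  theta <- numeric(ti$p)
  if (spec$mean_structure) theta[ti$nu] <- params$nu
  theta[ti$lambda] <- params$Lambda[ti$lam_pos]
  theta[ti$phi] <- params$Phi[ti$phi_pos]
  theta[ti$psi] <- params$Psi
  names(theta) <- theta_names(spec)
  theta
}

#' Unpack a free-parameter vector
#'
#' Inverse of [fa_pack()]; fixed loadings are zero (or one at anchor
#' positions), fixed `Phi` diagonal entries are one.
#'
#' @inheritParams fa_pack
#' @param theta Packed parameter vector.
#' @return An [fa_params()] object.
#' @export
fa_unpack <- function(theta, spec) {
  ti <- theta_index(spec)
  stopifnot(length(theta) == ti$p)
  nu <- if (spec$mean_structure) theta[ti$nu] else numeric(spec$m)
  Lambda <- matrix(0, spec$m, spec$d)
  Lambda[ti$lam_pos] <- theta[ti$lambda]
  if (!is.null(spec$anchor))
    for (k in seq_len(spec$d)) Lambda[spec$anchor[k], k] <- 1
  Phi <- diag(1, spec$d)
  Phi[ti$phi_pos] <- theta[ti$phi]
  Phi[upper.tri(Phi)] <- t(Phi)[upper.tri(Phi)]
  fa_params(nu = unname(nu), Lambda = Lambda, Phi = Phi,
            Psi = unname(theta[ti$psi]), spec = spec)
}

theta_names <- function(spec) {
  ti <- theta_index(spec)
  nm <- character(ti$p)
  if (spec$mean_structure) nm[ti$nu] <- paste0("nu", seq_len(spec$m))
  rc <- arrayInd(ti$lam_pos, c(spec$m, spec$d))
  nm[ti$lambda] <- paste0("lambda", rc[, 1], ".", rc[, 2])
  rcp <- arrayInd(ti$phi_pos, c(spec$d, spec$d))
  nm[ti$phi] <- paste0("phi", rcp[, 1], ".", rcp[, 2])
  nm[ti$psi] <- paste0("psi", seq_len(spec$m))
  nm
}

#' Model-implied marginal moments
#'
#' Mean and covariance of the manifest variables implied by the factor model:
#' mean `nu`, covariance `Lambda Phi Lambda' + diag(Psi)`.
#'
#' @param params An [fa_params()] object.
#' @return List with elements `mean` (length `m`) and `cov` (`m x m`).
#' @export
#' @examples
#' p <- fa_params(c(0, 0), matrix(c(1, 0.5), 2, 1), matrix(1), c(0.5, 0.75))
#' fa_marginal_moments(p)
fa_marginal_moments <- function(params) {
  stopifnot(inherits(params, "fa_params"))
  cov <- params$Lambda %*% params$Phi %*% t(params$Lambda) + diag(params$Psi,
                                                                  length(params$Psi))
  list(mean = params$nu, cov = (cov + t(cov)) / 2)
}

## Derivative arrays of the marginal mean and covariance with respect to the
## packed theta (natural parameterization). Returned as a list with, per
## parameter, either a mean basis index or a sparse description of dSigma.
## Everything downstream (score, information, fitting gradient) contracts
## these analytically rather than forming m x m derivative matrices densely.
param_derivs <- function(params, spec) {
  ti <- theta_index(spec)
  m <- spec$m; d <- spec$d
  LamPhi <- params$Lambda %*% params$Phi        # m x d
  lam_rc <- arrayInd(ti$lam_pos, c(m, d))
  phi_rc <- arrayInd(ti$phi_pos, c(d, d))
  list(ti = ti, LamPhi = LamPhi, lam_rc = lam_rc, phi_rc = phi_rc)
}

## Contract sum(A * dSigma_a) for all covariance-side parameters at once.
## A must be symmetric m x m. Returns the full-length gradient contribution
## (zeros on the nu block).
contract_dsigma <- function(A, params, dv) {
  ti <- dv$ti
  g <- numeric(ti$p)
  ## lambda_{jk}: dSigma = e_j w' + w e_j', w = (Lambda Phi)[, k]
  if (length(ti$lambda)) {
    AW <- A %*% dv$LamPhi                        # m x d
    g[ti$lambda] <- 2 * AW[cbind(dv$lam_rc[, 1], dv$lam_rc[, 2])]
  }
  ## phi_{kl}: dSigma = lam_k lam_l' + lam_l lam_k' (k != l), lam_k lam_k' (k = l)
  if (length(ti$phi)) {
    LAL <- t(params$Lambda) %*% A %*% params$Lambda   # d x d
    k <- dv$phi_rc[, 1]; l <- dv$phi_rc[, 2]
    g[ti$phi] <- ifelse(k == l, LAL[cbind(k, k)], 2 * LAL[cbind(k, l)])
  }
  g[ti$psi] <- diag(A)
  g
}
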