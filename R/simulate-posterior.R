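#' Simulate manifest variables from a factor model
#'
#' Draws i.i.d. observations from the marginal normal model implied by
#' `params`. With a `seed` the draw is bit-reproducible and the caller's RNG
#' state is left untouched.
#'
#' @param params An [fa_params()] object.
#' @param n Number of observations.
#' @param seed Optional integer seed.
#' @param return_eta If `TRUE`, the latent draws are attached as attribute
#'   `"eta"` (the draw is then generated as `nu + Lambda eta + e` rather than
#'   from the marginal Cholesky factor).
#' @return `n x m` numeric matrix.
#' @export
fa_simulate <- function(params, n, seed = NULL, return_eta = FALSE) {
  stopifnot(inherits(params, "fa_params"), is_count(n))
  with_seed(seed, {
    if (return_eta) {
      d <- ncol(params$Lambda); m <- length(params$nu)
      eta <- rmvn(n, numeric(d), params$Phi)
      eps <- matrix(stats::rnorm(n * m), n, m) *
        rep(sqrt(params$Psi), each = n)
      x <- sweep(eta %*% t(params$Lambda) + eps, 2L, params$nu, `+`)
      attr(x, "eta") <- eta
      x
    } else {
      mm <- fa_marginal_moments(params)
      rmvn(n, mm$mean, mm$cov)
    }
  })
}

#' Posterior moments of the latent vector
#'
#' Closed-form conditional normal: `Var(eta | x) = (Phi^{-1} +
#' Lambda' Psi^{-1} Lambda)^{-1}` is free of `x`, and `E(eta | x) =
#' Phi Lambda' Sigma^{-1} (x - nu)`.
#'
#' @param params An [fa_params()] object.
#' @param x Optional matrix (rows = observations) or single `m`-vector; when
#'   given, posterior means are returned for each row.
#' @return List with `cov` (`d x d`) and, when `x` is given, `mean`
#'   (`n x d` matrix of posterior means).
#' @export
fa_posterior_moments <- function(params, x = NULL) {
  d <- ncol(params$Lambda)
  Phinv <- chol2inv(chol(params$Phi))
  W <- t(params$Lambda / params$Psi)                  # Lambda' Psi^{-1}, d x m
  V <- chol2inv(chol(Phinv + W %*% params$Lambda))
  V <- (V + t(V)) / 2
  out <- list(cov = V)
  if (!is.null(x)) {
    if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
    out$mean <- sweep(x, 2L, params$nu) %*% t(V %*% W)  # n x d
  }
  out
}

#' Posterior density of the latent vector at fixed grid values
#'
#' Evaluates `f(eta | x)` for every row of `x` and every row of `eta`:
#' the conditional normal density with moments from
#' [fa_posterior_moments()]. This is the summary quantity underlying the
#' latent-density fit test, and (by Bayes' theorem) equals
#' `f(x | eta) f(eta) / f(x)`.
#'
#' @param params An [fa_params()] object.
#' @param x `n x m` matrix (or single `m`-vector) of manifest values.
#' @param eta `Q x d` matrix (or single `d`-vector) of latent values.
#' @return `n x Q` matrix of strictly positive density values.
#' @export
fa_posterior_density <- function(params, x, eta) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (is.null(dim(eta))) eta <- matrix(eta, nrow = 1L)
  pm <- fa_posterior_moments(params, x)
  d <- ncol(eta)
  ch <- chol(pm$cov)
  Vinv <- chol2inv(ch)
  lconst <- -0.5 * d * log(2 * pi) - sum(log(diag(ch)))
  ## log density per (i, q): -(mu_i - eta_q)' Vinv (mu_i - eta_q) / 2 + const
  Mu <- pm$mean                                     # n x d
  qf_mu <- rowSums((Mu %*% Vinv) * Mu)              # n
  qf_eta <- rowSums((eta %*% Vinv) * eta)           # Q
  cross <- Mu %*% Vinv %*% t(eta)                   # n x Q
  exp(lconst - 0.5 * (outer(qf_mu, qf_eta, `+`) - 2 * cross))
}
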