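## Small fixture models and independent oracles, built in code.

## One-factor model with 5 MVs, unit factor variance.
small_spec <- function(m = 5) fa_model_spec(m, 1)

small_params <- function(m = 5) {
  lam <- seq(0.5, 0.9, length.out = m)
  fa_params(nu = seq(-1, 1, length.out = m), Lambda = matrix(lam, m, 1),
            Phi = matrix(1), Psi = 1 - 0.7 * lam^2)
}

## Independent dense multivariate-normal log-density oracle: solve() and
## determinant() per row, no Cholesky sharing with the package internals.
oracle_loglik <- function(params, x) {
  mu <- params$nu
  Sig <- params$Lambda %*% params$Phi %*% t(params$Lambda) +
    diag(params$Psi, length(params$Psi))
  Sinv <- solve(Sig)
  ld <- determinant(Sig, logarithm = TRUE)$modulus
  sum(apply(x, 1L, function(row) {
    d <- row - mu
    -0.5 * (length(mu) * log(2 * pi) + ld + drop(t(d) %*% Sinv %*% d))
  }))
}

## Central finite-difference gradient of scalar f at x.
fd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(a) {
    xp <- x; xm <- x
    xp[a] <- xp[a] + h; xm[a] <- xm[a] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

## Population expected log-likelihood per observation under truth theta0,
## as a function of theta: closed form for the normal model. Its negative
## Hessian at theta0 is the per-observation Fisher information.
expected_loglik_fn <- function(theta0, spec) {
  p0 <- fa_unpack(theta0, spec)
  mu0 <- p0$nu
  Sig0 <- p0$Lambda %*% p0$Phi %*% t(p0$Lambda) + diag(p0$Psi, spec$m)
  function(theta) {
    pp <- fa_unpack(theta, spec)
    Sig <- pp$Lambda %*% pp$Phi %*% t(pp$Lambda) + diag(pp$Psi, spec$m)
    Sinv <- solve(Sig)
    d <- mu0 - pp$nu
    -0.5 * (spec$m * log(2 * pi) +
              determinant(Sig, logarithm = TRUE)$modulus +
              sum(Sinv * Sig0) + drop(t(d) %*% Sinv %*% d))
  }
}

## Central finite-difference Hessian of scalar f at x.
fd_hessian <- function(f, x, h = 1e-4) {
  p <- length(x)
  H <- matrix(0, p, p)
  f0 <- f(x)
  for (a in seq_len(p)) {
    xp <- x; xm <- x
    xp[a] <- xp[a] + h; xm[a] <- xm[a] - h
    H[a, a] <- (f(xp) - 2 * f0 + f(xm)) / h^2
    if (a < p) for (b in (a + 1):p) {
      xpp <- x; xpm <- x; xmp <- x; xmm <- x
      xpp[a] <- xpp[a] + h; xpp[b] <- xpp[b] + h
      xpm[a] <- xpm[a] + h; xpm[b] <- xpm[b] - h
      xmp[a] <- xmp[a] - h; xmp[b] <- xmp[b] + h
      xmm[a] <- xmm[a] - h; xmm[b] <- xmm[b] - h
      H[a, b] <- H[b, a] <- (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h^2)
    }
  }
  H
}
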