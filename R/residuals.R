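#' Transformation specifications for residual vectors
#'
#' A transform maps the `k`-vector of summary averages to the `k*`-vector the
#' fit test is phrased in. `transform_identity()` leaves the summaries
#' untouched (Jacobian = identity); `transform_ratio(Q)` maps a stacked vector
#' `(a_1..a_Q, b_1..b_Q)` to the elementwise ratios `a_q / b_q`, with Jacobian
#' `[diag(1/b), diag(-a/b^2)]`.
#'
#' @param k Length of the summary vector (identity transform).
#' @param Q Number of ratio components (`k = 2Q`).
#' @return A list with elements `g`, `jacobian`, `kind`, `k`, `kstar`.
#' @export
transform_identity <- function(k) {
  list(g = function(v) v,
       jacobian = function(v) diag(1, k),
       kind = "identity", k = k, kstar = k)
}

#' @rdname transform_identity
#' @export
transform_ratio <- function(Q) {
  list(g = function(v) v[seq_len(Q)] / v[Q + seq_len(Q)],
       jacobian = function(v) {
         a <- v[seq_len(Q)]; b <- v[Q + seq_len(Q)]
         cbind(diag(1 / b, Q), diag(-a / b^2, Q))
       },
       kind = "elementwise_ratio", k = 2L * Q, kstar = Q)
}

#' Define a summary-quantity design
#'
#' A design bundles the summary function `e(x; theta)` evaluated rowwise, the
#' transformation applied to its averages, and (optionally) a closed-form
#' model expectation used as the residual's model-implied side.
#'
#' @param eval Function `(X, params) -> n x k` matrix of summary values.
#' @param k Length of the summary vector.
#' @param transform A transform from [transform_identity()] or
#'   [transform_ratio()]; defaults to identity.
#' @param labels Optional character labels (length `k`).
#' @param exact_expectation Optional function `params -> k`-vector giving the
#'   model-implied expectation in closed form. When absent, the Monte-Carlo
#'   mean is used.
#' @return Object of class `"summary_design"`.
#' @export
summary_design <- function(eval, k, transform = NULL, labels = NULL,
                           exact_expectation = NULL) {
  stopifnot(is.function(eval), is_count(k))
  transform <- transform %||% transform_identity(k)
  stopifnot(transform$k == k)
  structure(list(eval = eval, k = as.integer(k), transform = transform,
                 labels = labels %||% paste0("e", seq_len(k)),
                 exact_expectation = exact_expectation),
            class = "summary_design")
}

#' Sample average of a summary vector
#'
#' Mean over the data rows of `e(x_i; theta-hat)`.
#'
#' @param design A [summary_design()].
#' @param data `n x m` data matrix.
#' @param fitted An `"fa_fit"` object.
#' @return Length-`k` numeric vector.
#' @export
sample_average <- function(design, data, fitted) {
  E <- design$eval(as.matrix(data), fitted$params)
  bad <- which(!is.finite(E), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-finite summary value at row ", bad[1, 1], ", component '",
         design$labels[bad[1, 2]], "'", call. = FALSE)
  colMeans(E)
}

#' Monte-Carlo moments of a summary vector
#'
#' Draws `R` observations from the fitted marginal model, evaluates the
#' summary vector and the per-observation scores on each draw, and returns the
#' MC mean `Ehat`, covariance `Sigma`, and score-summary cross-covariance
#' `Cross`. These stand in for the model expectation and (co)variances in the
#' residual asymptotic covariance; MC moments are used (rather than sample
#' moments) because sample-based moment plug-ins inflate Type I error at
#' small `n`.
#'
#' @param design A [summary_design()].
#' @param fitted An `"fa_fit"` object.
#' @param R Number of MC draws (warning when `R < 10 k`).
#' @param seed Seed controlling the draws (reproducible bit-for-bit).
#' @param draws Optional pre-simulated `R x m` matrix (then `seed` is ignored
#'   for data generation).
#' @param scores Optional pre-computed `R x p` score matrix for `draws`.
#' @return Object of class `"mc_moments"` with `Ehat`, `Sigma`, `Cross`
#'   (`p x k`, `NULL` for fixed-parameter fits), `R`, `seed`.
#' @export
mc_moments <- function(design, fitted, R = 50000, seed = NULL,
                       draws = NULL, scores = NULL) {
  stopifnot(is_count(R), R >= 2)
  if (R < 10 * design$k)
    warning("R = ", R, " is small relative to the summary dimension k = ",
            design$k, call. = FALSE)
  Y <- draws %||% fa_simulate(fitted$params, R, seed = seed)
  E <- design$eval(Y, fitted$params)
  Ec <- sweep(E, 2L, colMeans(E))
  Sigma <- crossprod(Ec) / nrow(E)
  Cross <- NULL
  if (!fitted$fixed_theta) {
    sc <- scores %||% fa_score(fitted$params, Y, fitted$spec)
    sc <- sweep(sc, 2L, colMeans(sc))
    Cross <- crossprod(sc, Ec) / nrow(E)
  }
  structure(list(Ehat = colMeans(E), Sigma = (Sigma + t(Sigma)) / 2,
                 Cross = Cross, R = as.integer(nrow(E)), seed = seed),
            class = "mc_moments")
}

#' Transformed residuals and their asymptotic covariance
#'
#' Computes `r = g(ebar) - g(E)` where `ebar` is the sample average and `E`
#' the model-implied expectation (closed form when the design provides one,
#' else the MC mean), together with the estimated asymptotic covariance of
#' `sqrt(n) r`:
#' `Omega = J (Sigma - Cross' I^{-1} Cross) J'`,
#' with `J` the transform Jacobian at `E` and `I` the per-observation expected
#' information. For fixed-parameter fits the information correction is
#' skipped. `Omega` is symmetrized and tiny negative eigenvalues are clipped.
#'
#' @param design A [summary_design()].
#' @param data `n x m` data matrix.
#' @param fitted An `"fa_fit"` object.
#' @param mc An [mc_moments()] object for the same design and fit.
#' @return Object of class `"residual_estimate"`: `r`, `acm`, `n`,
#'   `empirical` (`g(ebar)`), `model` (`g(E)`), `ebar`, `Ehat`.
#' @export
residual_acm <- function(design, data, fitted, mc) {
  ebar <- sample_average(design, data, fitted)
  Ehat <- if (!is.null(design$exact_expectation))
    design$exact_expectation(fitted$params) else mc$Ehat
  inner <- mc$Sigma
  if (!fitted$fixed_theta) {
    if (is.null(mc$Cross) || is.null(fitted$info))
      stop("score cross-covariance or information unavailable for an ",
           "estimated fit", call. = FALSE)
    Iinv <- tryCatch(solve(fitted$info), error = function(e)
      stop("expected information is singular: identification error",
           call. = FALSE))
    inner <- inner - crossprod(mc$Cross, Iinv %*% mc$Cross)
  }
  J <- design$transform$jacobian(Ehat)
  gbar <- design$transform$g(ebar)
  gE <- design$transform$g(Ehat)
  ## negative-eigenvalue tolerance is judged against the scale of the
  ## uncorrected variance: the corrected matrix may legitimately be zero
  ## (e.g., perfectly recovered moments) up to MC noise
  ref <- max(abs(eigen(J %*% mc$Sigma %*% t(J), symmetric = TRUE,
                       only.values = TRUE)$values))
  acm <- psd_project(J %*% inner %*% t(J), label = "residual ACM", ref = ref)
  structure(list(r = gbar - gE, acm = acm, n = nrow(as.matrix(data)),
                 empirical = gbar, model = gE, ebar = ebar, Ehat = Ehat),
            class = "residual_estimate")
}

#' Validate a transform Jacobian by finite differences
#'
#' Compares the design's analytic Jacobian against central finite differences
#' of `g` at random interior points.
#'
#' @param design A [summary_design()].
#' @param points Optional matrix of evaluation points (rows); defaults to 5
#'   random points with entries in (0.5, 2).
#' @param seed Seed for the random points.
#' @return List with `max_deviation` and `pass` (deviation below `1e-4`).
#' @export
check_transform <- function(design, points = NULL, seed = 1L) {
  k <- design$k
  if (is.null(points))
    points <- with_seed(seed, matrix(stats::runif(5 * k, 0.5, 2), 5, k))
  h <- 1e-6
  dev <- 0
  for (i in seq_len(nrow(points))) {
    v <- points[i, ]
    Ja <- design$transform$jacobian(v)
    Jn <- vapply(seq_len(k), function(a) {
      vp <- v; vm <- v
      vp[a] <- vp[a] + h; vm[a] <- vm[a] - h
      (design$transform$g(vp) - design$transform$g(vm)) / (2 * h)
    }, numeric(design$transform$kstar))
    dev <- max(dev, max(abs(Ja - Jn)))
  }
  list(max_deviation = dev, pass = dev <= 1e-4)
}
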