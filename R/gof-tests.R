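#' Evaluation grid of latent values
#'
#' Outer-product grid of evenly spaced per-axis values, with an evenly spaced
#' subgrid on which the overall chi-square statistic is computed. Defaults to
#' 31 points on \[-3, 3\] with an 11-point subgrid for `d = 1`, and 7 points
#' per axis (subgrid = full grid) for `d = 2`.
#'
#' @param d Latent dimension (refused for `d > 3`: the outer-product
#'   construction blows up combinatorially; build the grid manually instead).
#' @param per_axis Number of evenly spaced values per axis (>= 2).
#' @param lo,hi Per-axis range.
#' @param subgrid_per_axis Number of subgrid values per axis (evenly spaced
#'   over `[sub_lo, sub_hi]`, snapped to the nearest axis values); `NULL`
#'   uses the full grid.
#' @param sub_lo,sub_hi Subgrid range (defaults to the full axis range).
#' @return Object of class `"fa_grid"`: `points` (`Q x d`), `axis` (values per
#'   axis), `subgrid` (row indices of `points`), `d`.
#' @export
#' @examples
#' g <- make_grid(1, 31, -3, 3, 11)
#' range(diff(g$points[, 1]))  # spacing 0.2
make_grid <- function(d, per_axis, lo = -3, hi = 3, subgrid_per_axis = NULL,
                      sub_lo = lo, sub_hi = hi) {
  stopifnot(is_count(d), is_count(per_axis), per_axis >= 2, lo < hi)
  if (d > 3)
    stop("outer-product grids are refused for d > 3; supply a manual grid",
         call. = FALSE)
  vals <- seq(lo, hi, length.out = per_axis)
  grids <- rep(list(vals), d)
  pts <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  colnames(pts) <- paste0("eta", seq_len(d))
  if (is.null(subgrid_per_axis)) {
    sub <- seq_len(nrow(pts))
  } else {
    stopifnot(subgrid_per_axis >= 2, subgrid_per_axis <= per_axis)
    target <- seq(sub_lo, sub_hi, length.out = subgrid_per_axis)
    axis_idx <- unique(vapply(target, function(v) which.min(abs(vals - v)),
                              integer(1)))
    idx_grid <- as.matrix(expand.grid(rep(list(seq_len(per_axis)), d)))
    sub <- which(apply(idx_grid, 1L, function(row)
      all(row %in% axis_idx)))
  }
  structure(list(points = pts, axis = vals, subgrid = sub, d = as.integer(d),
                 per_axis = as.integer(per_axis)),
            class = "fa_grid")
}

## Defaults: d = 1 uses 31 points on [-3, 3] with an 11-point subgrid on
## [-2, 2] (extreme latent values make ratio denominators unstable and carry
## negligible probability mass); d = 2 uses the 7 x 7 grid on [-3, 3]^2 with
## the full grid as subgrid.
default_grid <- function(d) {
  if (d == 1L) make_grid(1, 31, -3, 3, 11, sub_lo = -2, sub_hi = 2)
  else if (d == 2L) make_grid(2, 7, -3, 3, NULL)
  else stop("supply a grid for d > 2", call. = FALSE)
}

## Model-implied latent density on the grid (factor means are zero).
lv_density_model <- function(params, pts) {
  as.numeric(exp(dmvn_log(pts, numeric(ncol(pts)), params$Phi)))
}

#' Summary designs for the three worked fit tests
#'
#' Build [summary_design()] objects for latent-density normality
#' (posterior densities at grid points, identity transform), MV-level
#' linearity (`x_j f(eta_q | x)` over `f(eta_q | x)`, ratio transform),
#' MV-level homoscedasticity (squared centered deviation times the posterior
#' density over the posterior density, ratio transform), and the direct
#' (untransformed) conditional-mean variant.
#'
#' @param grid An [make_grid()] grid.
#' @param j Manifest-variable index (MV-level designs).
#' @return A [summary_design()].
#' @export
design_lv_density <- function(grid) {
  Q <- nrow(grid$points)
  summary_design(
    eval = function(X, params) fa_posterior_density(params, X, grid$points),
    k = Q,
    transform = transform_identity(Q),
    labels = paste0("f@", seq_len(Q)),
    exact_expectation = function(params) lv_density_model(params, grid$points))
}

#' @rdname design_lv_density
#' @export
design_mv_linearity <- function(grid, j) {
  Q <- nrow(grid$points)
  summary_design(
    eval = function(X, params) {
      F <- fa_posterior_density(params, X, grid$points)
      cbind(X[, j] * F, F)
    },
    k = 2L * Q,
    transform = transform_ratio(Q),
    labels = c(paste0("a", seq_len(Q)), paste0("b", seq_len(Q))),
    exact_expectation = function(params) {
      f <- lv_density_model(params, grid$points)
      mu <- params$nu[j] + as.numeric(grid$points %*% params$Lambda[j, ])
      c(mu * f, f)
    })
}

#' @rdname design_lv_density
#' @export
design_mv_homoscedasticity <- function(grid, j) {
  Q <- nrow(grid$points)
  summary_design(
    eval = function(X, params) {
      F <- fa_posterior_density(params, X, grid$points)
      mu <- params$nu[j] + as.numeric(grid$points %*% params$Lambda[j, ])
      dev2 <- (matrix(X[, j], nrow(X), Q) -
                 matrix(mu, nrow(X), Q, byrow = TRUE))^2
      cbind(dev2 * F, F)
    },
    k = 2L * Q,
    transform = transform_ratio(Q),
    labels = c(paste0("a", seq_len(Q)), paste0("b", seq_len(Q))),
    exact_expectation = function(params) {
      f <- lv_density_model(params, grid$points)
      c(params$Psi[j] * f, f)
    })
}

#' @rdname design_lv_density
#' @export
design_mv_direct_mean <- function(grid, j) {
  Q <- nrow(grid$points)
  summary_design(
    eval = function(X, params)
      X[, j] * fa_posterior_density(params, X, grid$points),
    k = Q,
    transform = transform_identity(Q),
    labels = paste0("xf@", seq_len(Q)),
    exact_expectation = function(params) {
      f <- lv_density_model(params, grid$points)
      (params$nu[j] + as.numeric(grid$points %*% params$Lambda[j, ])) * f
    })
}

## Core runner shared by the turnkey tests.
run_gof_test <- function(fitted, data, type, j = NULL, grid = NULL,
                         s = 2, R = 50000, seed = NULL, alpha = 0.05,
                         draws = NULL, scores = NULL,
                         denom_floor_frac = 1e-4) {
  stopifnot(inherits(fitted, "fa_fit"))
  if (!isTRUE(fitted$converged))
    stop("fitted model did not converge; refusing to compute fit tests",
         call. = FALSE)
  grid <- grid %||% default_grid(fitted$spec$d)
  design <- switch(type,
    lv_density = design_lv_density(grid),
    mv_linearity = design_mv_linearity(grid, j),
    mv_homoscedasticity = design_mv_homoscedasticity(grid, j),
    mv_direct_mean = design_mv_direct_mean(grid, j))
  data <- as.matrix(data)
  mc <- mc_moments(design, fitted, R = R, seed = seed,
                   draws = draws, scores = scores)
  res <- residual_acm(design, data, fitted, mc)
  Q <- nrow(grid$points)
  f_model <- lv_density_model(fitted$params, grid$points)
  denom_ok <- rep(TRUE, Q)
  if (design$transform$kind == "elementwise_ratio")
    denom_ok <- f_model >= denom_floor_frac * max(f_model)
  zs <- lapply(seq_len(Q), function(q) {
    if (!denom_ok[q])
      return(list(z = NA_real_, se = NA_real_, p = NA_real_, usable = FALSE))
    z_statistic(res$r[q], res$acm[q, q], res$n)
  })
  usable <- denom_ok & vapply(zs, `[[`, logical(1), "usable")
  tab <- data.frame(grid$points,
                    empirical = res$empirical,
                    model_implied = res$model,
                    se = vapply(zs, `[[`, numeric(1), "se"),
                    z = vapply(zs, `[[`, numeric(1), "z"),
                    p = vapply(zs, `[[`, numeric(1), "p"),
                    usable = usable,
                    row.names = NULL)
  sub <- grid$subgrid
  if (any(!denom_ok[sub]))
    stop("subgrid contains unusable grid points (ratio denominator below ",
         "the stability floor); shrink the subgrid", call. = FALSE)
  W <- weight_matrix(res$acm[sub, sub, drop = FALSE], s)
  Tt <- t_statistic(res$r[sub], W, res$n)
  structure(list(type = type, j = j, table = tab,
                 overall = list(T = Tt$T, s = Tt$s, p = Tt$p,
                                eigvals = Tt$eigvals, kept = Tt$kept),
                 residual = res, grid = grid,
                 options = list(s = s, R = mc$R, seed = seed, alpha = alpha,
                                n = res$n, denom_floor_frac = denom_floor_frac)),
            class = "gof_report")
}

#' Fit tests based on generalized residuals
#'
#' Turnkey goodness-of-fit procedures on an evaluation grid of latent values:
#' `lv_density_test()` compares the sample average of posterior densities
#' against the model-implied normal latent density (detecting latent
#' non-normality); `mv_linearity_test()` compares the ratio-estimated
#' conditional mean of MV `j` against the model's linear mean
#' `nu_j + lambda_j' eta`; `mv_homoscedasticity_test()` compares the
#' ratio-estimated conditional variance against the constant `psi_j`;
#' `mv_direct_mean_test()` is the untransformed variant of the linearity test
#' (targeting the conditional mean times the latent density; more sensitive
#' to latent-density misspecification, provided for comparison).
#'
#' Each returns pointwise z-statistics per grid point plus an overall
#' chi-square statistic on the subgrid, using `s` retained eigenvalues of the
#' residual asymptotic covariance. Grid points where the model-implied latent
#' density falls below `1e-4` of its grid maximum are flagged unusable for
#' the ratio-based tests (the ratio denominator is unstable there).
#'
#' @param fitted A converged [fa_fit()] object.
#' @param data The `n x m` data matrix the model was fitted to.
#' @param grid An [make_grid()] grid; defaults to 31 points on \[-3, 3\] with
#'   an 11-point subgrid (`d = 1`) or a 7 x 7 grid (`d = 2`).
#' @param j Manifest-variable index (MV-level tests).
#' @param s Degrees of freedom of the overall statistic (default 2).
#' @param R Number of MC draws for moment estimation (default 50000).
#' @param seed Seed for the MC draws.
#' @param alpha Nominal level echoed into the report.
#' @return Object of class `"gof_report"`: a per-point `table` (grid
#'   coordinates, empirical and model-implied values, `se`, `z`, `p`,
#'   `usable`), an `overall` list (`T`, `s`, `p`), and the options used.
#' @export
lv_density_test <- function(fitted, data, grid = NULL, s = 2, R = 50000,
                            seed = NULL, alpha = 0.05)
  run_gof_test(fitted, data, "lv_density", grid = grid, s = s, R = R,
               seed = seed, alpha = alpha)

#' @rdname lv_density_test
#' @export
mv_linearity_test <- function(fitted, data, j, grid = NULL, s = 2, R = 50000,
                              seed = NULL, alpha = 0.05)
  run_gof_test(fitted, data, "mv_linearity", j = j, grid = grid, s = s,
               R = R, seed = seed, alpha = alpha)

#' @rdname lv_density_test
#' @export
mv_homoscedasticity_test <- function(fitted, data, j, grid = NULL, s = 2,
                                     R = 50000, seed = NULL, alpha = 0.05)
  run_gof_test(fitted, data, "mv_homoscedasticity", j = j, grid = grid,
               s = s, R = R, seed = seed, alpha = alpha)

#' @rdname lv_density_test
#' @export
mv_direct_mean_test <- function(fitted, data, j, grid = NULL, s = 2,
                                R = 50000, seed = NULL, alpha = 0.05)
  run_gof_test(fitted, data, "mv_direct_mean", j = j, grid = grid, s = s,
               R = R, seed = seed, alpha = alpha)

#' @export
print.gof_report <- function(x, ...) {
  lab <- switch(x$type,
                lv_density = "latent-density normality",
                mv_linearity = paste0("conditional-mean linearity (MV ", x$j, ")"),
                mv_homoscedasticity = paste0("homoscedasticity (MV ", x$j, ")"),
                mv_direct_mean = paste0("direct conditional mean (MV ", x$j, ")"))
  cat("Generalized-residual fit test:", lab, "\n")
  cat("  grid points:", nrow(x$table), " usable:", sum(x$table$usable),
      " subgrid:", length(x$grid$subgrid), "\n")
  cat("  overall T =", format(x$overall$T, digits = 4),
      " df =", x$overall$s,
      " p =", format.pval(x$overall$p, digits = 3), "\n")
  nz <- sum(abs(x$table$z) > stats::qnorm(1 - x$options$alpha / 2),
            na.rm = TRUE)
  cat("  pointwise |z| beyond the", 1 - x$options$alpha,
      "critical value at", nz, "of", sum(x$table$usable), "usable points\n")
  invisible(x)
}

#' Plot a fit-test report
#'
#' Draws the model-implied curve (solid), the empirical estimate (dotted),
#' and the pointwise confidence band `empirical +/- z_(1-alpha/2) se`
#' (dashed). A model curve escaping the band marks significant pointwise
#' misfit. For two-dimensional grids a one-dimensional slice is shown along
#' `axis`, holding the other coordinate at the grid value closest to zero.
#' Unusable grid points are left as gaps.
#'
#' @param x A `"gof_report"`.
#' @param axis Axis to plot along for `d = 2` grids.
#' @param alpha Band level (defaults to the report's).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the data frame of plotted values.
#' @export
plot.gof_report <- function(x, axis = 1L, alpha = x$options$alpha, ...) {
  tab <- x$table
  d <- x$grid$d
  if (d > 1L) {
    other <- setdiff(seq_len(d), axis)
    near0 <- x$grid$axis[which.min(abs(x$grid$axis))]
    keep <- rowSums(abs(as.matrix(tab[, other, drop = FALSE]) - near0) <
                      1e-9) == length(other)
    tab <- tab[keep, , drop = FALSE]
  }
  eta <- tab[[axis]]
  crit <- stats::qnorm(1 - alpha / 2)
  lo <- ifelse(tab$usable, tab$empirical - crit * tab$se, NA_real_)
  hi <- ifelse(tab$usable, tab$empirical + crit * tab$se, NA_real_)
  emp <- ifelse(tab$usable, tab$empirical, NA_real_)
  ylim <- range(c(tab$model_implied, lo, hi), na.rm = TRUE)
  ylab <- switch(x$type,
                 lv_density = "latent density",
                 mv_linearity = "conditional mean",
                 mv_direct_mean = "mean x density",
                 mv_homoscedasticity = "conditional variance")
  graphics::plot(eta, tab$model_implied, type = "l", lty = 1, ylim = ylim,
                 xlab = expression(eta), ylab = ylab, ...)
  graphics::lines(eta, emp, lty = 3)
  graphics::lines(eta, lo, lty = 2)
  graphics::lines(eta, hi, lty = 2)
  graphics::legend("topright", lty = c(1, 3, 2), bty = "n", cex = 0.8,
                   legend = c("model-implied", "empirical", "95% band"))
  graphics::mtext(sprintf("T = %.2f, df = %d, p = %.3g", x$overall$T,
                          x$overall$s, x$overall$p), cex = 0.8)
  invisible(data.frame(eta, empirical = emp, model = tab$model_implied,
                       lower = lo, upper = hi))
}

#' Write a fit-test report to disk
#'
#' Writes the per-point table as TSV and an overall summary (test type, T,
#' df, p, options) as JSON, so figures are reproducible from plain text.
#'
#' @param report A `"gof_report"`.
#' @param tsv,json Output paths (either may be `NULL` to skip).
#' @return Invisibly, the report.
#' @export
write_gof_report <- function(report, tsv = NULL, json = NULL) {
  if (!is.null(tsv))
    utils::write.table(report$table, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(
      list(test = report$type, mv = report$j,
           T = report$overall$T, s = report$overall$s, p = report$overall$p,
           options = report$options[c("s", "R", "seed", "alpha", "n")]),
      json, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}
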