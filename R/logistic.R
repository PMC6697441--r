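#' Fit the abundance-reproducibility logistic curve
#'
#' Least-squares fit of the three-parameter logistic
#' \deqn{y_i = \frac{\alpha}{1 + e^{(\beta - x_i)/\gamma}}}
#' where `x` is log10 mean taxon abundance and `y` a per-taxon
#' repeatability (point estimate or CI bound): \eqn{\alpha} is the
#' asymptote, \eqn{\beta} the inflection location in `x` units, and
#' \eqn{\gamma} the steepness at inflection. Fitted by Levenberg-Marquardt
#' least squares from at least five starting triples spanning the data
#' range, keeping the best-RSS convergent fit. The standard error of
#' \eqn{\gamma} comes from the Jacobian-based covariance at the optimum and
#' `t_gamma = gamma / se_gamma` tests whether the curve rises at all.
#'
#' @param x numeric vector (log10 mean abundance), length >= 10.
#' @param y numeric response in \[0, 1\] (repeatability or a CI bound).
#' @param n_starts number of starting triples (>= 5).
#' @return object of class `logistic_curve_fit`: list with `alpha`, `beta`,
#'   `gamma`, `se_alpha`, `se_beta`, `se_gamma`, `t_gamma`, `rss`,
#'   `n_points`, `fitted`.
#' @export
fit_logistic_curve <- function(x, y, n_starts = 7) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 10) stop("need at least 10 points", call. = FALSE)
  df <- data.frame(x = x, y = y)
  qs <- stats::quantile(x, seq(0.15, 0.85, length.out = max(3, n_starts)))
  starts <- data.frame(
    alpha = rep(c(max(y), 0.9 * max(y) + 0.05), length.out = n_starts),
    beta = as.numeric(qs)[seq_len(n_starts)],
    gamma = rep(c(0.1, 0.35, 1), length.out = n_starts))
  best <- NULL
  for (k in seq_len(n_starts)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ alpha / (1 + exp((beta - x) / gamma)),
                        data = df, start = as.list(starts[k, ]),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("logistic fit failed from all starts", call. = FALSE)
  co <- summary(best$fit)$coefficients
  out <- list(alpha = co["alpha", 1], beta = co["beta", 1],
              gamma = co["gamma", 1],
              se_alpha = co["alpha", 2], se_beta = co["beta", 2],
              se_gamma = co["gamma", 2],
              t_gamma = co["gamma", 1] / co["gamma", 2],
              rss = best$rss, n_points = length(x),
              fitted = stats::fitted(best$fit))
  class(out) <- "logistic_curve_fit"
  out
}

#' @export
print.logistic_curve_fit <- function(x, ...) {
  cat(sprintf(
    "logistic curve: alpha = %.4f, beta = %.4f, gamma = %.4f (SE %.4f, t = %.2f); RSS %.4g on %d points\n",
    x$alpha, x$beta, x$gamma, x$se_gamma, x$t_gamma, x$rss, x$n_points))
  invisible(x)
}

#' Abundance-reproducibility curve from per-taxon estimates
#'
#' Given a table of per-taxon repeatability estimates with bootstrap
#' bounds, fits three logistic curves -- one each for the point estimate,
#' lower, and upper CI bound -- against log10 mean abundance. The abundance
#' axis is log10 of the across-library mean rarefied count (zeros included
#' in the mean).
#'
#' @param points data.frame with columns `x` (log10 mean abundance), `y`
#'   (repeatability), and optionally `y_lo`, `y_hi`.
#' @param n_starts passed to [fit_logistic_curve()].
#' @return named list of `logistic_curve_fit` objects (`estimate`, and
#'   where available `lower`, `upper`).
#' @export
abundance_reproducibility_curve <- function(points, n_starts = 7) {
  stopifnot(all(c("x", "y") %in% names(points)))
  out <- list(estimate = fit_logistic_curve(points$x, points$y, n_starts))
  if ("y_lo" %in% names(points))
    out$lower <- fit_logistic_curve(points$x, points$y_lo, n_starts)
  if ("y_hi" %in% names(points))
    out$upper <- fit_logistic_curve(points$x, points$y_hi, n_starts)
  out
}

#' Log10 mean abundance per taxon
#'
#' Across-library mean of (rarefied) counts per taxon, on the log10 scale;
#' zero counts enter the mean.
#'
#' @param table a [count_table()].
#' @return named numeric vector.
#' @export
log10_mean_abundance <- function(table) {
  log10(rowMeans(table$counts))
}
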