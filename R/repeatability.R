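#' One-way variance components from ANOVA mean squares
#'
#' Partitions a univariate metric measured on replicate libraries into
#' among-group (among-fish, biological) and within-group (within-fish,
#' technical) variance components following the classical mean-squares
#' estimator for possibly unbalanced designs:
#' \deqn{n_0 = \frac{N - \sum_i n_i^2 / N}{a - 1},\quad
#'   \hat s^2_W = MS_W,\quad \hat s^2_A = \max(0, (MS_A - MS_W)/n_0)}
#' Negative moment estimates of \eqn{s^2_A} are truncated at zero so that
#' repeatability stays in \[0, 1\]. A REML alternative (one-way random-
#' effects model via \pkg{lme4}) is available with `method = "reml"`; the
#' two coincide for balanced designs.
#'
#' @param values numeric vector of metric values (one per library).
#' @param groups grouping labels (one per value; the fish IDs).
#' @param method `"anova"` (mean squares, default) or `"reml"`.
#' @return object of class `variance_decomposition`: list with `s2_A`,
#'   `s2_W`, `MS_A`, `MS_W`, `n0`, `n_groups`, `n_obs`, `method`, and
#'   `truncated` (TRUE when a negative among-group moment estimate was
#'   clamped to zero).
#' @export
anova_variance_components <- function(values, groups,
                                      method = c("anova", "reml")) {
  method <- match.arg(method)
  groups <- as.factor(as.character(groups))
  if (length(values) != length(groups)) stop("length mismatch", call. = FALSE)
  ok <- is.finite(values)
  values <- values[ok]; groups <- droplevels(groups[ok])
  a <- nlevels(groups); N <- length(values)
  if (a < 2) stop("need at least 2 groups", call. = FALSE)
  n_i <- as.vector(table(groups))
  if (all(n_i < 2))
    stop("within-group variance undefined: all groups are singletons",
         call. = FALSE)
  n0 <- (N - sum(n_i^2) / N) / (a - 1)
  if (method == "reml") {
    fit <- lme4::lmer(values ~ 1 + (1 | groups), REML = TRUE,
                      control = lme4::lmerControl(calc.derivs = FALSE))
    vc <- as.data.frame(lme4::VarCorr(fit))
    s2a <- vc$vcov[vc$grp == "groups"]
    s2w <- vc$vcov[vc$grp == "Residual"]
    out <- list(s2_A = s2a, s2_W = s2w, MS_A = NA_real_, MS_W = NA_real_,
                n0 = n0, n_groups = a, n_obs = N, method = "reml",
                truncated = s2a <= 0)
    class(out) <- "variance_decomposition"
    return(out)
  }
  gm <- mean(values)
  mu_i <- tapply(values, groups, mean)
  ss_a <- sum(n_i * (mu_i - gm)^2)
  ss_w <- sum((values - mu_i[groups])^2)
  MS_A <- ss_a / (a - 1)
  MS_W <- ss_w / (N - a)
  s2a_raw <- (MS_A - MS_W) / n0
  out <- list(s2_A = max(0, s2a_raw), s2_W = MS_W, MS_A = MS_A, MS_W = MS_W,
              n0 = n0, n_groups = a, n_obs = N, method = "anova",
              truncated = s2a_raw < 0)
  class(out) <- "variance_decomposition"
  out
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf(
    "variance decomposition (%s): s2_A = %.6g, s2_W = %.6g (%d groups, %d obs)%s\n",
    x$method, x$s2_A, x$s2_W, x$n_groups, x$n_obs,
    if (isTRUE(x$truncated)) " [among-group component truncated at 0]" else ""))
  invisible(x)
}

#' Repeatability (reproducibility) from variance components
#'
#' \eqn{r = s^2_A / (s^2_A + s^2_W)}: the fraction of total variance
#' attributable to among-host differences. Values near 1 mean technical
#' (within-host) variation is negligible relative to biological variation.
#'
#' @param s2_A among-group variance component (>= 0), or a
#'   `variance_decomposition`.
#' @param s2_W within-group variance component (>= 0).
#' @return repeatability in \[0, 1\].
#' @export
repeatability_from_components <- function(s2_A, s2_W) {
  if (inherits(s2_A, "variance_decomposition")) {
    s2_W <- s2_A$s2_W; s2_A <- s2_A$s2_A
  }
  if (s2_A < 0 || s2_W < 0) stop("components must be >= 0", call. = FALSE)
  if (s2_A + s2_W == 0)
    stop("repeatability undefined: both components are zero", call. = FALSE)
  s2_A / (s2_A + s2_W)
}

#' Variance components from a distance matrix
#'
#' Multivariate analogue of [anova_variance_components()]: sums of squares
#' are computed directly from squared pairwise dissimilarities
#' (\eqn{SS_{tot} = \frac1N \sum_{i<j} d^2_{ij}}, within-group sums over
#' within-group pairs scaled by group size), then converted to components
#' with the same \eqn{n_0}. When `D` holds Euclidean distances of a
#' univariate variable this reproduces the univariate decomposition to
#' machine precision.
#'
#' @param D symmetric dissimilarity matrix with library IDs as dimnames.
#' @param groups grouping labels, either named by library or ordered as
#'   `D`'s rows.
#' @return a `variance_decomposition`.
#' @export
distance_variance_components <- function(D, groups) {
  D <- validate_distance_matrix(D)
  if (!is.null(names(groups))) groups <- groups[rownames(D)]
  groups <- as.factor(as.character(groups))
  a <- nlevels(groups); N <- nrow(D)
  if (a < 2) stop("need at least 2 groups", call. = FALSE)
  n_i <- as.vector(table(groups))
  if (all(n_i < 2))
    stop("within-group variance undefined: all groups are singletons",
         call. = FALSE)
  D2 <- D^2
  ss_tot <- sum(D2[upper.tri(D2)]) / N
  ss_w <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2) next
    sub <- D2[idx, idx, drop = FALSE]
    ss_w <- ss_w + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss_a <- ss_tot - ss_w
  MS_A <- ss_a / (a - 1)
  MS_W <- ss_w / (N - a)
  if (MS_W == 0 && MS_A == 0)
    stop("degenerate distance matrix: no variation among libraries",
         call. = FALSE)
  n0 <- (N - sum(n_i^2) / N) / (a - 1)
  s2a_raw <- (MS_A - MS_W) / n0
  out <- list(s2_A = max(0, s2a_raw), s2_W = MS_W, MS_A = MS_A, MS_W = MS_W,
              n0 = n0, n_groups = a, n_obs = N, method = "distance",
              truncated = s2a_raw < 0)
  class(out) <- "variance_decomposition"
  out
}

#' Bootstrap repeatability with fish-level resampling
#'
#' Resamples whole fish (groups) with replacement, recomputes repeatability
#' per replicate, and reports the 2.5/97.5 percentile interval, following
#' the 500-replicate fish-bootstrap scheme used for the study's Table-1
#' style confidence intervals. A fish drawn twice contributes two distinct
#' groups; in distance mode, dissimilarities between the two copies are
#' read from the original matrix and count as among-group structure.
#' Replicates with undefined repeatability are dropped and counted.
#'
#' @param data numeric vector of metric values (`mode = "univariate"`) or a
#'   symmetric dissimilarity matrix (`mode = "distance"`).
#' @param groups fish labels (one per library).
#' @param n_boot bootstrap replicates (default 500).
#' @param seed RNG seed.
#' @param mode `"univariate"` or `"distance"`.
#' @return object of class `repeatability_estimate`: list with
#'   `decomposition` (full-data), `r`, `ci_low`, `ci_high`, `n_boot`,
#'   `n_dropped`, `seed`, `boot_r`.
#' @export
bootstrap_repeatability <- function(data, groups, n_boot = 500, seed = 1,
                                    mode = c("univariate", "distance")) {
  mode <- match.arg(mode)
  n_boot <- assert_count(n_boot, "n_boot")
  if (mode == "distance") {
    data <- validate_distance_matrix(data)
    if (!is.null(names(groups))) groups <- groups[rownames(data)]
  }
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 3)
    stop("need at least 3 groups to bootstrap", call. = FALSE)
  idx_by_group <- split(seq_along(groups), groups)
  decomp <- if (mode == "univariate")
    anova_variance_components(data, groups)
  else distance_variance_components(data, groups)
  r_hat <- repeatability_from_components(decomp)

  one_rep <- function() {
    picks <- sample(length(idx_by_group), replace = TRUE)
    idx <- unlist(idx_by_group[picks], use.names = FALSE)
    glab <- rep(seq_along(picks), lengths(idx_by_group)[picks])
    tryCatch({
      d <- if (mode == "univariate")
        anova_variance_components(data[idx], glab)
      else distance_variance_components(
        structure(data[idx, idx],
                  dimnames = list(seq_along(idx), seq_along(idx))), glab)
      repeatability_from_components(d)
    }, error = function(e) NA_real_)
  }
  boot_r <- with_seed(seed, vapply(seq_len(n_boot), function(i) one_rep(),
                                   numeric(1)))
  ok <- boot_r[!is.na(boot_r)]
  ci <- if (length(ok)) stats::quantile(ok, c(0.025, 0.975), names = FALSE)
        else c(NA_real_, NA_real_)
  out <- list(decomposition = decomp, r = r_hat,
              ci_low = ci[1], ci_high = ci[2],
              n_boot = n_boot, n_dropped = n_boot - length(ok),
              seed = seed, boot_r = boot_r)
  class(out) <- "repeatability_estimate"
  out
}

#' @export
print.repeatability_estimate <- function(x, ...) {
  cat(sprintf("repeatability r = %.3f (95%% CI %.3f, %.3f; %d bootstrap reps%s)\n",
              x$r, x$ci_low, x$ci_high, x$n_boot,
              if ((x$n_dropped %||% 0) > 0)
                sprintf(", %d dropped", x$n_dropped) else ""))
  invisible(x)
}

#' Per-taxon repeatability from an overdispersed Poisson model
#'
#' Fits the Poisson-lognormal mixed model of [pln_fit()] to one taxon's
#' counts across equal-depth libraries and reports latent-scale
#' repeatability \eqn{r = \sigma^2_A / (\sigma^2_A + \sigma^2_O)}, with a
#' percentile confidence interval from a parametric bootstrap (simulate
#' from the fitted model, refit, take 2.5/97.5 percentiles).
#'
#' @param counts_for_taxon non-negative integer counts, one per library.
#' @param fish_labels fish ID per library.
#' @param n_boot parametric-bootstrap replicates (default 500; 0 skips CI
#'   construction).
#' @param seed RNG seed.
#' @param nodes quadrature nodes (see [pln_loglik()]).
#' @return a `repeatability_estimate` with extra fields `mu`, `sigma2_A`,
#'   `sigma2_O`, `loglik`, `converged`, `boundary`.
#' @export
per_taxon_repeatability <- function(counts_for_taxon, fish_labels,
                                    n_boot = 500, seed = 1, nodes = 20) {
  fish <- as.factor(as.character(fish_labels))
  fit <- pln_fit(counts_for_taxon, fish, nodes = nodes)
  boot_r <- numeric(0)
  n_dropped <- 0L
  if (n_boot > 0) {
    n_i <- as.vector(table(fish))
    boot_r <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
      a <- stats::rnorm(nlevels(fish), 0, sqrt(fit$sigma2_A))
      eta <- fit$mu + a[as.integer(fish)] +
        stats::rnorm(length(fish), 0, sqrt(fit$sigma2_O))
      ystar <- stats::rpois(length(fish), exp(pmin(eta, 30)))
      tryCatch(pln_fit(ystar, fish, nodes = nodes,
                       start = c(fit$mu, 0.5 * log(fit$sigma2_A + 1e-6),
                                 0.5 * log(fit$sigma2_O + 1e-6)))$r,
               error = function(e) NA_real_)
    }, numeric(1)))
    n_dropped <- sum(is.na(boot_r))
    boot_r <- boot_r[!is.na(boot_r)]
  }
  ci <- if (length(boot_r))
    stats::quantile(boot_r, c(0.025, 0.975), names = FALSE)
  else c(NA_real_, NA_real_)
  out <- list(decomposition = NULL, r = fit$r, ci_low = ci[1],
              ci_high = ci[2], n_boot = n_boot, n_dropped = n_dropped,
              seed = seed, boot_r = boot_r,
              mu = fit$mu, sigma2_A = fit$sigma2_A, sigma2_O = fit$sigma2_O,
              loglik = fit$loglik, converged = fit$converged,
              boundary = fit$boundary)
  class(out) <- "repeatability_estimate"
  out
}

#' Repeatability table for several metrics and distance matrices
#'
#' Convenience wrapper producing a Table-1 style summary: one row per
#' univariate metric and per dissimilarity matrix, with variance
#' components, repeatability, and bootstrap confidence interval.
#'
#' @param metrics data.frame of per-library metric values (libraries in
#'   rows, one column per metric), or `NULL`.
#' @param distances named list of dissimilarity matrices, or `NULL`.
#' @param groups fish label per library (aligned with `metrics` rows and
#'   distance-matrix order).
#' @param n_boot,seed bootstrap settings.
#' @return data.frame with columns `metric`, `s2_A`, `s2_W`, `r`,
#'   `ci_low`, `ci_high`, `n_boot`, `seed`.
#' @export
repeatability_table <- function(metrics = NULL, distances = NULL, groups,
                                n_boot = 500, seed = 1) {
  one_row <- function(nm, data, mode) {
    est <- tryCatch(
      bootstrap_repeatability(data, groups, n_boot, seed, mode = mode),
      error = function(e) NULL)
    if (is.null(est)) {
      # degenerate metric (e.g. zero total variance): report as undefined
      warning(sprintf("repeatability undefined for '%s'", nm), call. = FALSE)
      return(data.frame(metric = nm, s2_A = NA_real_, s2_W = NA_real_,
                        r = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                        n_boot = n_boot, seed = seed,
                        stringsAsFactors = FALSE))
    }
    data.frame(metric = nm, s2_A = est$decomposition$s2_A,
               s2_W = est$decomposition$s2_W, r = est$r,
               ci_low = est$ci_low, ci_high = est$ci_high,
               n_boot = n_boot, seed = seed, stringsAsFactors = FALSE)
  }
  rows <- c(lapply(names(metrics), function(nm)
              one_row(nm, metrics[[nm]], "univariate")),
            lapply(names(distances), function(nm)
              one_row(nm, distances[[nm]], "distance")))
  do.call(rbind, rows)
}
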