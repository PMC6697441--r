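# Poisson-lognormal mixed model with a per-fish random intercept and an
# observation-level (overdispersion) random effect:
#
#   y_ij ~ Poisson(exp(mu + a_i + o_ij)),  a_i ~ N(0, s2_A),  o_ij ~ N(0, s2_O)
#
# The marginal likelihood integrates both effects out. Each observation
# contributes a 1-D integral over o (computed by adaptive Gauss-Hermite
# quadrature centred at the conditional mode), and each fish a 1-D integral
# over a of the product of its observations' contributions (again adaptive
# Gauss-Hermite, centred via a grid scan plus quadratic interpolation).

# Gauss-Hermite rule (physicists' weight e^{-x^2}) by Golub-Welsch.
gh_rule <- function(n) {
  if (n == 1) return(list(x = 0, w = sqrt(pi)))
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  eig <- eigen(J, symmetric = TRUE)
  ord <- order(eig$values)
  list(x = eig$values[ord], w = sqrt(pi) * eig$vectors[1, ord]^2)
}

logsumexp_rows <- function(M) {
  m <- apply(M, 1, max)
  m + log(rowSums(exp(M - m)))
}

# log g(y, eta) = log \int Pois(y | e^{eta + o}) N(o | 0, sd_o^2) do,
# vectorised over a matrix Eta (rows = observations, columns = quadrature
# points in a); y is recycled across columns.
pln_inner_log <- function(y, Eta, sd_o, gh) {
  Y <- matrix(y, nrow(Eta), ncol(Eta))
  v <- sd_o^2
  lgam <- matrix(lgamma(y + 1), nrow(Eta), ncol(Eta))
  lognorm_const <- -log(sd_o) - 0.5 * log(2 * pi)
  # Newton for the conditional mode of the integrand in o
  o <- matrix(0, nrow(Eta), ncol(Eta))
  for (it in 1:9) {
    lam <- exp(Eta + o)
    step <- (Y - lam - o / v) / (-lam - 1 / v)
    step[!is.finite(step)] <- 0
    o <- o - pmax(pmin(step, 2), -2)  # damped for large-count stability
  }
  s <- 1 / sqrt(exp(Eta + o) + 1 / v)
  sqs <- sqrt(2) * s
  acc <- vector("list", length(gh$x))
  for (k in seq_along(gh$x)) {
    ok <- o + sqs * gh$x[k]
    eta_k <- Eta + ok
    # Poisson log-pmf and N(0, sd_o) log-density written out for speed
    acc[[k]] <- Y * eta_k - exp(eta_k) - lgam -
      ok * ok / (2 * v) + lognorm_const +
      log(gh$w[k]) + gh$x[k]^2
  }
  M <- Reduce(pmax, acc)
  S <- Reduce(`+`, lapply(acc, function(lf) exp(lf - M)))
  log(sqs) + M + log(S)
}

#' Marginal log-likelihood of the Poisson-lognormal repeatability model
#'
#' Computes \eqn{\sum_i \log \int N(a; 0, \sigma^2_A) \prod_j \int
#' \mathrm{Pois}(y_{ij}; e^{\mu + a + o}) N(o; 0, \sigma^2_O)\, do\, da}
#' by nested adaptive Gauss-Hermite quadrature.
#'
#' @param mu intercept on the log scale.
#' @param sigma2_A among-fish variance (>= 0).
#' @param sigma2_O observation-level (overdispersion) variance (>= 0).
#' @param y non-negative integer counts.
#' @param fish grouping labels, one per count.
#' @param nodes quadrature nodes per 1-D integral (>= 5; default 20).
#' @return scalar log-likelihood.
#' @export
pln_loglik <- function(mu, sigma2_A, sigma2_O, y, fish, nodes = 20) {
  fish <- as.factor(fish)
  gh <- gh_rule(nodes)
  sd_a <- sqrt(max(sigma2_A, 1e-12))
  sd_o <- sqrt(max(sigma2_O, 1e-12))
  fi <- as.integer(fish)
  n_fish <- nlevels(fish)

  # stage 1: locate each fish's posterior mode of a on a shared z-grid
  zg <- seq(-6, 6, length.out = 17)
  Eta <- outer(rep(mu, length(y)), sd_a * zg, `+`)
  lg <- pln_inner_log(y, Eta, sd_o, gh)
  fgrid <- rowsum(lg, fi) +
    matrix(stats::dnorm(sd_a * zg, 0, sd_a, log = TRUE),
           n_fish, length(zg), byrow = TRUE)
  idx <- max.col(fgrid, ties.method = "first")
  idx <- pmin(pmax(idx, 2L), length(zg) - 1L)
  h <- (zg[2] - zg[1]) * sd_a
  f0 <- fgrid[cbind(seq_len(n_fish), idx)]
  fm <- fgrid[cbind(seq_len(n_fish), idx - 1L)]
  fp <- fgrid[cbind(seq_len(n_fish), idx + 1L)]
  curv <- (fm - 2 * f0 + fp) / h^2          # second derivative (<= 0)
  curv <- pmin(curv, -1e-8)
  mode_a <- sd_a * zg[idx] + 0.5 * h * (fm - fp) / (fm - 2 * f0 + fp)
  mode_a[!is.finite(mode_a)] <- sd_a * zg[idx][!is.finite(mode_a)]
  s_i <- 1 / sqrt(-curv)

  # stage 2: adaptive Gauss-Hermite around each fish's mode
  A_nodes <- outer(mode_a, rep(1, nodes)) +
    sqrt(2) * outer(s_i, rep(1, nodes)) *
    matrix(gh$x, n_fish, nodes, byrow = TRUE)
  Eta2 <- mu + A_nodes[fi, , drop = FALSE]
  lg2 <- pln_inner_log(y, Eta2, sd_o, gh)
  L <- rowsum(lg2, fi) + stats::dnorm(A_nodes, 0, sd_a, log = TRUE) +
    matrix(log(gh$w) + gh$x^2, n_fish, nodes, byrow = TRUE) +
    log(sqrt(2)) + log(s_i)
  sum(logsumexp_rows(L))
}

#' Fit the Poisson-lognormal repeatability model
#'
#' Maximises the marginal likelihood of [pln_loglik()] over
#' \eqn{(\mu, \log\sigma_A, \log\sigma_O)} by Nelder-Mead with a
#' moment-based start. Latent-scale repeatability is
#' \eqn{r = \sigma^2_A / (\sigma^2_A + \sigma^2_O)}.
#'
#' @inheritParams pln_loglik
#' @param start optional numeric(3): `mu`, `log(sd_A)`, `log(sd_O)`.
#' @return list with `mu`, `sigma2_A`, `sigma2_O`, `r`, `loglik`,
#'   `converged`, `boundary` (TRUE when a variance is at the lower
#'   optimisation bound), and `trace` (best log-likelihood after each
#'   evaluation; non-decreasing).
#' @export
pln_fit <- function(y, fish, nodes = 20, start = NULL) {
  fish <- as.factor(fish)
  if (any(y < 0) || any(y != floor(y)))
    stop("counts must be non-negative integers", call. = FALSE)
  lm_i <- tapply(y, fish, function(v) log(mean(v) + 0.5))
  if (is.null(start)) {
    start <- c(mean(lm_i), log(max(stats::sd(lm_i), 0.1)), log(0.3))
  }
  best <- -Inf
  trace <- numeric(0)
  obj <- function(par) {
    ls <- pmin(pmax(par[2:3], -7), 3)
    ll <- tryCatch(
      pln_loglik(par[1], exp(2 * ls[1]), exp(2 * ls[2]), y, fish, nodes),
      error = function(e) -Inf)
    if (!is.finite(ll)) ll <- -1e10
    best <<- max(best, ll)
    trace[length(trace) + 1L] <<- best
    -ll
  }
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-9, maxit = 800))
  ls <- pmin(pmax(opt$par[2:3], -7), 3)
  s2a <- exp(2 * ls[1]); s2o <- exp(2 * ls[2])
  list(mu = opt$par[1], sigma2_A = s2a, sigma2_O = s2o,
       r = s2a / (s2a + s2o),
       loglik = -opt$value,
       converged = opt$convergence == 0,
       boundary = any(ls < -6.5),
       trace = trace)
}
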