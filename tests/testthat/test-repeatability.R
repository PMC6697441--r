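test_that("ANOVA variance components match brute-force sums of squares", {
  # zero within-group variance
  vc0 <- anova_variance_components(c(1, 1, 1, 5, 5, 5), rep(c("a", "b"), each = 3))
  expect_equal(vc0$s2_W, 0)
  expect_equal(vc0$MS_W, 0)
  # brute force from definitions on unbalanced toy data
  set.seed(4)
  v <- rnorm(11)
  g <- c(1, 1, 1, 2, 2, 3, 3, 3, 3, 4, 4)
  vc <- anova_variance_components(v, g)
  N <- 11; a <- 4; n_i <- c(3, 2, 4, 2)
  ss_a <- sum(sapply(1:4, function(k)
    n_i[k] * (mean(v[g == k]) - mean(v))^2))
  ss_w <- sum(sapply(1:4, function(k) sum((v[g == k] - mean(v[g == k]))^2)))
  MS_A <- ss_a / (a - 1); MS_W <- ss_w / (N - a)
  n0 <- (N - sum(n_i^2) / N) / (a - 1)
  expect_equal(vc$MS_A, MS_A, tolerance = 1e-12)
  expect_equal(vc$MS_W, MS_W, tolerance = 1e-12)
  expect_equal(vc$n0, n0, tolerance = 1e-12)
  expect_equal(vc$s2_A, max(0, (MS_A - MS_W) / n0), tolerance = 1e-12)
  expect_error(anova_variance_components(1:4, 1:4), "singleton")
})

test_that("balanced-design moment components agree with REML", {
  set.seed(12)
  g <- rep(1:12, each = 4)
  v <- rnorm(12, 0, 2)[g] + rnorm(48)
  vc <- anova_variance_components(v, g)
  reml <- anova_variance_components(v, g, method = "reml")
  # balanced one-way: ANOVA moment estimator is the REML estimator
  # (when the among-group estimate is interior)
  expect_equal(vc$s2_A, reml$s2_A, tolerance = 1e-6)
  expect_equal(vc$s2_W, reml$s2_W, tolerance = 1e-6)
})

test_that("repeatability reproduces the published worked examples", {
  expect_equal(round(repeatability_from_components(77.409, 11.080), 3), 0.875)
  expect_equal(round(repeatability_from_components(6606.324, 123.393), 3),
               0.982)
  expect_equal(round(repeatability_from_components(287.929, 18.949), 3),
               0.938)
  expect_equal(round(repeatability_from_components(0.112, 0.004), 3), 0.966)
  expect_equal(repeatability_from_components(0, 3.7), 0)
  expect_error(repeatability_from_components(0, 0), "undefined")
  # strictly increasing in s2_A; invariant to common rescaling
  r1 <- repeatability_from_components(1, 2)
  expect_gt(repeatability_from_components(1.5, 2), r1)
  expect_equal(repeatability_from_components(10, 20), r1)
})

test_that("distance components on Euclidean matrices equal the univariate ANOVA", {
  set.seed(5)
  for (k in 1:25) {
    n_g <- sample(3:8, 1)
    n_i <- sample(2:5, n_g, replace = TRUE)
    g <- rep(seq_len(n_g), n_i)
    v <- rnorm(sum(n_i), mean = g)
    D <- as.matrix(dist(v))
    dimnames(D) <- list(as.character(seq_along(v)), as.character(seq_along(v)))
    vc_u <- anova_variance_components(v, g)
    vc_d <- distance_variance_components(D, g)
    expect_equal(vc_d$s2_A, vc_u$s2_A, tolerance = 1e-10)
    expect_equal(vc_d$s2_W, vc_u$s2_W, tolerance = 1e-10)
    expect_equal(vc_d$MS_A, vc_u$MS_A, tolerance = 1e-10)
  }
  # degenerate: all libraries identical
  Z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_error(distance_variance_components(Z, c(1, 1, 2, 2)), "degenerate")
  # Table-1 style worked value via the distance route
  expect_equal(round(repeatability_from_components(0.112, 0.004), 3), 0.966)
})

test_that("fish bootstrap gives degenerate and calibrated intervals", {
  # zero within-group variance -> r = 1 with CI (1, 1)
  v <- rep(c(1, 4, 9, 16), each = 3)
  est <- bootstrap_repeatability(v, rep(1:4, each = 3), n_boot = 50, seed = 1)
  expect_equal(est$r, 1)
  expect_equal(c(est$ci_low, est$ci_high), c(1, 1))
  # defaults mirror the study configuration
  expect_identical(formals(bootstrap_repeatability)$n_boot, 500)
  expect_error(bootstrap_repeatability(rnorm(4), c(1, 1, 2, 2)), "3 groups")
  # distance mode on Euclidean data matches univariate mode exactly
  sim <- sim_univariate(0.6, n_groups = 10, seed = 2)
  D <- as.matrix(dist(sim$values))
  dimnames(D) <- list(seq_along(sim$values), seq_along(sim$values))
  eu <- bootstrap_repeatability(sim$values, sim$groups, n_boot = 40, seed = 9)
  ed <- bootstrap_repeatability(D, sim$groups, n_boot = 40, seed = 9,
                                mode = "distance")
  expect_equal(eu$r, ed$r, tolerance = 1e-10)
  expect_equal(eu$boot_r, ed$boot_r, tolerance = 1e-10)
  # CI width shrinks as within-group variance -> 0
  wide <- bootstrap_repeatability(sim_univariate(0.5, seed = 3)$values,
                                  rep(1:35, each = 3), n_boot = 100, seed = 4)
  tight_y <- rep(rnorm(35), each = 3) + rnorm(105, 0, 0.01)
  tight <- bootstrap_repeatability(tight_y, rep(1:35, each = 3),
                                   n_boot = 100, seed = 4)
  expect_lt(tight$ci_high - tight$ci_low, wide$ci_high - wide$ci_low)
})

test_that("the Poisson-lognormal marginal likelihood matches dense integration", {
  oracle <- function(mu, s2a, s2o, y, fish) {
    ag <- seq(-8 * sqrt(s2a), 8 * sqrt(s2a), length.out = 400)
    og <- seq(-8 * sqrt(s2o), 8 * sqrt(s2o), length.out = 400)
    ll <- 0
    for (fsh in unique(fish)) {
      yi <- y[fish == fsh]
      ga <- sapply(ag, function(a) {
        prod(sapply(yi, function(yy) {
          fo <- dpois(yy, exp(mu + a + og)) * dnorm(og, 0, sqrt(s2o))
          sum((fo[-1] + fo[-length(og)]) / 2 * diff(og))
        }))
      })
      fa <- ga * dnorm(ag, 0, sqrt(s2a))
      ll <- ll + log(sum((fa[-1] + fa[-length(ag)]) / 2 * diff(ag)))
    }
    ll
  }
  y <- c(3, 5, 0, 1); fish <- c("a", "a", "b", "b")
  for (par in list(c(1, 0.8, 0.3), c(0.2, 0.05, 0.9), c(2, 1.5, 0.1))) {
    expect_equal(pln_loglik(par[1], par[2], par[3], y, fish),
                 oracle(par[1], par[2], par[3], y, fish), tolerance = 1e-4)
  }
})

test_that("per-taxon repeatability recovers strong and null signals", {
  # biology-dominated: r-hat > 0.9
  sim <- sim_pln_counts(4, 1, 0.01, n_fish = 100, seed = 31)
  est <- per_taxon_repeatability(sim$y, sim$fish, n_boot = 0)
  expect_gt(est$r, 0.9)
  expect_true(est$converged)
  # best log-likelihood is non-decreasing across optimiser evaluations
  fit <- pln_fit(sim$y, sim$fish)
  expect_true(all(diff(fit$trace) >= 0))
  # null: r-hat near 0 (median over a few datasets; single-dataset
  # estimates have sampling spread at 35 fish), CI lower bound near 0
  r0 <- vapply(1:3, function(k) {
    s <- sim_pln_counts(3, 0, 0.4, n_fish = 35, seed = 32 + k)
    per_taxon_repeatability(s$y, s$fish, n_boot = 0)$r
  }, numeric(1))
  expect_lt(median(r0), 0.1)
  sim0 <- sim_pln_counts(3, 0, 0.4, n_fish = 35, seed = 32)
  est0 <- per_taxon_repeatability(sim0$y, sim0$fish, n_boot = 30, seed = 5,
                                  nodes = 12)
  expect_lt(est0$r, 0.3)
  expect_lt(est0$ci_low, 0.1)
  # agreement with the Laplace-based glmer estimator
  sim9 <- sim_pln_counts(3, 1, 0.111, n_fish = 35, seed = 33)
  est9 <- per_taxon_repeatability(sim9$y, sim9$fish, n_boot = 0)
  d <- data.frame(y = sim9$y, fish = factor(sim9$fish),
                  obs = factor(seq_along(sim9$y)))
  g <- suppressWarnings(lme4::glmer(y ~ 1 + (1 | fish) + (1 | obs),
                                    data = d, family = poisson))
  vc <- as.data.frame(lme4::VarCorr(g))
  r_glmer <- vc$vcov[vc$grp == "fish"] /
    (vc$vcov[vc$grp == "fish"] + vc$vcov[vc$grp == "obs"])
  expect_equal(est9$r, r_glmer, tolerance = 0.05)
})

test_that("the logistic curve fit recovers known parameters", {
  x <- seq(-2, 3, length.out = 60)
  y <- 0.9 / (1 + exp((0.5 - x) / 0.35))
  fit <- fit_logistic_curve(x, y)
  expect_equal(fit$alpha, 0.9, tolerance = 1e-4)
  expect_equal(fit$beta, 0.5, tolerance = 1e-4)
  expect_equal(fit$gamma, 0.35, tolerance = 1e-4)
  # fitted values live in (0, alpha)
  expect_true(all(fit$fitted > 0 & fit$fitted <= fit$alpha))
  expect_error(fit_logistic_curve(x[1:5], y[1:5]), "at least 10")
  # three-curve wrapper fits estimate and both CI bounds
  set.seed(2)
  pts <- data.frame(x = x, y = pmin(pmax(y + rnorm(60, 0, 0.03), 0), 1))
  pts$y_lo <- pmax(pts$y - 0.1, 0)
  pts$y_hi <- pmin(pts$y + 0.1, 1)
  fits <- abundance_reproducibility_curve(pts)
  expect_named(fits, c("estimate", "lower", "upper"))
  expect_gt(fits$upper$alpha, fits$lower$alpha)
})

test_that("repeatability_table assembles metric and distance rows", {
  sim <- sim_univariate(0.7, n_groups = 8, seed = 6)
  D <- as.matrix(dist(sim$values))
  dimnames(D) <- list(seq_along(sim$values), seq_along(sim$values))
  tab <- repeatability_table(metrics = data.frame(m1 = sim$values),
                             distances = list(d1 = D),
                             groups = sim$groups, n_boot = 20, seed = 3)
  expect_equal(tab$metric, c("m1", "d1"))
  expect_equal(tab$r[1], tab$r[2], tolerance = 1e-10)  # Euclidean identity
  expect_true(all(tab$ci_low <= tab$ci_high))
})
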