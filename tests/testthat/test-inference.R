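test_that("LRT degrees of freedom follow the factorial design conventions", {
  des <- paper_design()
  set.seed(1)
  y <- rnorm(nrow(des))
  # 3 protocols -> 2 df; 2 populations -> 1 df; interaction -> 2 df
  expect_equal(lmm_lrt_alpha(y, des, "protocol")$df, 2)
  expect_equal(lmm_lrt_alpha(y, des, "population")$df, 1)
  expect_equal(lmm_lrt_alpha(y, des, "interaction")$df, 2)
  # a strong protocol effect is detected
  eff <- c(PCP = 0, PFP = 1.5, DEP = 3)
  y2 <- y + eff[des$protocol]
  tr <- lmm_lrt_alpha(y2, des, "protocol")
  expect_lt(tr$p_value, 1e-6)
  # protocol-free response: the dropped term explains nothing beyond noise
  set.seed(2)
  y3 <- rnorm(36)[as.integer(factor(des$fish_id))] + rnorm(nrow(des), 0, 0.3)
  tr0 <- lmm_lrt_alpha(y3, des, "protocol")
  expect_gte(tr0$statistic, 0)
  expect_gt(tr0$p_value, 0.05)
})

test_that("per-taxon Poisson-lognormal tests report LRT, AIC/BIC and flags", {
  des <- paper_design()
  tab <- sim_null_count_table(des, 3, seed = 7)
  # inject a strong protocol effect into taxon 1
  cnt <- tab$counts
  cnt[1, des$protocol == "DEP"] <- cnt[1, des$protocol == "DEP"] * 4L
  tab <- count_table(cnt)
  res <- pln_taxon_tests(tab, des, "protocol")
  expect_equal(nrow(res), 3)
  expect_true(all(res$converged))
  expect_true(res$flag_strict[1])
  expect_lt(res$p_fdr[1], 0.001)
  # AIC/BIC definitions: dAIC = 2*(k_f - k_r) - LRT is the identity
  # AIC = -2 logL + 2k, so dAIC = LRT - 2*df; BIC analogously with log n
  expect_equal(res$dAIC, res$statistic - 2 * res$df, tolerance = 1e-8)
  expect_equal(res$dBIC, res$statistic - log(nrow(des)) * res$df,
               tolerance = 1e-8)
})

test_that("BH-FDR equals the brute-force step-up procedure", {
  # hand trace: (0.01, 0.02, 0.04, 0.8) at q = 0.1 rejects the first three
  out <- bh_fdr(c(0.01, 0.02, 0.04, 0.8), q = 0.1)
  expect_identical(out$reject, c(TRUE, TRUE, TRUE, FALSE))
  expect_identical(bh_fdr(0.03, 0.1)$adjusted, 0.03)
  expect_false(any(bh_fdr(rep(1, 6), 0.1)$reject))
  # brute force over random p-vectors (<= 12 hypotheses)
  set.seed(8)
  for (k in 1:50) {
    m <- sample(1:12, 1)
    p <- round(runif(m), 3)
    q <- sample(c(0.05, 0.1, 0.2), 1)
    got <- bh_fdr(p, q)
    o <- order(p)
    thresh <- max(c(0, which(p[o] <= seq_len(m) * q / m)))
    reject_bf <- rep(FALSE, m)
    if (thresh > 0) reject_bf[o[seq_len(thresh)]] <- TRUE
    expect_identical(got$reject, reject_bf)
    adj_bf <- sapply(seq_len(m), function(i) {
      r <- rank(p, ties.method = "max")[i]
      min(1, min(sapply(which(rank(p, ties.method = "max") >= r),
                        function(j) m * p[j] / rank(p, ties.method = "max")[j])))
    })
    expect_equal(got$adjusted, adj_bf, tolerance = 1e-12)
    # adjusted p is monotone in p
    expect_true(all(diff(got$adjusted[order(p)]) >= -1e-12))
  }
})

test_that("PERMANOVA on Euclidean scalars equals classical ANOVA", {
  set.seed(9)
  for (k in 1:10) {
    n_g <- sample(3:5, 1)
    n_i <- sample(3:6, n_g, replace = TRUE)
    g <- factor(rep(letters[seq_len(n_g)], n_i))
    v <- rnorm(sum(n_i), as.integer(g) / 2)
    D <- as.matrix(dist(v))
    dimnames(D) <- list(seq_along(v), seq_along(v))
    des <- data.frame(grp = g)
    got <- permanova(D, des, "grp", n_perm = 99, seed = k)
    f_classic <- anova(lm(v ~ g))$`F value`[1]
    expect_equal(got$pseudo_F[1], f_classic, tolerance = 1e-10)
    expect_gte(got$p_value[1], 1 / 100)
  }
  # identical points: p reported as 1
  Z <- matrix(0, 6, 6, dimnames = list(1:6, 1:6))
  res0 <- permanova(Z, data.frame(grp = rep(1:2, 3)), "grp", n_perm = 49)
  expect_equal(res0$p_value, 1)
  # stratified permutations restrict shuffles within blocks and are seeded
  des <- paper_design()
  sim <- simulate_dataset(simulation_config(n_taxa = 15, library_depth = 300,
                                            seed = 13))
  D <- distance_matrix(sim$table, "bray_curtis")
  r1 <- permanova(D, des, c("protocol", "family_id"),
                  strata = des$fish_id, n_perm = 99, seed = 2)
  r2 <- permanova(D, des, c("protocol", "family_id"),
                  strata = des$fish_id, n_perm = 99, seed = 2)
  expect_identical(r1, r2)
  expect_equal(r1$term, c("protocol", "family_id"))
})

test_that("nested PERMANOVA permutes whole families with a discrete p floor", {
  sim <- simulate_dataset(simulation_config(
    n_taxa = 20, library_depth = 500, fish_per_family = 3,
    population_offsets = matrix(c(rep(2, 10), rep(0, 10), rep(0, 10), rep(2, 10)),
                                20, 2, dimnames = list(sprintf("taxon_%04d", 1:20),
                                                       c("pop1", "pop2"))),
    sigma2_A = 0.05, sigma2_W = 0.01, seed = 17))
  D <- distance_matrix(sim$table, "bray_curtis")
  res <- nested_permanova(D, sim$design)
  # 3+3 families: C(6,3) = 20 distinct assignments, enumerated exactly
  expect_true(res$auxiliary$exact)
  expect_equal(res$n_permutations, 20)
  # strong population effect: observed F is the maximum, but label-swap
  # symmetry makes the discrete floor 2/20
  expect_equal(res$p_value, 2 / 20)
  expect_gt(res$statistic, 1)
  # null: no population effect -> p well above the discrete floor on
  # average over datasets
  p0 <- vapply(1:8, function(k) {
    sim0 <- simulate_dataset(simulation_config(
      n_taxa = 20, library_depth = 500, fish_per_family = 3,
      sigma2_A = 0.3, sigma2_W = 0.05, seed = 18 + k))
    nested_permanova(distance_matrix(sim0$table, "bray_curtis"),
                     sim0$design)$p_value
  }, numeric(1))
  expect_gt(mean(p0), 0.2)
  expect_gte(min(p0), 2 / 20)
  expect_error(nested_permanova(D[1:6, 1:6], sim$design[1:6, ]),
               "2 families")
})

test_that("Mantel statistics behave like correlations", {
  set.seed(10)
  v <- rnorm(9)
  D1 <- as.matrix(dist(v)); dimnames(D1) <- list(1:9, 1:9)
  self <- mantel_test(D1, D1, n_perm = 99, seed = 1)
  expect_equal(self$statistic, 1)
  # invariant to positive affine rescaling of one matrix
  D2 <- 3 * D1; diag(D2) <- 0
  expect_equal(mantel_test(D1, D2, n_perm = 99, seed = 1)$statistic, 1)
  # independent matrices: p roughly uniform
  ps <- sapply(1:60, function(k) {
    set.seed(100 + k)
    A <- as.matrix(dist(rnorm(8))); B <- as.matrix(dist(rnorm(8)))
    dimnames(A) <- dimnames(B) <- list(1:8, 1:8)
    mantel_test(A, B, n_perm = 99, seed = k)$p_value
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_gte(min(ps), 1 / 100)
})

test_that("median-based Levene test matches a brute-force F computation", {
  # 2 fish x 3 replicates per protocol-pair toy data
  vals <- c(10, 12, 14, 20, 20, 26, 5, 5, 8, 7, 9, 7)
  fish <- rep(c("f1", "f2", "f3", "f4"), each = 3)
  prot <- rep(c("P1", "P2"), each = 6)
  got <- levene_median(vals, fish, prot)
  dev <- abs(vals - rep(tapply(vals, fish, median), each = 3))
  bf <- anova(lm(dev ~ factor(prot)))
  expect_equal(got$statistic, bf$`F value`[1], tolerance = 1e-12)
  expect_equal(got$p_value, bf$`Pr(>F)`[1], tolerance = 1e-12)
  # all deviations zero -> degenerate, flagged
  degen <- levene_median(rep(c(1, 5), each = 3), rep(c("a", "b"), each = 3),
                         rep(c("x", "y", "z"), 2))
  expect_true(degen$auxiliary$degenerate)
  # equal-spread null holds its size approximately
  set.seed(11)
  ps <- sapply(1:500, function(k) {
    f <- rep(1:6, each = 3)
    p <- rep(c("A", "B", "C"), 6)
    levene_median(rnorm(18, mean = f), f, p)$p_value
  })
  expect_gt(mean(ps < 0.05), 0.02)
  expect_lt(mean(ps < 0.05), 0.09)
})

test_that("centroid distances reproduce Euclidean geometry and stay real", {
  set.seed(12)
  pts <- matrix(rnorm(24), 12, 2)
  g <- rep(c("a", "b", "c"), each = 4)
  D <- as.matrix(dist(pts)); dimnames(D) <- list(1:12, 1:12)
  got <- centroid_distances(D, g)
  direct <- sapply(1:12, function(i) {
    cen <- colMeans(pts[g == g[i], , drop = FALSE])
    sqrt(sum((pts[i, ] - cen)^2))
  })
  expect_equal(as.vector(got), direct, tolerance = 1e-10)
  # identical group members -> zeros
  P0 <- rbind(pts[1:4, ], pts[rep(5, 4), ])
  D0 <- as.matrix(dist(P0)); dimnames(D0) <- list(1:8, 1:8)
  g0 <- rep(c("a", "b"), each = 4)
  expect_equal(unname(centroid_distances(D0, g0)[5:8]), rep(0, 4),
               tolerance = 1e-10)
  # a non-Euclidean matrix (negative PCoA eigenvalue) still yields real,
  # non-negative distances
  Dn <- matrix(c(0, 1, 2, 1,
                 1, 0, 1, 2,
                 2, 1, 0, 1,
                 1, 2, 1, 0), 4, 4, dimnames = list(1:4, 1:4))
  ev <- eigen(-0.5 * scale(scale(Dn^2, scale = FALSE), scale = FALSE))$values
  expect_lt(min(ev), -1e-8)  # genuinely non-Euclidean
  dn <- centroid_distances(Dn, c("a", "a", "b", "b"))
  expect_true(all(is.finite(dn)) && all(dn >= 0))
  # singleton groups are flagged with distance zero
  ds <- centroid_distances(D[1:5, 1:5], c("a", "a", "b", "b", "c"))
  expect_equal(unname(ds[5]), 0)
  expect_identical(attr(ds, "singleton_groups"), "c")
})

test_that("the Feltz-Miller CV test reproduces its formula and worked value", {
  # equal CVs -> statistic 0, p = 1
  eq <- feltz_miller_cv_test(c(0.4, 0.4), c(10, 20))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  # printed comparison: CVs (1.244, 0.527), n = (52, 144)
  fm <- feltz_miller_cv_test(c(1.244, 0.527), c(52, 144))
  expect_equal(fm$statistic, 37.376, tolerance = 0.005)
  expect_equal(fm$df, 1)
  expect_lt(fm$p_value, 1e-8)
  # independent re-evaluation of the formula on random inputs
  set.seed(13)
  for (k in 1:100) {
    ng <- sample(2:5, 1)
    cv <- runif(ng, 0.1, 2)
    n <- sample(5:200, ng, replace = TRUE)
    got <- feltz_miller_cv_test(cv, n)
    kb <- sum((n - 1) * cv) / sum(n - 1)
    dad <- sum((n - 1) * (cv - kb)^2) / (kb^2 * (0.5 + kb^2))
    expect_equal(got$statistic, dad, tolerance = 1e-12)
    expect_equal(got$p_value, pchisq(dad, ng - 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  # data.frame interface computes group CVs and sizes itself
  yy <- simulate_yields(c(3, 3), c(1.0, 0.4), c(60, 80), seed = 21)
  res <- feltz_miller_cv_test(yy)
  expect_lt(res$p_value, 0.05)
})
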