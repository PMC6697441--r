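# Hypothesis-test battery: mixed-model LRTs for alpha diversity,
# Poisson-lognormal per-taxon effect tests with AIC/BIC/FDR, PERMANOVA
# variants on distance matrices, Mantel tests, precision (Levene/dispersion)
# tests, and the Feltz-Miller coefficient-of-variation equality test.

test_result <- function(statistic, df, p_value, method,
                        n_permutations = NA_integer_, auxiliary = list()) {
  out <- list(statistic = statistic, df = df, p_value = p_value,
              method = method, n_permutations = n_permutations,
              auxiliary = auxiliary)
  class(out) <- "test_result"
  out
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n", x$method,
              x$statistic, paste(x$df, collapse = ","), x$p_value))
  invisible(x)
}

lrt_effect_formulas <- function(effect) {
  switch(effect,
    protocol = list(full = ~ protocol + population,
                    reduced = ~ population),
    population = list(full = ~ protocol + population,
                      reduced = ~ protocol),
    interaction = list(full = ~ protocol * population,
                       reduced = ~ protocol + population),
    stop("unknown effect: ", effect, call. = FALSE))
}

#' Mixed-model likelihood ratio test for an alpha-diversity metric
#'
#' Tests the fixed effect of DNA-isolation protocol, host population, or
#' their interaction on a per-library alpha metric using Gaussian linear
#' mixed models with random intercepts for family and fish-within-family.
#' Full and reduced models are fit by maximum likelihood (not REML, as
#' required for fixed-effect LRTs) and compared by \eqn{2\Delta\log L}
#' against a chi-square with df equal to the number of dropped parameters
#' (protocol 2, population 1, interaction 2 in the 3-protocol, 2-population
#' design).
#'
#' @param values numeric metric values, one per design row.
#' @param design a [study_design()].
#' @param effect `"protocol"`, `"population"`, or `"interaction"`.
#' @return a `test_result`; `auxiliary$singular` flags boundary fits.
#' @export
lmm_lrt_alpha <- function(values, design,
                          effect = c("protocol", "population",
                                     "interaction")) {
  effect <- match.arg(effect)
  ff <- lrt_effect_formulas(effect)
  dat <- data.frame(y = values,
                    protocol = factor(design$protocol),
                    population = factor(design$population),
                    family = factor(design$family_id),
                    fish = factor(design$fish_id))
  dat <- dat[is.finite(dat$y), , drop = FALSE]
  fit_one <- function(fixed) {
    f <- stats::update(fixed, y ~ . + (1 | family) + (1 | family:fish))
    suppressMessages(suppressWarnings(
      lme4::lmer(f, data = dat, REML = FALSE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore"))))
  }
  full <- fit_one(ff$full)
  red <- fit_one(ff$reduced)
  df <- length(lme4::fixef(full)) - length(lme4::fixef(red))
  stat <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                        as.numeric(stats::logLik(red))))
  test_result(stat, df, stats::pchisq(stat, df, lower.tail = FALSE),
              method = sprintf("LMM LRT (%s)", effect),
              auxiliary = list(
                singular = lme4::isSingular(full) || lme4::isSingular(red),
                logLik_full = as.numeric(stats::logLik(full)),
                logLik_reduced = as.numeric(stats::logLik(red))))
}

#' Per-taxon Poisson-lognormal effect tests with AIC/BIC and FDR control
#'
#' For each taxon, fits full and reduced Poisson generalized linear mixed
#' models with a log link, random intercepts for family and
#' fish-within-family, and an observation-level random effect capturing
#' overdispersion (the Poisson-lognormal), then compares them by
#' likelihood ratio test. Reports \eqn{\Delta}AIC and \eqn{\Delta}BIC
#' (reduced minus full; positive favours the full model), raw and
#' Benjamini-Hochberg adjusted p-values, and two decision flags: the
#' strict joint rule (\eqn{\Delta}AIC > 2, \eqn{\Delta}BIC > 0, FDR p <
#' 0.1) and the weaker rule (\eqn{\Delta}AIC > 2, \eqn{\Delta}BIC > 0,
#' uncorrected p < 0.05). Pre-filter taxa with [filter_taxa_by_count()]
#' (the 5-counts-in-9-libraries preset) before calling.
#'
#' @param table a [count_table()] of equal-depth libraries.
#' @param design a [study_design()].
#' @param effect `"protocol"`, `"population"`, or `"interaction"`.
#' @param fdr_q FDR level for the strict flag (default 0.1).
#' @return data.frame with one row per taxon (`taxon`, `statistic`, `df`,
#'   `p_value`, `p_fdr`, `dAIC`, `dBIC`, `flag_strict`, `flag_weak`,
#'   `converged`, `note`).
#' @export
pln_taxon_tests <- function(table, design,
                            effect = c("protocol", "population",
                                       "interaction"),
                            fdr_q = 0.1) {
  effect <- match.arg(effect)
  ff <- lrt_effect_formulas(effect)
  design <- design_for(design, table)
  base <- data.frame(protocol = factor(design$protocol),
                     population = factor(design$population),
                     family = factor(design$family_id),
                     fish = factor(design$fish_id),
                     obs = factor(seq_len(nrow(design))))
  fit_one <- function(fixed, dat) {
    f <- stats::update(fixed,
                       y ~ . + (1 | family) + (1 | family:fish) + (1 | obs))
    suppressMessages(suppressWarnings(
      lme4::glmer(f, data = dat, family = stats::poisson(),
                  control = lme4::glmerControl(
                    calc.derivs = FALSE,
                    check.conv.singular = "ignore",
                    check.conv.grad = "ignore",
                    check.conv.hess = "ignore"))))
  }
  rows <- lapply(taxon_ids(table), function(tx) {
    dat <- base
    dat$y <- table$counts[tx, ]
    res <- tryCatch({
      full <- fit_one(ff$full, dat)
      red <- fit_one(ff$reduced, dat)
      ll_f <- as.numeric(stats::logLik(full))
      ll_r <- as.numeric(stats::logLik(red))
      df <- length(lme4::fixef(full)) - length(lme4::fixef(red))
      stat <- max(0, 2 * (ll_f - ll_r))
      data.frame(taxon = tx, statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 dAIC = stats::AIC(red) - stats::AIC(full),
                 dBIC = stats::BIC(red) - stats::BIC(full),
                 converged = TRUE, note = "", stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(taxon = tx, statistic = NA_real_, df = NA_integer_,
                 p_value = NA_real_, dAIC = NA_real_, dBIC = NA_real_,
                 converged = FALSE, note = conditionMessage(e),
                 stringsAsFactors = FALSE))
    res
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- NA_real_
  ok <- !is.na(out$p_value)
  out$p_fdr[ok] <- stats::p.adjust(out$p_value[ok], method = "BH")
  out$flag_strict <- ok & out$dAIC > 2 & out$dBIC > 0 & out$p_fdr < fdr_q
  out$flag_weak <- ok & out$dAIC > 2 & out$dBIC > 0 & out$p_value < 0.05
  out[, c("taxon", "statistic", "df", "p_value", "p_fdr", "dAIC", "dBIC",
          "flag_strict", "flag_weak", "converged", "note")]
}

#' Benjamini-Hochberg FDR adjustment with a rejection set
#'
#' Step-up BH procedure; the rejection set is every hypothesis whose
#' adjusted p-value is at most `q`.
#'
#' @param p_values numeric p-values in \[0, 1\].
#' @param q FDR level (default 0.1).
#' @return list with `adjusted`, `reject` (logical), and `q`.
#' @export
bh_fdr <- function(p_values, q = 0.1) {
  adj <- stats::p.adjust(p_values, method = "BH")
  list(adjusted = adj, reject = !is.na(adj) & adj <= q, q = q)
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance with sequential
#' (Type-I) sums of squares from the Gower-centred inner-product matrix,
#' computed via [vegan::adonis2()]. Factors are tested in the order given
#' (the study's factorial analysis used protocol, family, then their
#' interaction). When `strata` is supplied, permutations are restricted to
#' shuffles within each stratum (e.g. within fish), respecting the
#' repeated-measures structure. Note that in the motivating design family
#' and rearing tank are confounded; a family effect cannot be separated
#' from a tank effect.
#'
#' @param D symmetric dissimilarity matrix.
#' @param design a [study_design()] (or data.frame) with one row per
#'   library, in `D`'s order.
#' @param factors character vector of model terms (columns of `design`,
#'   optionally including interactions like `"protocol:family_id"`).
#' @param strata optional blocking factor (one per library).
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed.
#' @return data.frame with columns `term`, `df`, `SS`, `R2`, `pseudo_F`,
#'   `p_value`, `n_perm`.
#' @export
permanova <- function(D, design, factors, strata = NULL, n_perm = 999,
                      seed = 1) {
  D <- validate_distance_matrix(D)
  dat <- as.data.frame(design)
  if (nrow(dat) != nrow(D)) stop("design/distance size mismatch",
                                 call. = FALSE)
  if (sum(D^2) == 0) {
    return(data.frame(term = factors, df = NA_integer_, SS = 0, R2 = NA_real_,
                      pseudo_F = NA_real_, p_value = 1, n_perm = n_perm,
                      stringsAsFactors = FALSE))
  }
  for (cl in names(dat)) if (is.character(dat[[cl]]))
    dat[[cl]] <- factor(dat[[cl]])
  f <- stats::as.formula(paste("stats::as.dist(D) ~",
                               paste(factors, collapse = " + ")))
  ctrl <- if (is.null(strata))
    permute::how(nperm = n_perm)
  else permute::how(nperm = n_perm, blocks = factor(strata))
  res <- with_seed(seed,
    vegan::adonis2(f, data = dat, permutations = ctrl, by = "terms"))
  terms_idx <- seq_len(nrow(res) - 2)
  data.frame(term = rownames(res)[terms_idx],
             df = res$Df[terms_idx],
             SS = res$SumOfSqs[terms_idx],
             R2 = res$R2[terms_idx],
             pseudo_F = res$F[terms_idx],
             p_value = res$`Pr(>F)`[terms_idx],
             n_perm = n_perm, stringsAsFactors = FALSE)
}

# Within-group sum of squared dissimilarities, scaled by group size.
ss_within_groups <- function(D2, groups) {
  tot <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2) next
    sub <- D2[idx, idx, drop = FALSE]
    tot <- tot + sum(sub[upper.tri(sub)]) / length(idx)
  }
  tot
}

#' Nested PERMANOVA: a between-group factor tested against nested groups
#'
#' Tests a population-level effect on community dissimilarity while
#' treating families (tanks) nested within population as the error
#' stratum: \eqn{F = MS_{population} / MS_{family\,within\,population}},
#' with significance from permuting whole families between populations
#' (keeping each family's libraries together). With two populations of
#' three families each there are only \eqn{\binom{6}{3} = 20} distinct
#' assignments, so the achievable p-value has a discrete floor; exact
#' enumeration is used when feasible (2 populations, <= 12 families)
#' unless `exact = FALSE`.
#'
#' @param D symmetric dissimilarity matrix.
#' @param design design table in `D`'s order with the columns named below.
#' @param between column name of the between-group factor (default
#'   `"population"`).
#' @param nested column name of the nested grouping (default
#'   `"family_id"`).
#' @param n_perm random permutations when not enumerating (default 999).
#' @param seed RNG seed.
#' @param exact force or forbid exhaustive enumeration (`NULL` = auto).
#' @return a `test_result`; `auxiliary` holds the mean squares and the
#'   number of distinct assignments when enumerated.
#' @export
nested_permanova <- function(D, design, between = "population",
                             nested = "family_id", n_perm = 999, seed = 1,
                             exact = NULL) {
  D <- validate_distance_matrix(D)
  pop <- as.character(design[[between]])
  fam <- as.character(design[[nested]])
  fam_pop <- tapply(pop, fam, function(v) v[1])
  fams <- names(fam_pop)
  P <- length(unique(pop)); Fg <- length(fams); N <- nrow(D)
  if (any(table(fam_pop) < 2))
    stop("need at least 2 families per population", call. = FALSE)
  D2 <- D^2
  ss_tot <- sum(D2[upper.tri(D2)]) / N
  f_stat <- function(assign_pop) {
    pop_per_lib <- assign_pop[fam]
    w_pop <- ss_within_groups(D2, pop_per_lib)
    w_fam <- ss_within_groups(D2, fam)
    ms_pop <- (ss_tot - w_pop) / (P - 1)
    ms_fam <- (w_pop - w_fam) / (Fg - P)
    c(F = ms_pop / ms_fam, ms_pop = ms_pop, ms_fam = ms_fam)
  }
  obs <- f_stat(fam_pop)
  do_exact <- exact %||% (P == 2 && Fg <= 12)
  if (do_exact && P == 2) {
    lv <- unique(fam_pop)
    n1 <- sum(fam_pop == lv[1])
    picks <- utils::combn(Fg, n1)
    fs <- apply(picks, 2, function(ix) {
      ap <- stats::setNames(rep(lv[2], Fg), fams)
      ap[fams[ix]] <- lv[1]
      f_stat(ap)["F"]
    })
    p <- mean(fs >= obs["F"] - 1e-12)
    n_used <- ncol(picks)
  } else {
    fs <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      ap <- stats::setNames(sample(unname(fam_pop)), fams)
      f_stat(ap)["F"]
    }, numeric(1)))
    p <- (sum(fs >= obs["F"] - 1e-12) + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  test_result(unname(obs["F"]), c(P - 1, Fg - P), p,
              method = sprintf("nested PERMANOVA (%s / %s)", between, nested),
              n_permutations = n_used,
              auxiliary = list(MS_between = unname(obs["ms_pop"]),
                               MS_nested = unname(obs["ms_fam"]),
                               exact = do_exact))
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal dissimilarities (via
#' [vegan::mantel()]), with significance from jointly permuting one
#' matrix's rows and columns. Matrices are aligned on their shared IDs
#' (e.g. fish-level matrices computed separately per protocol).
#'
#' @param D1,D2 symmetric dissimilarity matrices with matching ID sets.
#' @param n_perm permutations (default 999).
#' @param seed RNG seed.
#' @return a `test_result` with `statistic` = Mantel r.
#' @export
mantel_test <- function(D1, D2, n_perm = 999, seed = 1) {
  D1 <- validate_distance_matrix(D1)
  D2 <- validate_distance_matrix(D2)
  ids <- intersect(rownames(D1), rownames(D2))
  if (length(ids) < 3) stop("fewer than 3 shared IDs", call. = FALSE)
  res <- with_seed(seed,
    vegan::mantel(stats::as.dist(D1[ids, ids]),
                  stats::as.dist(D2[ids, ids]),
                  method = "pearson", permutations = n_perm))
  test_result(res$statistic, NA_integer_, res$signif,
              method = "Mantel test", n_permutations = n_perm)
}

#' Median-based Levene test across protocols
#'
#' Tests whether measurement spread differs among protocols: each
#' observation is reduced to its absolute deviation from the median of its
#' own group (fish gut), and the deviations are compared across protocol
#' levels by one-way ANOVA.
#'
#' @param values numeric metric values.
#' @param groups group labels defining the medians (the fish).
#' @param compare factor whose levels are compared (the protocols).
#' @return a `test_result` with the ANOVA F statistic and (df1, df2).
#' @export
levene_median <- function(values, groups, compare) {
  groups <- as.factor(as.character(groups))
  compare <- as.factor(as.character(compare))
  med <- tapply(values, groups, stats::median)
  dev <- abs(values - med[groups])
  if (all(dev == 0))
    return(test_result(NA_real_, c(nlevels(compare) - 1,
                                   length(values) - nlevels(compare)),
                       NA_real_, method = "Levene (median) test",
                       auxiliary = list(degenerate = TRUE)))
  an <- stats::anova(stats::lm(dev ~ compare))
  test_result(an$`F value`[1], c(an$Df[1], an$Df[2]), an$`Pr(>F)`[1],
              method = "Levene (median) test",
              auxiliary = list(mean_abs_deviation =
                                 tapply(dev, compare, mean)))
}

#' Distances from observations to their group centroid in PCoA space
#'
#' Embeds the dissimilarity matrix by principal-coordinates analysis,
#' keeping negative-eigenvalue (imaginary) axes separately, and returns
#' each library's distance to its group centroid, computed as the square
#' root of (real-part squared distance minus imaginary-part squared
#' distance), truncated at zero -- the standard multivariate-dispersion
#' construction (via [vegan::betadisper()]). Used as the response in
#' beta-diversity precision tests.
#'
#' @param D symmetric dissimilarity matrix.
#' @param groups group (fish) label per library.
#' @return named numeric vector of distances, with attribute
#'   `singleton_groups` listing groups of size 1 (their distance is a
#'   degenerate 0).
#' @export
centroid_distances <- function(D, groups) {
  D <- validate_distance_matrix(D)
  if (!is.null(names(groups))) groups <- groups[rownames(D)]
  groups <- factor(as.character(groups), levels = unique(as.character(groups)))
  bd <- vegan::betadisper(stats::as.dist(D), groups, type = "centroid")
  out <- stats::setNames(as.numeric(bd$distances), rownames(D))
  singles <- names(which(table(groups) == 1))
  out[groups %in% singles] <- 0
  attr(out, "singleton_groups") <- singles
  out
}

#' Feltz-Miller asymptotic test for equality of coefficients of variation
#'
#' \deqn{\bar k = \frac{\sum_i (n_i - 1) k_i}{\sum_i (n_i - 1)}, \qquad
#'   D'AD = \frac{\sum_i (n_i - 1)(k_i - \bar k)^2}
#'               {\bar k^2 (0.5 + \bar k^2)}}
#' referred to a chi-square with (number of groups - 1) degrees of
#' freedom.
#'
#' @param cvs per-group coefficients of variation (> 0), or a data.frame
#'   with columns `group` and `yield` from which group CVs and sizes are
#'   computed.
#' @param ns per-group sample sizes (each >= 2); ignored when `cvs` is a
#'   data.frame.
#' @return a `test_result`.
#' @export
feltz_miller_cv_test <- function(cvs, ns = NULL) {
  if (is.data.frame(cvs)) {
    stopifnot(all(c("group", "yield") %in% names(cvs)))
    ns <- as.vector(table(cvs$group))
    cvs <- as.vector(tapply(cvs$yield, cvs$group,
                            function(v) stats::sd(v) / mean(v)))
  }
  if (length(cvs) < 2 || length(cvs) != length(ns))
    stop("need CVs and sample sizes for >= 2 groups", call. = FALSE)
  if (any(ns < 2)) stop("each group needs n >= 2", call. = FALSE)
  if (any(cvs <= 0)) stop("CVs must be positive", call. = FALSE)
  w <- ns - 1
  kbar <- sum(w * cvs) / sum(w)
  dad <- sum(w * (cvs - kbar)^2) / (kbar^2 * (0.5 + kbar^2))
  df <- length(cvs) - 1
  test_result(dad, df, stats::pchisq(dad, df, lower.tail = FALSE),
              method = "Feltz-Miller CV equality test",
              auxiliary = list(pooled_cv = kbar))
}
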