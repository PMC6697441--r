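#' Configuration for the synthetic microbiome study generator
#'
#' Describes a nested host-microbiome sampling design with known variance
#' structure: populations of full-sib families, fish (host individuals)
#' within families, and replicate libraries within fish (one per
#' DNA-isolation protocol). Per taxon `t`, fish `i`, replicate `j`, the
#' latent log intensity is
#' \deqn{\log\lambda_{tij} = b_t + \mathrm{offsets} + a_{ti} + e_{tij}}
#' with \eqn{a_{ti} \sim N(0, \sigma^2_A)} (among-fish, biological) and
#' \eqn{e_{tij} \sim N(0, \sigma^2_W)} (within-fish, technical). Library
#' counts are a single multinomial draw of `library_depth` reads with
#' probabilities proportional to \eqn{\lambda_{tij}}, so compositional
#' closure happens at the sequencing step and column totals are fixed,
#' mirroring libraries downsampled to a common depth.
#'
#' Defaults mirror the reproducibility experiment that motivated the
#' package: 2 populations x 3 full-sib families x 6 fish x 3 protocol
#' replicates (108 libraries), libraries at 105,000 reads.
#'
#' @param n_populations,families_per_population,fish_per_family,replicates_per_fish
#'   design sizes (all >= 1).
#' @param n_taxa number of taxa (>= 1).
#' @param library_depth reads per library (>= 1).
#' @param sigma2_A among-fish variance of taxon log-intensity (natural-log
#'   scale).
#' @param sigma2_W within-fish (replicate-level) variance on the same scale.
#' @param baseline_logabundance_spread SD of baseline taxon log abundances;
#'   baselines are drawn Normal(0, spread^2) and rank-sorted, giving a
#'   lognormal rank-abundance curve with a rare-taxon tail.
#' @param protocol_offsets optional taxa x protocols matrix (or named list of
#'   per-taxon vectors) of additive log effects; simulates protocol bias.
#' @param population_offsets optional taxa x populations matrix of additive
#'   log effects; simulates true population divergence.
#' @param n_classes number of class-level taxonomy groups taxa are assigned
#'   to (for aggregation exercises).
#' @param seed RNG seed; identical configs produce identical datasets.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_populations = 2,
                              families_per_population = 3,
                              fish_per_family = 6,
                              replicates_per_fish = 3,
                              n_taxa = 2000,
                              library_depth = 105000,
                              sigma2_A = 0.5,
                              sigma2_W = 0.05,
                              baseline_logabundance_spread = 2,
                              protocol_offsets = NULL,
                              population_offsets = NULL,
                              n_classes = 15,
                              seed = 1) {
  cfg <- list(
    n_populations = assert_count(n_populations, "n_populations"),
    families_per_population = assert_count(families_per_population,
                                           "families_per_population"),
    fish_per_family = assert_count(fish_per_family, "fish_per_family"),
    replicates_per_fish = assert_count(replicates_per_fish,
                                       "replicates_per_fish"),
    n_taxa = assert_count(n_taxa, "n_taxa"),
    library_depth = assert_count(library_depth, "library_depth"),
    sigma2_A = assert_nonneg(sigma2_A, "sigma2_A"),
    sigma2_W = assert_nonneg(sigma2_W, "sigma2_W"),
    baseline_logabundance_spread =
      assert_nonneg(baseline_logabundance_spread,
                    "baseline_logabundance_spread"),
    protocol_offsets = protocol_offsets,
    population_offsets = population_offsets,
    n_classes = assert_count(n_classes, "n_classes"),
    seed = seed)
  for (nm in c("protocol_offsets", "population_offsets"))
    if (!is.null(cfg[[nm]]) && any(!is.finite(as.matrix(cfg[[nm]]))))
      stop(sprintf("`%s` must be finite", nm), call. = FALSE)
  class(cfg) <- "simulation_config"
  cfg
}

protocol_names <- function(k) {
  if (k == 3) c("PCP", "PFP", "DEP") else sprintf("P%02d", seq_len(k))
}

#' Simulate a full study dataset with known ground truth
#'
#' Generates a count table, study design, and random phylogeny under the
#' generative model described in [simulation_config()]. The retained latent
#' effects (baselines, fish effects, replicate effects, and the full
#' log-intensity array) are returned so that recovery tests can compare
#' estimates against truth without re-deriving it from counts.
#'
#' @param config a [simulation_config()].
#' @return list with elements `table` ([count_table()]), `design`
#'   ([study_design()]), `tree` (`phylo`), and `latents` (list of `b`
#'   (taxa), `a` (taxa x fish), `e` (taxa x libraries), `log_lambda`
#'   (taxa x libraries)).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  n_fish <- cfg$n_populations * cfg$families_per_population *
    cfg$fish_per_family
  n_lib <- n_fish * cfg$replicates_per_fish
  if (cfg$n_taxa < 1 || n_fish < 1)
    stop("configuration yields zero taxa or zero fish", call. = FALSE)

  taxa <- sprintf("taxon_%04d", seq_len(cfg$n_taxa))
  prots <- protocol_names(cfg$replicates_per_fish)
  pops <- sprintf("pop%d", seq_len(cfg$n_populations))

  design <- expand.grid(replicate = seq_len(cfg$replicates_per_fish),
                        fish_in_family = seq_len(cfg$fish_per_family),
                        family_in_pop = seq_len(cfg$families_per_population),
                        pop = seq_len(cfg$n_populations))
  design <- data.frame(
    library_id = sprintf("lib_%03d", seq_len(n_lib)),
    fish_id = sprintf("fish_%03d",
                      (design$pop - 1) * cfg$families_per_population *
                        cfg$fish_per_family +
                        (design$family_in_pop - 1) * cfg$fish_per_family +
                        design$fish_in_family),
    family_id = sprintf("family_%02d",
                        (design$pop - 1) * cfg$families_per_population +
                          design$family_in_pop),
    population = pops[design$pop],
    protocol = prots[design$replicate],
    experiment = "reproducibility",
    stringsAsFactors = FALSE)
  fish_ids <- unique(design$fish_id)

  with_seed(cfg$seed, {
    # lognormal rank-abundance baseline: draw, then sort so taxon_0001 is
    # the most abundant -- gives a realistic rare tail
    b <- sort(stats::rnorm(cfg$n_taxa, 0, cfg$baseline_logabundance_spread),
              decreasing = TRUE)
    names(b) <- taxa
    a <- matrix(stats::rnorm(cfg$n_taxa * n_fish, 0, sqrt(cfg$sigma2_A)),
                cfg$n_taxa, n_fish, dimnames = list(taxa, fish_ids))
    e <- matrix(stats::rnorm(cfg$n_taxa * n_lib, 0, sqrt(cfg$sigma2_W)),
                cfg$n_taxa, n_lib, dimnames = list(taxa, design$library_id))

    log_lambda <- b + a[, design$fish_id, drop = FALSE] + e
    colnames(log_lambda) <- design$library_id
    log_lambda <- log_lambda +
      offset_matrix(cfg$protocol_offsets, taxa, design$protocol) +
      offset_matrix(cfg$population_offsets, taxa, design$population)

    counts <- vapply(seq_len(n_lib), function(j) {
      lam <- exp(log_lambda[, j] - max(log_lambda[, j]))
      drop(stats::rmultinom(1, cfg$library_depth, lam / sum(lam)))
    }, numeric(cfg$n_taxa))
    counts <- matrix(counts, nrow = cfg$n_taxa,
                     dimnames = list(taxa, design$library_id))

    tree <- simulate_random_phylogeny(cfg$n_taxa, seed = NULL, labels = taxa)
    taxonomy <- simulate_taxonomy(taxa, cfg$n_classes)
  })

  list(table = count_table(counts, taxonomy = taxonomy),
       design = study_design(design),
       tree = tree,
       latents = list(b = b, a = a, e = e, log_lambda = log_lambda))
}

# Expand optional taxa x level offset specification to taxa x libraries.
offset_matrix <- function(off, taxa, level_per_library) {
  n <- length(level_per_library)
  if (is.null(off)) return(matrix(0, length(taxa), n))
  off <- as.matrix(as.data.frame(off))
  if (is.null(rownames(off))) rownames(off) <- taxa[seq_len(nrow(off))]
  full <- matrix(0, length(taxa), ncol(off),
                 dimnames = list(taxa, colnames(off)))
  full[rownames(off), ] <- off
  lev <- level_per_library
  out <- matrix(0, length(taxa), n)
  known <- lev %in% colnames(full)
  out[, known] <- full[, lev[known], drop = FALSE]
  out
}

# Random but seed-stable taxonomy: taxa assigned among a few phyla/classes.
simulate_taxonomy <- function(taxa, n_classes) {
  n_phyla <- max(1L, ceiling(n_classes / 3))
  cls <- sample.int(n_classes, length(taxa), replace = TRUE)
  phy <- ((cls - 1L) %% n_phyla) + 1L
  stats::setNames(sprintf("k__Bacteria;p__Phylum%02d;c__Class%02d;s__%s",
                          phy, cls, taxa), taxa)
}

#' Simulate a random rooted phylogeny over the study taxa
#'
#' Random binary topology with uniform positive branch lengths (via
#' [ape::rtree()]); deterministic under `seed`.
#'
#' @param n_taxa number of leaves (>= 2).
#' @param seed RNG seed (`NULL` to use the current RNG state).
#' @param labels optional leaf labels, length `n_taxa`.
#' @return an [ape::phylo] tree.
#' @export
simulate_random_phylogeny <- function(n_taxa, seed = 1, labels = NULL) {
  n_taxa <- assert_count(n_taxa, "n_taxa", min = 2L)
  labels <- labels %||% sprintf("taxon_%04d", seq_len(n_taxa))
  with_seed(seed, {
    tree <- ape::rtree(n_taxa)
    # rtree labels tips t1..tn in a scrambled order; relabel so that the
    # i-th taxon ID maps to tip "ti"
    tree$tip.label <- labels[as.integer(sub("^t", "", tree$tip.label))]
    tree$edge.length <- pmax(tree$edge.length, 1e-8)
    tree
  })
}

#' Simulate per-sample DNA yields with prescribed coefficients of variation
#'
#' Yields are lognormal within each group with population-level mean and CV
#' matching the request exactly (lognormal \eqn{\sigma^2 = \ln(1 + CV^2)}).
#' Used to exercise the Feltz-Miller CV-equality test.
#'
#' @param group_means,group_cvs,group_ns equal-length vectors of group mean
#'   yield, target CV, and sample size (each n >= 2).
#' @param group_labels optional group names.
#' @param seed RNG seed.
#' @return data.frame with columns `group` and `yield`.
#' @export
simulate_yields <- function(group_means, group_cvs, group_ns,
                            group_labels = NULL, seed = 1) {
  k <- length(group_means)
  if (length(group_cvs) != k || length(group_ns) != k)
    stop("group_means, group_cvs, group_ns must have equal length",
         call. = FALSE)
  if (any(group_means < 0) || any(group_cvs < 0))
    stop("means and CVs must be non-negative", call. = FALSE)
  if (any(group_ns < 2)) stop("each group needs n >= 2", call. = FALSE)
  labels <- group_labels %||% sprintf("group%d", seq_len(k))
  with_seed(seed, {
    out <- lapply(seq_len(k), function(g) {
      n <- group_ns[g]
      if (group_cvs[g] == 0) {
        y <- rep(group_means[g], n)
      } else {
        s2 <- log(1 + group_cvs[g]^2)
        y <- stats::rlnorm(n, log(group_means[g]) - s2 / 2, sqrt(s2))
      }
      data.frame(group = labels[g], yield = y, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}
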