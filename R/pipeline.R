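#' Assemble a run configuration
#'
#' Either `simulation` (a list of [simulation_config()] arguments) or the
#' three input paths (`counts`, `design`, `tree`) must be given, not both.
#' All downstream seeds are derived from `seed`, so a rerun with the same
#' configuration is numerically identical.
#'
#' @param simulation list of [simulation_config()] arguments, or `NULL`.
#' @param counts,design,tree input file paths (counts TSV, design TSV,
#'   Newick), or `NULL` when simulating.
#' @param depth rarefaction depth (`NULL` skips rarefaction; simulated
#'   libraries are already at fixed depth).
#' @param min_replicates fish with fewer libraries are dropped.
#' @param class_level taxonomy rank count for "class-level" aggregation
#'   (QIIME L3 convention).
#' @param n_boot bootstrap replicates for metric repeatability CIs.
#' @param n_boot_taxon parametric-bootstrap replicates per taxon (0 skips
#'   per-taxon CIs and the CI-bound curve fits).
#' @param n_perm PERMANOVA/Mantel permutations.
#' @param min_count,min_libraries per-taxon count filter before taxon
#'   effect tests.
#' @param min_fish prevalence filter before per-taxon repeatability.
#' @param alpha_effects,taxon_effects effects tested for alpha metrics and
#'   taxon counts.
#' @param taxon_tests,otu_curve logical switches for the expensive stages.
#' @param seed master seed.
#' @param output_dir directory for TSV/JSON outputs (`NULL` returns
#'   results without writing).
#' @return a `run_config` list.
#' @export
run_config <- function(simulation = NULL, counts = NULL, design = NULL,
                       tree = NULL, depth = NULL, min_replicates = 1,
                       class_level = 3, n_boot = 500, n_boot_taxon = 100,
                       n_perm = 999, min_count = 5, min_libraries = 9,
                       min_fish = 10,
                       alpha_effects = c("protocol", "population",
                                         "interaction"),
                       taxon_effects = "protocol",
                       taxon_tests = TRUE, otu_curve = TRUE,
                       seed = 1, output_dir = NULL) {
  has_sim <- !is.null(simulation)
  has_files <- !is.null(counts)
  if (has_sim == has_files)
    stop("give exactly one of `simulation` or input paths", call. = FALSE)
  if (has_files && (is.null(design)))
    stop("file input needs `counts` and `design`", call. = FALSE)
  cfg <- mget(setdiff(ls(environment()), c("has_sim", "has_files")))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#' @param path YAML file whose keys are [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full synthetic-study analysis pipeline
#'
#' Orchestrates prep, diversity, repeatability, and inference into one
#' reproducible bundle: a Table-1 style repeatability table (variance
#' components, r, bootstrap CI for five alpha metrics and four
#' dissimilarities), a Table-2 style LRT table (protocol / population /
#' interaction per alpha metric), per-taxon effect-test tables, the
#' abundance-reproducibility logistic fit, and a machine-readable manifest
#' recording seeds, thresholds, library/taxon drop counts, and collected
#' warnings.
#'
#' @param config a [run_config()] or path to a YAML file.
#' @return (invisibly) a list with elements `alpha`, `repeatability`,
#'   `lrt`, `taxon_tests`, `otu_repeatability`, `curve`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  warnings_log <- character(0)
  catch_warn <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnings_log[length(warnings_log) + 1L] <<- conditionMessage(w)
    invokeRestart("muffleWarning")
  })
  stage <- function(name, expr) {
    tryCatch(catch_warn(expr), error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  # --- input -----------------------------------------------------------
  dataset <- stage("input", {
    if (!is.null(config$simulation)) {
      sim <- simulate_dataset(do.call(simulation_config, config$simulation))
      sim[c("table", "design", "tree")]
    } else {
      list(table = read_count_tsv(config$counts),
           design = read_design_tsv(config$design),
           tree = if (!is.null(config$tree)) ape::read.tree(config$tree))
    }
  })
  table <- dataset$table; design <- dataset$design; tree <- dataset$tree

  # --- prep ------------------------------------------------------------
  dropped_libs <- character(0)
  if (!is.null(config$depth)) {
    table <- stage("rarefy", rarefy(table, config$depth,
                                    seed = config$seed + 1))
    dropped_libs <- attr(table, "dropped_libraries")
  }
  pruned <- stage("prep", drop_incomplete_fish(table, design,
                                               config$min_replicates))
  table <- pruned$table; design <- design_for(pruned$design, table)
  class_table <- stage("prep", aggregate_by_taxonomy(table,
                                                     config$class_level))

  # --- diversity -------------------------------------------------------
  alpha <- stage("diversity", {
    cls <- alpha_diversity(class_table)
    spp <- alpha_diversity(table, tree = tree)
    out <- data.frame(library_id = cls$library_id,
                      class_richness = cls$richness,
                      class_evenness = cls$evenness,
                      species_richness = spp$richness,
                      species_evenness = spp$evenness,
                      stringsAsFactors = FALSE)
    if (!is.null(tree)) out$faith_pd <- spp$faith_pd
    out
  })
  distances <- stage("diversity", {
    d <- list(class_bray_curtis = distance_matrix(class_table, "bray_curtis"),
              species_bray_curtis = distance_matrix(table, "bray_curtis"))
    if (!is.null(tree)) {
      d$unweighted_unifrac <-
        distance_matrix(table, "unweighted_unifrac", tree)
      d$weighted_unifrac <- distance_matrix(table, "weighted_unifrac", tree)
    }
    d
  })

  # --- repeatability (Table-1 style) -----------------------------------
  metric_cols <- setdiff(names(alpha), "library_id")
  rep_table <- stage("repeatability",
    repeatability_table(metrics = alpha[metric_cols], distances = distances,
                        groups = design$fish_id, n_boot = config$n_boot,
                        seed = config$seed + 2))

  # --- inference (Table-2 style LRTs) ----------------------------------
  lrt_table <- stage("inference", do.call(rbind, lapply(metric_cols,
    function(m) do.call(rbind, lapply(config$alpha_effects, function(ef) {
      tr <- lmm_lrt_alpha(alpha[[m]], design, ef)
      data.frame(metric = m, effect = ef, statistic = tr$statistic,
                 df = tr$df, p_value = tr$p_value,
                 singular = isTRUE(tr$auxiliary$singular),
                 stringsAsFactors = FALSE)
    })))))

  taxon_tests <- NULL
  if (isTRUE(config$taxon_tests)) {
    taxon_tests <- stage("taxon_tests", {
      filt <- filter_taxa_by_count(class_table, config$min_count,
                                   config$min_libraries)
      do.call(rbind, lapply(config$taxon_effects, function(ef) {
        res <- pln_taxon_tests(filt, design, ef)
        cbind(effect = ef, res, stringsAsFactors = FALSE)
      }))
    })
  }

  # --- per-taxon repeatability and the abundance curve ------------------
  otu_rep <- NULL; curve <- NULL
  if (isTRUE(config$otu_curve)) {
    otu_rep <- stage("otu_repeatability", {
      filt <- filter_taxa_by_fish_prevalence(table, design, config$min_fish)
      ests <- lapply(seq_len(nrow(filt$counts)), function(i)
        per_taxon_repeatability(filt$counts[i, ], design$fish_id,
                                n_boot = config$n_boot_taxon,
                                seed = config$seed + 3 + i))
      data.frame(taxon = taxon_ids(filt),
                 x = log10_mean_abundance(filt),
                 r = vapply(ests, `[[`, numeric(1), "r"),
                 ci_low = vapply(ests, `[[`, numeric(1), "ci_low"),
                 ci_high = vapply(ests, `[[`, numeric(1), "ci_high"),
                 converged = vapply(ests, `[[`, logical(1), "converged"),
                 stringsAsFactors = FALSE)
    })
    curve <- stage("curve", {
      pts <- data.frame(x = otu_rep$x, y = otu_rep$r)
      if (config$n_boot_taxon > 0) {
        pts$y_lo <- otu_rep$ci_low; pts$y_hi <- otu_rep$ci_high
      }
      if (nrow(pts) >= 10) abundance_reproducibility_curve(pts) else NULL
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("microrepeat")),
    r_version = R.version.string,
    seed = config$seed,
    config = config[setdiff(names(config), "simulation")],
    simulation = config$simulation,
    n_libraries = ncol(table$counts),
    n_taxa = nrow(table$counts),
    libraries_dropped_at_rarefaction = dropped_libs,
    libraries_removed = pruned$audit$libraries_removed,
    fish_removed = pruned$audit$fish_removed,
    warnings = warnings_log)

  result <- list(alpha = alpha, repeatability = rep_table, lrt = lrt_table,
                 taxon_tests = taxon_tests, otu_repeatability = otu_rep,
                 curve = curve, manifest = manifest)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) if (!is.null(df))
      utils::write.table(df, file.path(config$output_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    wr(alpha, "alpha_diversity.tsv")
    wr(rep_table, "repeatability.tsv")
    wr(lrt_table, "lrt_tests.tsv")
    wr(taxon_tests, "taxon_tests.tsv")
    wr(otu_rep, "otu_repeatability.tsv")
    if (!is.null(curve)) {
      cf <- do.call(rbind, lapply(names(curve), function(nm)
        data.frame(response = nm, alpha = curve[[nm]]$alpha,
                   beta = curve[[nm]]$beta, gamma = curve[[nm]]$gamma,
                   se_gamma = curve[[nm]]$se_gamma,
                   t_gamma = curve[[nm]]$t_gamma, rss = curve[[nm]]$rss,
                   n_points = curve[[nm]]$n_points,
                   stringsAsFactors = FALSE)))
      wr(cf, "abundance_curve.tsv")
    }
    jsonlite::write_json(manifest,
                         file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
  }
  invisible(result)
}
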