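#' Rarefy (downsample) libraries to a common depth
#'
#' Each library with at least `depth` reads is downsampled to exactly
#' `depth` reads by sampling without replacement (a single multivariate-
#' hypergeometric draw per library, as in one-shot pipeline downsampling).
#' Libraries with fewer than `depth` reads are dropped and recorded in the
#' `dropped_libraries` attribute of the result.
#'
#' @param table a [count_table()].
#' @param depth target reads per library (>= 1); e.g. 105000 for the
#'   primary OTU analysis or 74300 for a denoised-ASV comparison.
#' @param seed RNG seed; the draw is deterministic under a fixed seed.
#' @return a [count_table()] whose columns each sum to exactly `depth`,
#'   with attribute `dropped_libraries` (character vector).
#' @export
rarefy <- function(table, depth, seed = 1) {
  depth <- assert_count(depth, "depth")
  totals <- colSums(table$counts)
  keep <- totals >= depth
  dropped <- library_ids(table)[!keep]
  counts <- table$counts[, keep, drop = FALSE]
  with_seed(seed, {
    for (j in seq_len(ncol(counts))) {
      if (sum(counts[, j]) == depth) next  # already at depth: unchanged
      counts[, j] <- rarefy_column(counts[, j], depth)
    }
  })
  out <- count_table(counts, taxonomy = table$taxonomy)
  attr(out, "dropped_libraries") <- dropped
  out
}

# One multivariate-hypergeometric draw: sample `depth` read positions from
# the 1..total read pool without replacement and map them back to taxa.
rarefy_column <- function(x, depth) {
  total <- sum(x)
  pos <- sample.int(total, depth)
  cuts <- cumsum(x)
  idx <- findInterval(pos - 1L, c(0, cuts), rightmost.closed = FALSE)
  tabulate(idx, nbins = length(x))
}

#' Drop under-replicated fish and synchronise table and design
#'
#' Removes libraries absent from the table (e.g. dropped at rarefaction)
#' from the design, then optionally removes every library of any fish left
#' with fewer than `min_replicates` libraries. Returns an audit log of
#' removals, mirroring study bookkeeping where losing all replicates of a
#' fish removes that fish from analysis.
#'
#' @param table a [count_table()].
#' @param design a [study_design()] covering at least the table's libraries.
#' @param min_replicates minimum libraries a fish must retain (default 1).
#' @return list with `table`, `design` (synchronised), and `audit`
#'   (list: `libraries_removed`, `fish_removed`).
#' @export
drop_incomplete_fish <- function(table, design, min_replicates = 1) {
  libs <- library_ids(table)
  design <- design[design$library_id %in% libs, , drop = FALSE]
  reps <- table(design$fish_id)
  bad_fish <- names(reps)[reps < min_replicates]
  keep_libs <- design$library_id[!design$fish_id %in% bad_fish]
  out_table <- subset_count_table(table, libraries = keep_libs)
  out_design <- study_design(design[design$library_id %in% keep_libs, ,
                                    drop = FALSE])
  audit <- list(libraries_removed = setdiff(libs, keep_libs),
                fish_removed = bad_fish)
  if (nrow(out_design) == 0) warning("no libraries remain after filtering")
  list(table = out_table, design = out_design, audit = audit)
}

#' Filter taxa by minimum count in a minimum number of libraries
#'
#' Keeps taxa observed with at least `min_count` reads in at least
#' `min_libraries` libraries. The defaults (5 counts in 9 libraries) are
#' the preset used for per-taxon model fitting.
#'
#' @param table a [count_table()].
#' @param min_count,min_libraries thresholds (>= 0).
#' @return filtered [count_table()].
#' @export
filter_taxa_by_count <- function(table, min_count = 5, min_libraries = 9) {
  hits <- rowSums(table$counts >= min_count)
  subset_count_table(table, taxa = hits >= min_libraries)
}

#' Filter taxa by per-fish prevalence
#'
#' A taxon is "present in a fish" if any of that fish's replicate libraries
#' has a nonzero count. Keeps taxa present in at least `min_fish` fish
#' (preset 10, as used before per-taxon repeatability estimation).
#'
#' @param table a [count_table()].
#' @param design a [study_design()].
#' @param min_fish minimum number of fish (>= 1).
#' @return filtered [count_table()].
#' @export
filter_taxa_by_fish_prevalence <- function(table, design, min_fish = 10) {
  design <- design_for(design, table)
  present <- table$counts > 0
  by_fish <- rowsum(t(present) * 1L, group = design$fish_id)  # fish x taxa
  n_fish_present <- colSums(by_fish > 0)
  subset_count_table(table, taxa = n_fish_present >= min_fish)
}

#' Remove taxa whose taxonomy matches blacklist patterns
#'
#' Generic label-blacklist filter, e.g. to drop mitochondrial or
#' chloroplast lineages before analysis.
#'
#' @param table a [count_table()] with taxonomy.
#' @param patterns character vector of regular expressions matched (case-
#'   insensitively) against taxonomy strings.
#' @return filtered [count_table()].
#' @export
filter_taxa_by_label <- function(table,
                                 patterns = c("mitochondria", "chloroplast")) {
  if (is.null(table$taxonomy)) return(table)
  tax <- table$taxonomy[taxon_ids(table)]
  tax[is.na(tax)] <- ""
  bad <- Reduce(`|`, lapply(patterns, function(p)
    grepl(p, tax, ignore.case = TRUE)))
  subset_count_table(table, taxa = !bad)
}

#' Aggregate counts to a taxonomy level
#'
#' Sums counts over taxa sharing the first `level` semicolon-delimited
#' taxonomy ranks (QIIME-style "L3" = class when ranks run
#' kingdom;phylum;class;...). Taxa lacking a taxonomy string pool into
#' `"Unassigned"`. Per-library totals are conserved exactly.
#'
#' @param table a [count_table()] with taxonomy.
#' @param level number of leading ranks to keep (>= 1).
#' @return aggregated [count_table()] whose taxon IDs are the truncated
#'   lineage strings.
#' @export
aggregate_by_taxonomy <- function(table, level) {
  level <- assert_count(level, "level")
  tax <- rep(NA_character_, nrow(table$counts))
  names(tax) <- taxon_ids(table)
  if (!is.null(table$taxonomy))
    tax[names(table$taxonomy)] <- table$taxonomy
  label <- vapply(tax, function(s) {
    if (is.na(s) || !nzchar(s)) return("Unassigned")
    ranks <- strsplit(s, ";", fixed = TRUE)[[1]]
    paste(ranks[seq_len(min(level, length(ranks)))], collapse = ";")
  }, character(1))
  agg <- rowsum(table$counts, group = label)
  count_table(agg,
              taxonomy = stats::setNames(rownames(agg), rownames(agg)))
}

#' Per-library rarefaction (accumulation) curves
#'
#' For each library and iteration, the library's reads are put in one
#' random order; the metric at depth `d` is computed on the counts formed
#' by the first `d` reads of that ordering. Nesting depths within a single
#' read permutation makes mean richness monotone non-decreasing in depth by
#' construction, and the full-depth point reproduces the un-rarefied metric
#' exactly.
#'
#' @param table a [count_table()].
#' @param depths increasing vector of depths (entries beyond a library's
#'   total are skipped for that library).
#' @param metric function mapping a count vector to a scalar (default
#'   [richness()]).
#' @param iterations random orderings averaged per library.
#' @param seed RNG seed.
#' @return data.frame with columns `library_id`, `depth`, `mean_value`,
#'   `n_iterations`.
#' @export
rarefaction_curve <- function(table, depths, metric = richness,
                              iterations = 10, seed = 1) {
  depths <- sort(unique(as.integer(depths)))
  stopifnot(all(depths >= 1))
  with_seed(seed, {
    rows <- lapply(library_ids(table), function(lib) {
      x <- table$counts[, lib]
      total <- sum(x)
      ds <- depths[depths <= total]
      if (!length(ds)) return(NULL)
      vals <- matrix(NA_real_, iterations, length(ds))
      for (it in seq_len(iterations)) {
        reads <- sample(rep.int(seq_along(x), x))
        for (k in seq_along(ds)) {
          cnt <- tabulate(reads[seq_len(ds[k])], nbins = length(x))
          names(cnt) <- names(x)
          vals[it, k] <- metric(cnt)
        }
      }
      data.frame(library_id = lib, depth = ds, mean_value = colMeans(vals),
                 n_iterations = iterations, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
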