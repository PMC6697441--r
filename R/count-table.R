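#' Construct a taxon-by-library count table
#'
#' The central container for amplicon count data: a non-negative integer
#' matrix with taxa as rows and sequencing libraries as columns, optionally
#' carrying a semicolon-delimited hierarchical taxonomy string per taxon
#' (e.g. `"k__Bacteria;p__Proteobacteria;c__Gammaproteobacteria"`).
#'
#' @param counts numeric matrix (taxa x libraries) of non-negative integers,
#'   with unique rownames (taxon IDs) and colnames (library IDs).
#' @param taxonomy optional named character vector mapping taxon IDs to
#'   taxonomy strings; names must be a subset of `rownames(counts)`.
#' @return an object of class `count_table`: a list with elements `counts`
#'   (integer-valued matrix) and `taxonomy` (named character or `NULL`).
#' @export
count_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("`counts` must be numeric", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have rownames (taxa) and colnames (libraries)",
         call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate taxon IDs", call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate library IDs", call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != floor(counts)))
    stop("counts must be finite non-negative integers", call. = FALSE)
  if (!is.null(taxonomy)) {
    if (is.null(names(taxonomy)) ||
        !all(names(taxonomy) %in% rownames(counts)))
      stop("`taxonomy` must be named by taxon IDs present in `counts`",
           call. = FALSE)
    taxonomy <- taxonomy[intersect(rownames(counts), names(taxonomy))]
  }
  structure(list(counts = counts, taxonomy = taxonomy),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d taxa x %d libraries (total reads %s)%s\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ","),
              if (is.null(x$taxonomy)) "" else ", with taxonomy"))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

taxon_ids <- function(table) rownames(table$counts)
library_ids <- function(table) colnames(table$counts)

# Subset a count_table by taxa and/or libraries, keeping taxonomy in sync.
subset_count_table <- function(table, taxa = NULL, libraries = NULL) {
  counts <- table$counts
  if (!is.null(taxa)) counts <- counts[taxa, , drop = FALSE]
  if (!is.null(libraries)) counts <- counts[, libraries, drop = FALSE]
  tax <- table$taxonomy
  if (!is.null(tax)) tax <- tax[names(tax) %in% rownames(counts)]
  count_table(counts, taxonomy = tax)
}

#' Construct a study-design table
#'
#' Maps every sequencing library to the fish (host individual) it came from,
#' that fish's full-sib family and source population, the DNA-isolation
#' protocol used for the library, and an experiment tag. This is the grouping
#' backbone for all variance decompositions: within-fish replicates are
#' libraries sharing `fish_id`.
#'
#' @param df data.frame with character/factor columns `library_id`,
#'   `fish_id`, `family_id`, `population`, `protocol` and optionally
#'   `experiment`.
#' @return a `study_design` data.frame.
#' @export
study_design <- function(df) {
  needed <- c("library_id", "fish_id", "family_id", "population", "protocol")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("design is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!"experiment" %in% names(df)) df$experiment <- "reproducibility"
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c(needed, "experiment")) df[[col]] <- as.character(df[[col]])
  if (anyDuplicated(df$library_id))
    stop("duplicate library_id in design", call. = FALSE)
  # each fish must resolve to a single family and population
  per_fish <- unique(df[, c("fish_id", "family_id", "population")])
  if (anyDuplicated(per_fish$fish_id))
    stop("a fish maps to more than one family or population", call. = FALSE)
  class(df) <- c("study_design", "data.frame")
  df
}

# Align a design to a count table's libraries (same order); error on mismatch.
design_for <- function(design, table) {
  libs <- library_ids(table)
  missing <- setdiff(libs, design$library_id)
  if (length(missing))
    stop("libraries absent from design: ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- design[match(libs, design$library_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
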