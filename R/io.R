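# Readers/writers for the plain-text formats used throughout: count tables
# and designs as TSV, trees as Newick (via ape), distance matrices as square
# TSV, BIOM-style JSON via the biomformat package when available.

#' Write / read a count table as TSV
#'
#' Rows are taxa, columns are libraries; the first column (`taxon_id`) holds
#' taxon IDs and an optional final `taxonomy` column holds the semicolon-
#' delimited lineage.
#'
#' @param table a [count_table()].
#' @param path file path.
#' @export
write_count_tsv <- function(table, path) {
  df <- data.frame(taxon_id = taxon_ids(table), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(table$taxonomy))
    df$taxonomy <- unname(table$taxonomy[taxon_ids(table)])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_tsv
#' @export
read_count_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  tax <- NULL
  if ("taxonomy" %in% names(df)) {
    tax <- stats::setNames(as.character(df$taxonomy), df$taxon_id)
    df$taxonomy <- NULL
  }
  m <- as.matrix(df[, setdiff(names(df), "taxon_id"), drop = FALSE])
  rownames(m) <- df$taxon_id
  count_table(m, taxonomy = tax)
}

#' Write / read a study design as TSV
#' @param design a [study_design()].
#' @param path file path.
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_tsv
#' @export
read_design_tsv <- function(path) {
  study_design(utils::read.table(path, sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE))
}

#' Write / read a count table as BIOM-format JSON
#'
#' Uses the Bioconductor \pkg{biomformat} package (sparse BIOM v1 JSON).
#' @param table a [count_table()].
#' @param path file path.
#' @export
write_count_biom <- function(table, path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("package 'biomformat' is required for BIOM I/O", call. = FALSE)
  b <- biomformat::make_biom(table$counts)
  biomformat::write_biom(b, path)
  invisible(path)
}

#' @rdname write_count_biom
#' @export
read_count_biom <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("package 'biomformat' is required for BIOM I/O", call. = FALSE)
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix")
  count_table(m)
}

#' Write / read a distance matrix as square TSV
#'
#' Square layout with a leading header row and column of library IDs.
#' @param D symmetric numeric matrix with matching dimnames.
#' @param path file path.
#' @export
write_distance_tsv <- function(D, path) {
  D <- validate_distance_matrix(D)
  df <- data.frame(library_id = rownames(D), D, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_tsv
#' @export
read_distance_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$library_id
  validate_distance_matrix(m)
}

# Symmetry/diagonal checks shared by distance-matrix consumers.
validate_distance_matrix <- function(D, tol = 1e-12) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("distance matrix must be square", call. = FALSE)
  if (is.null(rownames(D)) && !is.null(colnames(D))) rownames(D) <- colnames(D)
  if (is.null(colnames(D)) && !is.null(rownames(D))) colnames(D) <- rownames(D)
  if (is.null(rownames(D)))
    stop("distance matrix must carry library IDs as dimnames", call. = FALSE)
  if (!isTRUE(all.equal(rownames(D), colnames(D))))
    stop("distance matrix row/column IDs disagree", call. = FALSE)
  if (any(D < -tol)) stop("negative dissimilarities", call. = FALSE)
  if (max(abs(D - t(D))) > tol)
    stop("distance matrix is not symmetric", call. = FALSE)
  if (any(abs(diag(D)) > tol))
    stop("distance matrix diagonal must be zero", call. = FALSE)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  D
}
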