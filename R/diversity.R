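#' Taxon richness of a library
#'
#' Number of taxa with a nonzero count.
#' @param x numeric vector of counts (one library).
#' @return integer richness.
#' @export
richness <- function(x) sum(x > 0)

#' Shannon evenness (Pielou equitability, log base 2)
#'
#' Shannon entropy \eqn{H = -\sum p_t \log_2 p_t} over present taxa,
#' divided by \eqn{\log_2} richness; 1 iff all present taxa are
#' equiabundant. Undefined (returned as `NA` with a warning) when fewer
#' than two taxa are present.
#'
#' @param x numeric vector of counts.
#' @return evenness in \[0, 1\], or `NA`.
#' @export
evenness <- function(x) {
  p <- x[x > 0]
  if (length(p) < 2) {
    warning("evenness undefined for richness < 2", call. = FALSE)
    return(NA_real_)
  }
  p <- p / sum(p)
  H <- -sum(p * log2(p))
  H / log2(length(p))
}

# --- phylogeny plumbing -----------------------------------------------------

# Edge x tip incidence: entry (e, t) is TRUE when tip t descends from the
# child node of edge e. Computed once per tree and cached on the tree object
# by callers that loop over many samples.
edge_tip_incidence <- function(tree) {
  nt <- length(tree$tip.label)
  tree <- stats::reorder(tree, "postorder")
  n_nodes <- nt + tree$Nnode
  under <- matrix(FALSE, n_nodes, nt)
  under[cbind(seq_len(nt), seq_len(nt))] <- TRUE
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    under[p, ] <- under[p, ] | under[ch, ]
  }
  M <- under[tree$edge[, 2], , drop = FALSE]
  colnames(M) <- tree$tip.label
  list(incidence = M, lengths = tree$edge.length)
}

# Map a named count vector onto the tree's tips; taxa missing from the tree
# are a hard error (silent drops would corrupt UniFrac denominators).
tip_counts <- function(x, tree) {
  if (is.null(names(x))) stop("count vector must be named by taxon",
                              call. = FALSE)
  missing <- setdiff(names(x)[x > 0], tree$tip.label)
  if (length(missing))
    stop("taxa absent from the tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- stats::setNames(numeric(length(tree$tip.label)), tree$tip.label)
  common <- intersect(names(x), tree$tip.label)
  out[common] <- x[common]
  out
}

#' Faith's phylogenetic diversity
#'
#' Total branch length of the union of root-to-tip paths for the taxa
#' present in the sample. The default convention is root-inclusive: the
#' path from the observed taxa's most recent common ancestor up to the tree
#' root is counted. Set `include_root = FALSE` to sum only branches within
#' the subtree spanned by the observed taxa.
#'
#' @param x named count vector.
#' @param tree rooted [ape::phylo] tree with branch lengths whose tips are
#'   a superset of the taxa.
#' @param include_root logical.
#' @return branch-length sum (0 for an empty sample).
#' @export
faith_pd <- function(x, tree, include_root = TRUE) {
  inc <- edge_tip_incidence(tree)
  present <- tip_counts(x, tree) > 0
  if (!any(present)) return(0)
  n_desc <- rowSums(inc$incidence[, present, drop = FALSE])
  has <- n_desc > 0
  # non-root form keeps only branches strictly inside the spanned subtree,
  # i.e. drops every edge on the MRCA-to-root path (those subtend all
  # present tips)
  if (!include_root) has <- has & n_desc < sum(present)
  sum(inc$lengths[has])
}

#' Bray-Curtis dissimilarity
#'
#' \eqn{\sum_t |x_t - y_t| / \sum_t (x_t + y_t)} on (rarefied) counts.
#' @param x,y count vectors over the same taxa.
#' @return dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  tot <- sum(x) + sum(y)
  if (tot == 0) stop("both samples are empty", call. = FALSE)
  sum(abs(x - y)) / tot
}

#' Unweighted UniFrac dissimilarity
#'
#' Presence/absence phylogenetic dissimilarity: branch length leading to
#' taxa found in exactly one of the two samples, divided by branch length
#' leading to taxa found in either.
#'
#' @param x,y named count vectors.
#' @param tree rooted [ape::phylo] tree.
#' @return dissimilarity in \[0, 1\].
#' @export
unweighted_unifrac <- function(x, y, tree) {
  inc <- edge_tip_incidence(tree)
  px <- inc$incidence %*% (tip_counts(x, tree) > 0) > 0
  py <- inc$incidence %*% (tip_counts(y, tree) > 0) > 0
  union_len <- sum(inc$lengths[px | py])
  if (union_len == 0) stop("both samples are empty", call. = FALSE)
  sum(inc$lengths[xor(px, py)]) / union_len
}

#' Weighted UniFrac dissimilarity
#'
#' \eqn{\sum_b \ell_b |p_x(b) - p_y(b)|} where \eqn{p(b)} is the fraction
#' of a sample's reads descending from branch `b`. The raw (non-normalised)
#' form is the default; with `normalized = TRUE` the sum is divided by the
#' abundance-weighted maximum \eqn{\sum_t d_t (p_x(t) + p_y(t))}, where
#' \eqn{d_t} is the root-to-tip distance, scaling the result into \[0, 1\].
#'
#' @param x,y named count vectors.
#' @param tree rooted [ape::phylo] tree.
#' @param normalized logical.
#' @return dissimilarity (>= 0; in \[0, 1\] when normalised).
#' @export
weighted_unifrac <- function(x, y, tree, normalized = FALSE) {
  inc <- edge_tip_incidence(tree)
  cx <- tip_counts(x, tree); cy <- tip_counts(y, tree)
  if (sum(cx) == 0 || sum(cy) == 0)
    stop("weighted UniFrac needs nonzero totals in both samples",
         call. = FALSE)
  px <- drop(inc$incidence %*% (cx / sum(cx)))
  py <- drop(inc$incidence %*% (cy / sum(cy)))
  d <- sum(inc$lengths * abs(px - py))
  if (normalized) {
    depth <- drop(crossprod(inc$incidence, inc$lengths))  # root-to-tip dist
    d <- d / sum(depth * (cx / sum(cx) + cy / sum(cy)))
  }
  d
}

#' Pairwise distance matrix over libraries
#'
#' Applies one of the study's dissimilarity metrics to every pair of
#' libraries in a count table. For taxonomy-level variants (class-level
#' Bray-Curtis), aggregate with [aggregate_by_taxonomy()] first.
#'
#' @param table a [count_table()].
#' @param metric one of `"bray_curtis"`, `"unweighted_unifrac"`,
#'   `"weighted_unifrac"`, `"weighted_unifrac_normalized"`.
#' @param tree rooted [ape::phylo] tree (required for UniFrac metrics).
#' @return symmetric numeric matrix with zero diagonal and library IDs as
#'   dimnames.
#' @export
distance_matrix <- function(table,
                            metric = c("bray_curtis", "unweighted_unifrac",
                                       "weighted_unifrac",
                                       "weighted_unifrac_normalized"),
                            tree = NULL) {
  metric <- match.arg(metric)
  counts <- table$counts
  n <- ncol(counts)
  D <- matrix(0, n, n, dimnames = list(colnames(counts), colnames(counts)))
  if (metric == "bray_curtis") {
    for (i in seq_len(n)) for (j in seq_len(n)) if (j > i)
      D[i, j] <- D[j, i] <- bray_curtis(counts[, i], counts[, j])
    return(D)
  }
  if (is.null(tree)) stop("UniFrac metrics require `tree`", call. = FALSE)
  inc <- edge_tip_incidence(tree)
  C <- vapply(seq_len(n), function(j) tip_counts(counts[, j], tree),
              numeric(length(tree$tip.label)))
  if (metric == "unweighted_unifrac") {
    B <- inc$incidence %*% (C > 0) > 0       # edge presence per library
    for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) {
      u <- sum(inc$lengths[B[, i] | B[, j]])
      D[i, j] <- D[j, i] <-
        if (u == 0) 0 else sum(inc$lengths[xor(B[, i], B[, j])]) / u
    }
  } else {
    P <- inc$incidence %*% sweep(C, 2, colSums(C), "/")
    depth <- drop(crossprod(inc$incidence, inc$lengths))
    rel <- sweep(C, 2, colSums(C), "/")
    for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) {
      d <- sum(inc$lengths * abs(P[, i] - P[, j]))
      if (metric == "weighted_unifrac_normalized")
        d <- d / sum(depth * (rel[, i] + rel[, j]))
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Alpha-diversity table for all libraries
#'
#' Convenience wrapper computing richness, evenness, and (when a tree is
#' given) Faith's PD per library, optionally at an aggregated taxonomy
#' level.
#'
#' @param table a [count_table()].
#' @param tree optional [ape::phylo] tree.
#' @return data.frame with one row per library.
#' @export
alpha_diversity <- function(table, tree = NULL) {
  counts <- table$counts
  out <- data.frame(
    library_id = colnames(counts),
    richness = apply(counts, 2, richness),
    evenness = suppressWarnings(apply(counts, 2, evenness)),
    stringsAsFactors = FALSE)
  if (!is.null(tree)) {
    inc <- edge_tip_incidence(tree)
    pres <- vapply(seq_len(ncol(counts)),
                   function(j) tip_counts(counts[, j], tree) > 0,
                   logical(length(tree$tip.label)))
    out$faith_pd <- vapply(seq_len(ncol(counts)), function(j)
      sum(inc$lengths[rowSums(inc$incidence[, pres[, j], drop = FALSE]) > 0]),
      numeric(1))
  }
  rownames(out) <- NULL
  out
}
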