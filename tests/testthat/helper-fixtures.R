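# Fixtures and independent oracles used across the suite.

# Small deterministic count table.
toy_table <- function() {
  m <- matrix(c(5, 0, 2, 1,
                0, 3, 3, 0,
                10, 10, 10, 10), nrow = 3, byrow = TRUE,
              dimnames = list(c("tA", "tB", "tC"),
                              c("lib1", "lib2", "lib3", "lib4")))
  count_table(m)
}

toy_design <- function(libs = paste0("lib", 1:4)) {
  study_design(data.frame(
    library_id = libs,
    fish_id = rep(c("f1", "f2"), each = 2)[seq_along(libs)],
    family_id = "fam1", population = "pop1",
    protocol = rep(c("PCP", "PFP"), 2)[seq_along(libs)],
    stringsAsFactors = FALSE))
}

# The 4-leaf reference tree used in worked examples.
quartet_tree <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

# --- naive path-enumeration oracles for phylogenetic metrics ----------------
# Deliberately independent of the package's postorder incidence machinery:
# each tip's root path is enumerated with ape::nodepath and edges are
# identified by their child node.

tip_path_edges <- function(tree, tip_label) {
  tip <- match(tip_label, tree$tip.label)
  path <- ape::nodepath(tree, from = length(tree$tip.label) + 1, to = tip)
  # edges as child nodes along the root -> tip walk
  path[-1]
}

edge_length_of <- function(tree, child) {
  tree$edge.length[match(child, tree$edge[, 2])]
}

oracle_edge_set <- function(tree, present_tips) {
  unique(unlist(lapply(present_tips, function(tp) tip_path_edges(tree, tp))))
}

oracle_faith_pd <- function(tree, present_tips) {
  if (!length(present_tips)) return(0)
  sum(edge_length_of(tree, oracle_edge_set(tree, present_tips)))
}

oracle_unweighted_unifrac <- function(tree, tips_x, tips_y) {
  ex <- oracle_edge_set(tree, tips_x)
  ey <- oracle_edge_set(tree, tips_y)
  uni <- union(ex, ey)
  sum(edge_length_of(tree, setdiff(uni, intersect(ex, ey)))) /
    sum(edge_length_of(tree, uni))
}

oracle_weighted_unifrac <- function(tree, x, y, normalized = FALSE) {
  px <- x / sum(x); py <- y / sum(y)
  d <- 0; denom <- 0
  all_children <- tree$edge[, 2]
  for (ch in all_children) {
    ell <- edge_length_of(tree, ch)
    wx <- sum(px[vapply(names(px), function(tp)
      ch %in% tip_path_edges(tree, tp), logical(1))])
    wy <- sum(py[vapply(names(py), function(tp)
      ch %in% tip_path_edges(tree, tp), logical(1))])
    d <- d + ell * abs(wx - wy)
  }
  if (normalized) {
    for (tp in tree$tip.label) {
      dt <- sum(edge_length_of(tree, tip_path_edges(tree, tp)))
      denom <- denom + dt * (px[tp] + py[tp])
    }
    d <- d / denom
  }
  unname(d)
}

# Gaussian one-way data with a prescribed latent repeatability.
sim_univariate <- function(r_true, n_groups = 35, reps = 3, seed = 1) {
  set.seed(seed)
  a <- rnorm(n_groups, 0, sqrt(r_true))
  g <- rep(seq_len(n_groups), each = reps)
  list(values = a[g] + rnorm(n_groups * reps, 0, sqrt(1 - r_true)),
       groups = g)
}

# Counts from the Poisson-lognormal repeatability model.
sim_pln_counts <- function(mu, s2a, s2o, n_fish = 35, reps = 3, seed = 1) {
  set.seed(seed)
  a <- rnorm(n_fish, 0, sqrt(s2a))
  fish <- rep(seq_len(n_fish), each = reps)
  o <- rnorm(n_fish * reps, 0, sqrt(s2o))
  list(y = rpois(n_fish * reps, exp(mu + a[fish] + o)), fish = fish)
}

# Paper-shaped design (2 populations x 3 families x 6 fish x 3 protocols)
# without counts, for inference-module simulations.
paper_design <- function() {
  simulate_dataset(simulation_config(n_taxa = 2, library_depth = 10,
                                     seed = 42))$design
}

# Null Poisson-lognormal count table on a design: family + fish + obs
# effects, no protocol or population effect.
sim_null_count_table <- function(design, n_taxa, mu = 3, sd_fam = 0.3,
                                 sd_fish = 0.5, sd_obs = 0.3, seed = 1) {
  set.seed(seed)
  fam <- rnorm(length(unique(design$family_id)), 0, sd_fam)
  names(fam) <- unique(design$family_id)
  fsh <- rnorm(length(unique(design$fish_id)), 0, sd_fish)
  names(fsh) <- unique(design$fish_id)
  n <- nrow(design)
  eta <- outer(rep(mu, n_taxa), fam[design$family_id] + fsh[design$fish_id],
               `+`) + matrix(rnorm(n_taxa * n, 0, sd_obs), n_taxa, n)
  cnt <- matrix(rpois(n_taxa * n, exp(eta)), n_taxa, n,
                dimnames = list(sprintf("t%02d", seq_len(n_taxa)),
                                design$library_id))
  count_table(cnt)
}
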