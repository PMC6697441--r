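# microrepeat

Partitioning biological and technical variation in host-associated
microbiome surveys.

## The problem

When a gut microbiome is profiled by 16S amplicon sequencing, how much of
the variation we measure reflects real differences among host individuals,
and how much is an artifact of the lab pipeline — the DNA-isolation
protocol, tissue subsampling, and sequencing noise? `microrepeat`
implements a repeated-measures framework for answering this: libraries
prepared from the same host with different protocols are treated as
repeated measurements, and variation in any diversity metric is split into
an among-host (biological) component *s²A* and a within-host (technical)
component *s²W*. The headline statistic is the repeatability (here,
reproducibility across protocols)

    r = s²A / (s²A + s²W),   0 ≤ r ≤ 1,

where *r* = 1 means the protocol contributes nothing and *r* = 0.5 means
host and protocol contribute equally. The package estimates *r* for

- **univariate alpha metrics** (richness, Shannon/Pielou evenness, Faith's
  phylogenetic diversity) from one-way ANOVA mean squares or REML, with
  confidence intervals from a bootstrap that resamples whole hosts;
- **distance matrices** (class- and species-level Bray-Curtis, weighted
  and unweighted UniFrac) via the analogous partitioning of squared
  dissimilarities;
- **individual taxa**, via an overdispersed Poisson (Poisson-lognormal)
  mixed model with a host random intercept and an observation-level
  effect, fit by nested adaptive Gauss-Hermite quadrature, with parametric
  bootstrap CIs — and a three-parameter logistic curve
  `y = α / (1 + exp((β − x)/γ))` describing how reproducibility rises with
  log10 mean taxon abundance.

Around the core sit the standard steps: rarefaction to a fixed depth,
prevalence/count filters, taxonomy-level aggregation, a synthetic-data
generator with known ground truth, and a hypothesis-test battery
(mixed-model likelihood-ratio tests, factorial and nested PERMANOVA,
Mantel tests, median-based Levene precision tests, and the Feltz-Miller
test for equality of coefficients of variation).

It is aimed at microbial ecologists designing or auditing amplicon
studies: it answers "can I trust cross-protocol comparisons?" and "how
rare can a taxon be before its abundance is unmeasurable?".

## Worked example

```r
library(microrepeat)

# a study-shaped synthetic dataset: 2 populations x 3 families x 6 fish
# x 3 DNA-isolation protocols, libraries of 20,000 reads
sim <- simulate_dataset(simulation_config(
  n_taxa = 300, library_depth = 20000,
  sigma2_A = 0.5, sigma2_W = 0.05, seed = 1))

# alpha diversity per library, then reproducibility of species richness
alpha <- alpha_diversity(sim$table, tree = sim$tree)
est <- bootstrap_repeatability(alpha$richness, sim$design$fish_id,
                               n_boot = 500, seed = 1)
est
#> repeatability r = 0.433 (95% CI 0.239, 0.567; 500 bootstrap reps)

# multivariate: species-level Bray-Curtis
D <- distance_matrix(sim$table, "bray_curtis")
bootstrap_repeatability(D, sim$design$fish_id, n_boot = 500, seed = 1,
                        mode = "distance")
#> repeatability r = 0.872 (95% CI 0.854, 0.882; 500 bootstrap reps)

# published-value check: class-richness variance components 77.409 (among
# fish) and 11.080 (within fish) give
repeatability_from_components(77.409, 11.080)
#> [1] 0.8747867
```

Composition (Bray-Curtis, r = 0.87) is far more reproducible than
richness (r = 0.43) in this simulation: richness depends on
presence/absence of rare taxa, whose detection flickers with sampling
noise at finite depth — the same mechanism that makes unweighted,
presence-based metrics the least reproducible in real surveys — while
abundance-weighted composition tracks the latent biology
(true latent-scale r = 0.5 / 0.55 ≈ 0.91).

`run_pipeline(run_config(...))` chains the whole analysis (prep →
diversity → repeatability → tests → abundance-reproducibility curve) and
writes TSV tables plus a JSON manifest of seeds and drop counts.

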