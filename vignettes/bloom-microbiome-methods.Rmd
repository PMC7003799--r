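---
title: "Methods: community phylogenetics and functional profiling of bloom microbiomes"
author: "interactome package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community phylogenetics and functional profiling of bloom microbiomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(interactome)
```

# The analysis this package implements

Harmful *Microcystis* blooms carry a community of particle-attached
("microbiome") bacteria. A survey of such blooms across many lakes asks three
questions that this package turns into reusable, tested code:

1. **Is the microbiome spatially structured?** Pairwise community
   dissimilarity — taxonomic (Bray–Curtis) and phylogenetic (abundance-
   weighted UniFrac) — is regressed on pairwise great-circle distance with a
   Gaussian-identity GLM. A significant positive slope is a distance-decay
   relationship, the signature of dispersal limitation; its absence suggests
   the same pool of organisms reaches every bloom.

2. **Is the community phylogenetically structured?** Within every site, the
   mean nearest taxon distance (MNTD) is compared against a null distribution
   obtained by shuffling taxa across the tips of the phylogeny 999 times.
   The standardized index `alphaNTI = -(obs - mean(null)) / sd(null)` exceeds
   +2 when co-occurring taxa are more closely related than chance
   (environmental filtering); between sites, the analogous `betaNTI` on
   betaMNTD below -2 means two communities are more phylogenetically similar
   than chance — a shared environmental filter. Welch t-tests compare the
   observed index distributions against their standardized nulls.

3. **Is functional potential shared or complementary?** KO (KEGG Orthology)
   abundance profiles per lake give a functional Bray–Curtis decay analysis,
   and KEGG-style module definitions are scored for completeness — a module
   counts as "complete or nearly complete" when at most one of its gene
   blocks is missing — then partitioned into host-only, shared, and
   microbiome-only sets (the Venn diagram of the survey's functional
   comparison).

The upstream production of the inputs (read processing, OTU clustering,
taxonomy assignment, tree building, assembly, binning, KO annotation) is out
of scope: the package starts from an OTU table, a taxonomy table, a rooted
phylogeny, site coordinates, KO tables and module definitions.

# The OTU-table processing chain

`apply_filter_chain()` reproduces the survey's conventions, in this order:

1. discard taxa classified as eukaryote, archaea, chloroplast or
   mitochondria (`filter_by_taxonomy()`); matching is **exact per lineage
   rank and case-insensitive**, never substring, so excluding `"bacteria"`
   cannot remove `Melainabacteria`;
2. discard taxa with fewer than 100 counts summed across samples
   (`filter_low_abundance()`; the boundary is strict: a 99-count taxon goes,
   a 100-count taxon stays);
3. remove the cyanobacterial host lineage (`remove_group()`);
4. rarefy every sample to the depth of the shallowest sample — a single
   draw without replacement per sample, deterministic given the seed
   (`rarefy()`);
5. pool replicate samples of a site by summing counts
   (`pool_replicates()`; an averaging option exists).

Two orderings are ambiguous in the source protocol and fixed here by
documented convention: the 100-count rule is applied *before* host removal
(the order the protocol lists them in), and rarefaction precedes pooling.
Because rarefaction equalizes depths first, pooled site totals are exactly
`n_replicates * depth`.

# Dissimilarity and distance decay

* **Bray–Curtis**: `sum|x - y| / sum(x + y)` over taxa (vegan's `vegdist`),
  defined for counts or real-valued abundances (KO profiles reuse it).
* **Weighted UniFrac**: for each branch `b` with length `l_b` and descendant
  proportional abundances `p_b`, `q_b` in the two samples, the raw statistic
  is `sum_b l_b |p_b - q_b|`; the default normalized variant divides by
  `sum_b l_b (p_b + q_b)` and lies in `[0, 1]`. The source protocol does not
  state which variant its QIIME run used; the normalized one is the default
  here because the reported values are bounded, and the raw variant is a
  flag away. On a star tree with unit branches the raw variant reduces to
  the L1 distance of the proportion vectors — a property test ties it to
  Bray–Curtis.
* **Great-circle distances**: haversine on a sphere of radius 6371 km by
  default (configurable; the classic `rdist.earth` default differs slightly,
  and the survey reports distances only coarsely).
* **Decay GLM**: Gaussian family, identity link, over the `n(n-1)/2` site
  pairs; the deviance explained then equals the coefficient of
  determination, and the reported p-value is the Wald p for the slope. The
  pairs are not independent — this is deliberately faithful to the source
  analysis — and a Mantel-style permutation p-value is available via
  `n_perm` for robustness checks, off by default.

# Null-model community phylogenetics

`alpha_nti()` and `beta_nti()` implement the taxa-label randomization: each
of the `n_null = 999` replicates draws one uniform permutation of all tip
labels of the supplied phylogeny, applied to the patristic matrix and shared
by every sample (or pair) in that replicate — the `taxa.labels` convention
of the picante/Stegen lineage of methods. Design points:

* MNTD is unweighted by default (the cited implementation's default); the
  abundance-weighted variant is a flag.
* `sd(null)` is the sample (n-1) standard deviation.
* A zero-variance null (e.g. a sample containing every tip, or a star tree)
  yields an explicit `NA` index with reason `"zero null variance"` — never a
  silent zero.
* Classification uses strict inequalities: an index of exactly 2 or -2 is
  "random".
* Indices are invariant under uniform branch-length rescaling (z-scores are
  scale-free) — enforced by a property test.
* The t-test compares observed indices against pooled standardized null
  indices (each replicate z-scored within its own sample's null
  distribution); the raw null values are returned for alternatives.

# The synthetic-data generator

Every analysis stage is tested against data with known ground truth, so the
generator is itself first-class, tested code. It emulates the survey's
design: 9 sites sampled in triplicate, a regional pool of 300 taxa, 60 taxa
per site, ~20 000 reads per replicate with log-normal (sigma = 1.5)
abundances — a steep rank-abundance curve with many rare taxa, so taxonomic
dissimilarity is high even between sites assembled by the same filter.

* **Phylogeny** (`simulate_tree()`): constant-rate pure-birth (Yule) trees
  with unit birth rate, grown lineage-by-lineage with exponential waiting
  times and extended past the last split so every pendant branch is
  positive. The closed-form expected crown age
  `sum(1/(2:(n-1))) + 1/n` anchors a moment-recovery test.
* **Niche trait** (`evolve_trait_bm()`): Brownian motion from a root value
  of 0 (only trait differences matter). Because a BM trait on a Yule tree is
  phylogenetically labile — in our measurements roughly a quarter of the
  taxa in any trait band have no close relative in the band — the survey
  generator first applies Pagel's delta transform
  (`delta_transform()`, default `niche_conservatism = 0.15`) to concentrate
  trait divergence on basal branches. This makes the niche clade-conserved,
  which is precisely the regime in which environmental filtering produces
  the clustered alphaNTI / negative betaNTI pattern; the transform preserves
  root-to-tip depths, so the BM tip-variance moment test is unaffected.
* **Assembly** (`assemble_community()`): three modes mapping one-to-one onto
  the interpretive categories of the null models —
  * *filtered*: candidate pool = taxa within `filter_width` (default 0.3
    trait units) of the site optimum, floored at the `2 * richness` taxa
    nearest the optimum so the draw never degenerates; the community is a
    uniform draw of `richness` taxa from the pool (filtering plus
    ecological drift). A deterministic nearest-to-optimum rule was rejected
    during design: with a shared optimum it makes all site communities
    identical, so betaMNTD and all its null replicates are exactly zero and
    betaNTI is undefined. Filtered assembly also biases expected abundances
    by a Gaussian kernel in trait distance from the optimum (width
    `2 * filter_width`), so abundance structure tracks the environment.
  * *neutral*: uniform sampling without replacement — the calibration
    control (about 5% of neutral communities should exceed |alphaNTI| = 2).
  * *overdispersed*: greedy max-min patristic selection (limiting
    similarity), seeded at the taxon nearest the optimum, ties broken by
    label order (as everywhere in the generator, for bit-reproducibility).
* **Geography** (`place_sites()`): sites uniform on the sphere. Under
  `shared_optimum` all optima are equal — no distance-decay ground truth;
  this is the regime the real survey inferred. Under `autocorrelated` the
  optima follow the dominant spatial axis of the realized layout (first
  principal coordinate of the great-circle distance matrix, rank-mapped to
  the unit interval and then onto the realized trait quantile scale). A
  latitude-only gradient was rejected during design: with uniform
  longitudes, latitude explains little of pairwise great-circle distance,
  so the planted decay was unrecoverable at 9 sites in most realizations.
* **Replicates** share their site's taxon pool and redraw abundances —
  mirroring triplicate field sampling of one bloom; whether real replicates
  were independent stations is unknown, so this is an explicit assumption.
* **Taxonomy** (`simulate_taxonomy()`): synthetic semicolon lineages with a
  genuine Cyanobacteria-labelled clade, and (`simulate_filter_fixture()`)
  planted chloroplast/mitochondria/eukaryote/archaea and sub-100-count taxa,
  so the full filter chain has an exact expected outcome.
* **KO tables** (`simulate_ko_tables()`, `simulate_module_defs()`): three
  disjoint module collections (host / microbiome / shared) with 3–6 blocks
  of 1–3 alternative KOs; with zero dropout noise the Venn partition of
  complete modules recovers the generating lists exactly. Modules get at
  least three blocks so an entirely absent module is never "nearly
  complete" under the at-most-one-missing-block rule.

What the generator does *not* emulate: sequencing error, chimeras, OTU
clustering artifacts, compositional biases of extraction/PCR, toxin-gene
content, or any covariance between taxonomy and function. Passing
parameter-recovery tests therefore shows the *statistics* behave as designed
under the assumed assembly processes — not that the upstream bioinformatics
of a real survey is reproduced.

# Numerical choices

* All stochastic functions take an explicit seed, restore the caller's RNG
  state, and are pure functions of (arguments, seed); the pipeline expands
  one user seed into per-stage seeds (`derive_seed()`), so stages can be
  rerun in isolation and full reruns are bit-identical.
* Ties everywhere break by lexicographic taxon label.
* Matrices are validated symmetric with zero diagonal on every output.
* A constant dissimilarity vector in the decay GLM is reported as slope 0,
  deviance explained 0, p = 1 rather than NaN.
* Rarefaction is a single draw (not an average over draws), matching common
  single-rarefaction practice; the seed is recorded in the run manifest.
* Module completeness treats a block as present if *any* alternative KO is
  present (KEGG-mapper convention); a strict all-alternatives mode is a
  flag. KO "presence" means pooled abundance above 0 by default, with a
  configurable minimum-abundance threshold.

# Problem sizes used by the tests

Oracle-equivalence tests run 100 random fixtures of up to 20 tips against
brute-force implementations (tolerance 1e-12). Null-model calibration uses
200 neutral communities of 60 taxa from a 300-tip pool with 999 null
replicates; parameter recovery runs the full survey generator (300 tips,
9 sites, triplicates, 999 nulls) across five seeds per assembly mode. These
sizes make the whole suite run in minutes on one CPU while keeping
Monte-Carlo error well inside the asserted margins.

# Known limitations

* The GLM on dissimilarity pairs inherits the non-independence of pairwise
  designs; use the permutation option when inference matters.
* alphaNTI/betaNTI nulls shuffle across **all** tips of the supplied
  phylogeny: the tree you pass defines the null's regional species pool,
  and the pipeline deliberately uses the tree as supplied rather than
  pruning it to the observed taxa. This matters: restricting the pool to
  the union of the observed communities removes exactly the clustering
  shared by all sites (under one common filter the union *is* the filtered
  pool, and within it sites are random draws). Prune with
  `prune_tree_to_table()` first if you want the restricted null.
* The module grammar is the pre-flattened block/alternative form; the full
  KEGG boolean grammar (nested parentheses, plus/minus operators) is not
  parsed.
* The Venn partition depends on which KO evidence (MAGs, total metagenome,
  or their union) is supplied; the package accepts any KO set and leaves
  that choice to the user.
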