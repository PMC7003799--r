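# interactome

Community phylogenetics and functional profiling of cyanobacterial
(*Microcystis*) bloom microbiomes.

## The scientific problem

*Microcystis* blooms carry a dense community of particle-attached bacteria —
the bloom "microbiome" — hypothesized to form a coevolved, functionally
complementary consortium with its host (an *interactome*). Testing that idea
from a multi-lake 16S + metagenomic survey requires a specific statistical
stack:

* **Distance decay.** If the microbiome were dispersal-limited, community
  similarity should fall with geographic distance. The package regresses
  pairwise Bray–Curtis (`sum|x-y| / sum(x+y)`) and abundance-weighted UniFrac
  (`sum_b l_b |p_b - q_b|`, optionally normalized by `sum_b l_b (p_b + q_b)`)
  on great-circle distances with a Gaussian-identity GLM, reporting slope,
  deviance explained and the Wald p-value.

* **Null-model phylogenetic structure.** For each community the mean nearest
  taxon distance `MNTD = mean_i min_{j != i} d(i, j)` is standardized against
  999 taxa-label shuffles of the phylogeny:
  `alphaNTI = -(MNTD_obs - mean(MNTD_null)) / sd(MNTD_null)`; values above +2
  indicate phylogenetic clustering (environmental filtering), below −2
  overdispersion. Between communities, `betaMNTD(k, m)` averages each taxon's
  distance to its nearest relative in the other sample, and
  `betaNTI = (obs - mean(null)) / sd(null)` below −2 means two communities
  are more related than chance — a shared filter. Welch t-tests compare the
  index distributions against their standardized nulls.

* **Functional complementarity.** KO (KEGG Orthology) abundance profiles per
  lake feed the same Bray–Curtis decay analysis, and KEGG-style modules
  (ordered blocks of alternative KOs) are called *complete or nearly
  complete* when at most one block is missing, then partitioned into
  host-only / shared / microbiome-only sets — the machine-readable Venn of
  host–microbiome functional comparison.

The package also implements the survey's OTU-table processing chain
(discard eukaryote/archaea/chloroplast/mitochondria lineages, drop taxa with
fewer than 100 total counts, remove the cyanobacterial host, rarefy every
sample to the shallowest depth, pool replicates) and a fully seeded
synthetic-data generator (Yule phylogenies, conserved Brownian niche traits,
filtered / neutral / overdispersed assembly, site geographies with or
without a planted spatial gradient, KO tables with known module content) so
every analysis stage has a parameter-recovery test. See the methods
vignette (`vignettes/bloom-microbiome-methods.Rmd`) for the model details
and design choices.

## Worked example

Simulate a nine-lake triplicate survey assembled by a shared environmental
filter (the regime the real survey inferred) and run the whole pipeline:

```r
library(interactome)

cfg <- list(seed = 42, n_null = 999,
            simulate = list(assembly_mode = "filtered",
                            spatial_mode  = "shared_optimum"),
            output_dir = "bloom_run")
report <- run_pipeline(cfg)
report
#> Bloom-microbiome analysis report
#>   taxa surviving the filter chain: 92
#>   Bray-Curtis decay : DE = 0.73%, p = 0.621
#>   UniFrac decay     : DE = 1.12%, p = 0.539
#>   mean alphaNTI = 3.97 (t = 14.60, p = 4.6e-07)
#>   mean betaNTI  = -3.34 (t = -27.09, p = 3.91e-25)
```

Reading the numbers: neither dissimilarity metric scales with distance
(deviance explained below ~1%, p ≫ 0.05 — no distance decay), while
communities are phylogenetically clustered within lakes (mean alphaNTI ≈ 4,
far above the +2 threshold) and more related *between* lakes than chance
(mean betaNTI ≈ −3, below −2): the signature of one shared environmental
filter rather than dispersal limitation. `bloom_run/` holds every stage's
output (filtered table, dissimilarity matrices, per-site alphaNTI with
classifications, betaNTI matrix, `summary.json`, and a `manifest.json`
recording seeds and parameters; the same config reruns bit-identically).

Individual stages are plain functions — `read_otu_table()`,
`apply_filter_chain()`, `bray_curtis()`, `weighted_unifrac()`,
`great_circle_distances()`, `distance_decay_glm()`, `alpha_nti()`,
`beta_nti()`, `parse_module_defs()`, `module_completeness()`,
`venn_partition()`, `functional_decay()` — and the generator is exported
(`simulate_survey()`, `simulate_ko_tables()`, ...) for building fixtures
with known ground truth.

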