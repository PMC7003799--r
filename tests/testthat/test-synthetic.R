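# Generators: Yule tree, Brownian trait, assembly modes, abundances,
# site placement, survey bundling.

test_that("Yule trees satisfy their basic contracts", {
  t2 <- simulate_tree(2, 1)
  expect_length(t2$tip.label, 2)
  expect_length(unique(t2$tip.label), 2)
  expect_error(simulate_tree(1, 1), "at least 2")
  expect_identical(ape::write.tree(simulate_tree(100, 7)),
                   ape::write.tree(simulate_tree(100, 7)))
  tr <- simulate_tree(100, 3)
  expect_length(tr$tip.label, 100)
  expect_true(all(tr$edge.length > 0))
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  d <- patristic_matrix(tr)
  expect_true(all(d[upper.tri(d)] > 0))
})

test_that("Yule crown age matches its closed-form expectation", {
  # with unit birth rate: E[age] = sum_{k=2}^{n-1} 1/k + 1/n
  n <- 20
  want <- sum(1 / (2:(n - 1))) + 1 / n
  ages <- vapply(1:500, function(s)
    max(ape::node.depth.edgelength(simulate_tree(n, 1000 + s))), numeric(1))
  se <- stats::sd(ages) / sqrt(length(ages))
  expect_lt(abs(mean(ages) - want), 4 * se)
})

test_that("Brownian trait moments and degenerate limits are correct", {
  tr <- simulate_tree(30, 11)
  # sigma -> 0: all traits collapse to the root value 0
  tiny <- evolve_trait_bm(tr, 1e-12, 2)
  expect_true(all(abs(tiny) < 1e-6))
  expect_identical(evolve_trait_bm(tr, 1, 5), evolve_trait_bm(tr, 1, 5))
  expect_error(evolve_trait_bm(tr, 0, 1), "positive")
  # tip variance = sigma^2 * root-to-tip depth (ultrametric: same for all)
  depth <- max(ape::node.depth.edgelength(tr))
  sigma <- 0.8
  tips <- vapply(1:500, function(s) evolve_trait_bm(tr, sigma, 3000 + s)[1],
                 numeric(1))
  v <- sigma^2 * depth
  se <- v * sqrt(2 / 499)      # sd of a sample variance of normals
  expect_lt(abs(var(tips) - v), 4 * se)
  # sister tips sharing ancestry correlate positively across seeds
  d <- patristic_matrix(tr)
  dd <- d; dd[upper.tri(dd, diag = TRUE)] <- Inf
  pair <- rownames(d)[arrayInd(which.min(dd), dim(dd))]
  xs <- t(vapply(1:500, function(s) evolve_trait_bm(tr, 1, 4000 + s)[pair],
                 numeric(2)))
  expect_gt(cor(xs[, 1], xs[, 2]), 0)
})

test_that("assembly modes honour their selection rules", {
  tr <- simulate_tree(40, 21)
  trait <- evolve_trait_bm(tr, 1, 22)
  # filter saturates when richness equals the pool
  all40 <- assemble_community(tr, trait, 0, 40, "filtered", seed = 1)
  expect_setequal(all40, tr$tip.label)
  expect_identical(assemble_community(tr, trait, 0, 10, "filtered", seed = 2),
                   assemble_community(tr, trait, 0, 10, "filtered", seed = 2))
  # neutral: inclusion frequency ~ richness / n_tips
  freq <- table(unlist(lapply(1:999, function(s)
    assemble_community(tr, trait, 0, 4, "neutral", seed = s))))
  p <- freq / 999
  expect_lt(max(abs(p - 0.1)), 4 * sqrt(0.1 * 0.9 / 999))
  # overdispersed with richness 2 finds the maximally distant pair
  sel2 <- assemble_community(tr, trait, trait[which.min(abs(trait))], 2,
                             "overdispersed", seed = 3)
  d <- patristic_matrix(tr)
  # brute force over all pairs containing the trait-nearest start taxon
  start <- sort(tr$tip.label)[order(abs(trait[sort(tr$tip.label)]))][1]
  expect_true(start %in% sel2)
  other <- setdiff(sel2, start)
  expect_equal(d[start, other], max(d[start, ]), tolerance = 1e-12)
  expect_error(assemble_community(tr, trait, 0, 99, "neutral"), "richness")
})

test_that("abundance draws are deterministic with the expected shape", {
  one <- sample_abundances("solo", 500, 1, seed = 5)
  expect_equal(sum(one), unname(one["solo"]))
  expect_gte(sum(one), 1)
  expect_identical(sample_abundances(letters[1:5], 100, 1, 7),
                   sample_abundances(letters[1:5], 100, 1, 7))
  expect_error(sample_abundances(character(0), 100, 1, 1), "empty")
  # steeper lognormal -> more unequal counts (Gini over 100 seeds)
  gini <- function(x) {
    x <- sort(x)
    n <- length(x)
    sum((2 * seq_len(n) - n - 1) * x) / (n * sum(x))
  }
  g_flat <- vapply(1:100, function(s)
    gini(sample_abundances(letters[1:20], 5000, 0.1, s)), numeric(1))
  g_steep <- vapply(1:100, function(s)
    gini(sample_abundances(letters[1:20], 5000, 2.0, s)), numeric(1))
  expect_gt(mean(g_steep), mean(g_flat))
})

test_that("site placement respects ranges and plants gradients only when asked", {
  expect_error(place_sites(1, "shared_optimum", 1), "two sites")
  shared <- place_sites(9, "shared_optimum", seed = 2)
  expect_equal(var(shared$optima), 0)
  expect_true(all(shared$geo$latitude >= -90 & shared$geo$latitude <= 90))
  expect_true(all(shared$geo$longitude >= -180 & shared$geo$longitude <= 180))
  # autocorrelated: |optimum difference| rises with distance (pooled seeds)
  cors <- vapply(1:20, function(s) {
    ps <- place_sites(9, "autocorrelated", seed = s)
    d <- great_circle_distances(ps$geo)
    dopt <- abs(outer(ps$optima, ps$optima, "-"))
    ut <- upper.tri(d)
    cor(d[ut], dopt[ut])
  }, numeric(1))
  expect_gt(mean(cors), 0)
})

test_that("surveys are deterministic, internally consistent bundles", {
  cfg <- assembly_config(n_tips = 60, n_sites = 4, richness_per_site = 15,
                         seed = 12)
  tru <- simulate_survey(cfg)
  tru2 <- simulate_survey(cfg)
  expect_identical(tru$communities, tru2$communities)
  expect_identical(ape::write.tree(tru$tree), ape::write.tree(tru2$tree))
  # every community taxon is a tree tip; counts non-negative
  expect_true(all(colnames(tru$communities) %in% tru$tree$tip.label))
  expect_true(all(tru$communities >= 0))
  # replicates of a site share its taxon pool
  for (s in names(tru$site_taxa)) {
    reps <- names(tru$replicate_map)[tru$replicate_map == s]
    for (r in reps) {
      present <- colnames(tru$communities)[tru$communities[r, ] > 0]
      expect_true(all(present %in% tru$site_taxa[[s]]))
    }
  }
  expect_equal(nrow(tru$communities), 12)      # 4 sites x 3 replicates
  expect_length(validate_inputs(tru$communities, tree = tru$tree,
                                geo = tru$geo, mapping = tru$replicate_map), 0)
})

test_that("survey bundles round-trip through the on-disk formats", {
  cfg <- assembly_config(n_tips = 40, n_sites = 3, richness_per_site = 10,
                         seed = 6)
  tru <- simulate_survey(cfg)
  dir <- withr::local_tempdir()
  paths <- write_survey(tru, dir)
  expect_identical(read_otu_table(paths["otu"]), tru$communities)
  expect_equal(read_coordinates(paths["coordinates"]), tru$geo)
  back_tree <- ape::read.tree(paths["tree"])
  expect_setequal(back_tree$tip.label, tru$tree$tip.label)
  expect_equal(patristic_matrix(back_tree)[colnames(tru$communities),
                                           colnames(tru$communities)],
               patristic_matrix(tru$tree)[colnames(tru$communities),
                                          colnames(tru$communities)],
               tolerance = 1e-8)
  tax <- read_taxonomy(paths["taxonomy"])
  expect_setequal(tax$taxon_id, tru$tree$tip.label)
  expect_true(any(grepl("Cyanobacteria", tax$lineage)))
  truth <- jsonlite::read_json(paths["truth"])
  expect_equal(truth$config$seed, cfg$seed)
})

test_that("the filter fixture plants exactly what the chain must remove", {
  fx <- simulate_filter_fixture(31)
  expect_true(all(unlist(fx$planted$excluded) %in% colnames(fx$table)))
  expect_true(all(colSums(fx$table[, fx$planted$low_count, drop = FALSE]) < 100))
  lin <- fx$taxonomy$lineage[match(fx$planted$cyanobacteria,
                                   fx$taxonomy$taxon_id)]
  expect_true(all(grepl("Cyanobacteria", lin)))
})
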