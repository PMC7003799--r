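# MNTD/betaMNTD, the taxa-shuffle null models, t-test, classification.

test_that("patristic distances match the root-path oracle", {
  tree2 <- ape::read.tree(text = "(a:0.4,b:1.1);")
  expect_equal(patristic_matrix(tree2)["a", "b"], 1.5, tolerance = 1e-12)
  # balanced ultrametric 4-tip tree: cherry mates at 2*(h - t)
  bal <- ape::read.tree(text = "((a:1,b:1):2,(c:1,d:1):2);")
  pm <- patristic_matrix(bal)
  expect_equal(pm["a", "b"], 2, tolerance = 1e-12)
  expect_equal(pm["a", "c"], 6, tolerance = 1e-12)
  for (s in 1:5) {
    tr <- simulate_tree(10, 40 + s)
    expect_equal(patristic_matrix(tr),
                 brute_patristic(tr)[tr$tip.label, tr$tip.label],
                 tolerance = 1e-12)
  }
})

test_that("MNTD matches hand cases and the double-loop oracle", {
  tree2 <- ape::read.tree(text = "(a:0.4,b:1.1);")
  d2 <- patristic_matrix(tree2)
  expect_equal(mntd(c(a = 1, b = 1), d2), 1.5, tolerance = 1e-12)
  # star tree with unit branches: every nearest distance is 2
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1,e:1);")
  ds <- patristic_matrix(star)
  for (k in 2:5) {
    comm <- setNames(rep(1, k), letters[1:k])
    expect_equal(mntd(comm, ds), 2, tolerance = 1e-12)
  }
  expect_error(mntd(c(a = 1), d2), "fewer than two")
  # random fixtures against the brute-force oracle, both weightings
  for (s in 1:10) {
    tr <- simulate_tree(12, 60 + s)
    d <- patristic_matrix(tr)
    set.seed(s)
    comm <- setNames(rpois(12, 2), tr$tip.label)
    if (sum(comm > 0) < 2) comm[1:2] <- 1
    expect_equal(mntd(comm, d), brute_mntd(comm, d), tolerance = 1e-12)
    expect_equal(mntd(comm, d, abundance_weighted = TRUE),
                 brute_mntd(comm, d, abundance_weighted = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("betaMNTD matches trivial cases and the double-loop oracle", {
  tr <- simulate_tree(12, 77)
  taxa <- sort(tr$tip.label)
  d <- patristic_matrix(tr)
  # identical samples -> 0; singleton samples -> their patristic distance
  tab <- matrix(1L, 2, 12, dimnames = list(c("s1", "s2"), taxa))
  expect_equal(beta_mntd(tab, tr)["s1", "s2"], 0, tolerance = 1e-12)
  singles <- matrix(0L, 2, 12, dimnames = list(c("s1", "s2"), taxa))
  singles[1, 1] <- 1L; singles[2, 5] <- 1L
  expect_equal(beta_mntd(singles, tr)["s1", "s2"], d[taxa[1], taxa[5]],
               tolerance = 1e-12)
  for (s in 1:10) {
    tr <- simulate_tree(14, 90 + s)
    set.seed(s)
    tab <- matrix(rpois(2 * 14, 1.5), 2,
                  dimnames = list(c("s1", "s2"), sort(tr$tip.label)))
    tab[, 1:2] <- 1L   # keep both samples non-empty
    storage.mode(tab) <- "integer"
    for (w in c(FALSE, TRUE)) {
      got <- beta_mntd(tab, tr, abundance_weighted = w)["s1", "s2"]
      want <- brute_beta_mntd(tab["s1", ], tab["s2", ], patristic_matrix(tr), w)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("alphaNTI flags permutation-invariant communities as undefined", {
  tr <- simulate_tree(10, 5)
  tab <- matrix(1L, 1, 10, dimnames = list("all", sort(tr$tip.label)))
  a <- alpha_nti(tab, tr, n_null = 25, seed = 1)
  expect_true(is.na(a$nti))
  expect_equal(a$reason, "zero null variance")
  expect_equal(a$classification, "undefined")
})

test_that("the two closest tips form a strongly clustered community", {
  tr <- simulate_tree(50, 8)
  d <- patristic_matrix(tr)
  dd <- d; dd[upper.tri(dd, diag = TRUE)] <- Inf
  pair <- arrayInd(which.min(dd), dim(dd))
  taxa <- rownames(d)[as.vector(pair)]
  tab <- matrix(0L, 1, 50, dimnames = list("s", rownames(d)))
  tab[1, taxa] <- 1L
  a <- alpha_nti(tab, tr, n_null = 999, seed = 3)
  expect_gt(a$nti, 2)
  expect_equal(a$classification, "clustered")
  # observed MNTD is the distribution minimum, so the index is positive
  expect_equal(a$observed, min(d[d > 0]))
})

test_that("betaNTI separates joint-clade pairs from disjoint-clade pairs", {
  tr <- simulate_tree(100, 13)
  # two disjoint true clades of moderate size, as far apart as possible
  clades <- ape::prop.part(tr)
  tipsets <- lapply(clades, function(idx) tr$tip.label[idx])
  ok <- which(lengths(tipsets) >= 12 & lengths(tipsets) <= 30)
  d <- patristic_matrix(tr)
  best <- c(NA, NA); best_d <- -Inf
  for (i in ok) for (j in ok) {
    if (i < j && !length(intersect(tipsets[[i]], tipsets[[j]]))) {
      gap <- min(d[tipsets[[i]], tipsets[[j]]])
      if (gap > best_d) { best_d <- gap; best <- c(i, j) }
    }
  }
  near <- tipsets[[best[1]]]; far <- tipsets[[best[2]]]
  taxa <- sort(tr$tip.label)
  tab <- matrix(0L, 4, 100, dimnames = list(c("n1", "n2", "f1", "f2"), taxa))
  set.seed(4)
  tab["n1", sample(near, 8)] <- 1L
  tab["n2", sample(near, 8)] <- 1L
  tab["f1", sample(far, 8)] <- 1L
  tab["f2", sample(far, 8)] <- 1L
  b <- beta_nti(tab, tr, n_null = 999, seed = 6)
  expect_lt(b$nti["n1", "n2"], -2)   # same clade: more related than chance
  expect_lt(b$nti["f1", "f2"], -2)
  expect_gt(b$nti["n1", "f1"], 2)    # disjoint distant clades: less related
  # identical full-composition samples have an undefined index
  tab2 <- matrix(1L, 2, 100, dimnames = list(c("a", "b"), taxa))
  b2 <- beta_nti(tab2, tr, n_null = 25, seed = 2)
  expect_true(is.na(b2$nti["a", "b"]))
})

test_that("indices are invariant under uniform branch-length rescaling", {
  tru <- simulate_survey(assembly_config(n_tips = 60, n_sites = 4,
                                         richness_per_site = 15, seed = 31))
  pooled <- pool_replicates(tru$communities, tru$replicate_map)
  tr2 <- tru$tree
  tr2$edge.length <- tr2$edge.length * 7.3
  a1 <- alpha_nti(pooled, tru$tree, n_null = 199, seed = 9)
  a2 <- alpha_nti(pooled, tr2, n_null = 199, seed = 9)
  expect_equal(a1$nti, a2$nti, tolerance = 1e-9)
  b1 <- beta_nti(pooled, tru$tree, n_null = 99, seed = 9)
  b2 <- beta_nti(pooled, tr2, n_null = 99, seed = 9)
  expect_equal(b1$nti, b2$nti, tolerance = 1e-9)
})

test_that("null replicates only relabel taxa and runs are bit-reproducible", {
  tru <- simulate_survey(assembly_config(n_tips = 50, n_sites = 3,
                                         richness_per_site = 12, seed = 17))
  pooled <- pool_replicates(tru$communities, tru$replicate_map)
  a1 <- alpha_nti(pooled, tru$tree, n_null = 99, seed = 42)
  a2 <- alpha_nti(pooled, tru$tree, n_null = 99, seed = 42)
  expect_identical(a1, a2)
  b1 <- beta_nti(pooled, tru$tree, n_null = 49, seed = 42)
  b2 <- beta_nti(pooled, tru$tree, n_null = 49, seed = 42)
  expect_identical(b1$nti, b2$nti)
  # richness never changes under the null: observed and null MNTD for a
  # sample containing k of n tips stay within the patristic range
  nulls <- attr(a1, "nulls")
  expect_equal(dim(nulls), c(3, 99))
  d <- patristic_matrix(tru$tree)
  expect_true(all(nulls >= min(d[d > 0]) & nulls <= max(d)))
})

test_that("alphaNTI agrees with the independent picante implementation", {
  skip_if_not_installed("picante")
  tru <- simulate_survey(assembly_config(n_tips = 40, n_sites = 4,
                                         richness_per_site = 12, seed = 23))
  pooled <- pool_replicates(tru$communities, tru$replicate_map)
  d <- patristic_matrix(tru$tree)
  # observed MNTD identical to picante::mntd
  got <- vapply(rownames(pooled), function(s) mntd(pooled[s, ], d), numeric(1))
  want <- picante::mntd(pooled, d[colnames(pooled), colnames(pooled)])
  expect_equal(unname(got), want, tolerance = 1e-12)
  gotw <- vapply(rownames(pooled), function(s)
    mntd(pooled[s, ], d, abundance_weighted = TRUE), numeric(1))
  wantw <- picante::mntd(pooled, d[colnames(pooled), colnames(pooled)],
                         abundance.weighted = TRUE)
  expect_equal(unname(gotw), wantw, tolerance = 1e-12)
  # standardized index agrees in distribution (same null model, different RNG)
  ses <- picante::ses.mntd(pooled, d, null.model = "taxa.labels", runs = 499)
  ours <- alpha_nti(pooled, tru$tree, n_null = 499, seed = 77)
  expect_equal(ours$nti, -ses$mntd.obs.z, tolerance = 0.35)
})

test_that("index t-test holds its type-I error and detects shifts", {
  set.seed(19)
  rej <- mean(replicate(1000, index_t_test(rnorm(20), rnorm(50))$p < 0.05))
  expect_lt(abs(rej - 0.05), 0.02)
  same <- c(1.2, -0.4, 0.8, 2.2)
  expect_equal(index_t_test(same, same)$t, 0, tolerance = 1e-12)
  expect_lt(index_t_test(rnorm(30) + 5, rnorm(30))$p, 0.001)
  expect_error(index_t_test(1, c(1, 2)), "at least two")
})

test_that("structure classification uses strict +/-2 boundaries", {
  expect_equal(classify_structure(c(4.64, 0, -2, 2, -2.01, NA)),
               c("clustered", "random", "random", "random", "overdispersed",
                 "undefined"))
  expect_equal(classify_structure(1.5, threshold = 1), "clustered")
})
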