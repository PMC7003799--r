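# Synthetic-data generator: Yule phylogenies, Brownian niche traits,
# trait-filtered / neutral / limiting-similarity community assembly,
# site geographies with or without a spatial gradient, replicate abundance
# sampling, and KO tables with known module content. Every downstream
# statistic has a known ground truth here.

#' Assembly configuration for the synthetic survey
#'
#' Bundles the generator parameters. Defaults emulate a multi-lake bloom
#' survey: 9 sites sampled in triplicate, a few hundred candidate taxa, a few
#' dozen taxa per site, environmental filtering on a Brownian niche trait,
#' and no spatial structure in the site optima.
#'
#' @param n_tips Number of tips of the regional-pool phylogeny.
#' @param n_sites Number of sites (lakes).
#' @param n_replicates Replicate samples per site (default 3).
#' @param richness_per_site Taxa per site community.
#' @param assembly_mode `"filtered"`, `"neutral"` or `"overdispersed"`.
#' @param trait_sigma Brownian-motion rate of the niche trait (per unit
#'   branch length).
#' @param filter_width Half-width of the trait window used by filtered
#'   assembly (trait units); small values give strong phylogenetic
#'   clustering.
#' @param niche_conservatism Pagel's delta applied to the tree before the
#'   trait evolves (see [delta_transform()]); values below 1 concentrate
#'   trait divergence on basal branches, making the niche phylogenetically
#'   conserved so that trait filtering selects coherent clades. Default
#'   0.15 (strong conservatism, the regime in which filtering produces the
#'   clustered alphaNTI/betaNTI pattern).
#' @param spatial_mode `"shared_optimum"` (all sites share one trait
#'   optimum; no distance-decay ground truth) or `"autocorrelated"` (optima
#'   follow a smooth latitudinal gradient; decay present).
#' @param depth_mean Expected reads per replicate sample.
#' @param abundance_lognormal_sigma Log-normal sd of per-taxon expected
#'   abundances.
#' @param seed Integer seed; the whole survey is a pure function of
#'   (config, seed).
#' @return List of class `assembly_config`.
#' @export
assembly_config <- function(n_tips = 300, n_sites = 9, n_replicates = 3,
                            richness_per_site = 60,
                            assembly_mode = c("filtered", "neutral",
                                              "overdispersed"),
                            trait_sigma = 1, filter_width = 0.3,
                            niche_conservatism = 0.15,
                            spatial_mode = c("shared_optimum", "autocorrelated"),
                            depth_mean = 20000,
                            abundance_lognormal_sigma = 1.5, seed = 1) {
  assembly_mode <- match.arg(assembly_mode)
  spatial_mode <- match.arg(spatial_mode)
  stopifnot(n_tips >= 2, n_sites >= 2, n_replicates >= 1,
            richness_per_site >= 2, richness_per_site <= n_tips,
            trait_sigma > 0, filter_width > 0, niche_conservatism > 0,
            niche_conservatism <= 1, depth_mean >= 1,
            abundance_lognormal_sigma > 0)
  structure(list(n_tips = n_tips, n_sites = n_sites,
                 n_replicates = n_replicates,
                 richness_per_site = richness_per_site,
                 assembly_mode = assembly_mode, trait_sigma = trait_sigma,
                 filter_width = filter_width,
                 niche_conservatism = niche_conservatism,
                 spatial_mode = spatial_mode,
                 depth_mean = depth_mean,
                 abundance_lognormal_sigma = abundance_lognormal_sigma,
                 seed = as.integer(seed)),
            class = "assembly_config")
}

#' Simulate a pure-birth (Yule) phylogeny
#'
#' Grows a tree under a constant-rate pure-birth process (unit birth rate):
#' starting from two crown lineages, waiting times between speciations are
#' exponential with rate `k` while `k` lineages are extant and the splitting
#' lineage is uniform; after the pool reaches `n_tips` lineages the tree is
#' extended by one further exponential waiting time so every pendant branch
#' is positive. The tree is ultrametric with expected crown age
#' `sum(1/(2:(n-1))) + 1/n`.
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Integer seed.
#' @return Rooted ultrametric `phylo` with tips `otu0001, otu0002, ...`.
#' @export
simulate_tree <- function(n_tips, seed) {
  if (n_tips < 2) stop("n_tips must be at least 2", call. = FALSE)
  with_seed(seed, {
    # internal nodes: creation time and parent internal node (0 = crown root)
    int_time <- 0
    int_parent <- 0L
    lin_parent <- c(1L, 1L)          # active lineages -> parent internal node
    t <- 0
    k <- 2L
    while (k < n_tips) {
      t <- t + stats::rexp(1, rate = k)
      i <- sample.int(k, 1)
      int_time <- c(int_time, t)
      int_parent <- c(int_parent, lin_parent[i])
      new_id <- length(int_time)
      lin_parent[i] <- new_id
      lin_parent <- c(lin_parent, new_id)
      k <- k + 1L
    }
    t_end <- t + stats::rexp(1, rate = n_tips)
    n <- as.integer(n_tips)
    node_of <- function(int) n + int
    tip_edges <- cbind(node_of(lin_parent), seq_len(n))
    tip_lens <- t_end - int_time[lin_parent]
    if (length(int_time) > 1) {
      ii <- 2:length(int_time)
      int_edges <- cbind(node_of(int_parent[ii]), node_of(ii))
      int_lens <- int_time[ii] - int_time[int_parent[ii]]
    } else {
      int_edges <- matrix(integer(0), ncol = 2)
      int_lens <- numeric(0)
    }
    phy <- list(edge = rbind(int_edges, tip_edges),
                edge.length = c(int_lens, tip_lens),
                tip.label = sprintf("otu%04d", seq_len(n)),
                Nnode = n - 1L)
    storage.mode(phy$edge) <- "integer"
    class(phy) <- "phylo"
    stats::reorder(phy, "cladewise")
  })
}

#' Evolve a niche trait by Brownian motion
#'
#' Simulates a trait along the tree from a root value of 0: each branch adds
#' an independent normal increment with sd `sigma * sqrt(branch length)`, so
#' a tip's marginal variance is `sigma^2` times its root-to-tip path length
#' and covariance between tips equals `sigma^2` times shared path length.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param sigma Brownian rate (> 0).
#' @param seed Integer seed.
#' @return Named numeric vector of tip trait values.
#' @export
evolve_trait_bm <- function(tree, sigma, seed) {
  assert_phylo(tree)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  cw <- stats::reorder(tree, "cladewise")   # parents precede children
  n_tip <- length(cw$tip.label)
  with_seed(seed, {
    steps <- stats::rnorm(nrow(cw$edge), 0, sigma * sqrt(cw$edge.length))
    x <- numeric(n_tip + cw$Nnode)
    for (e in seq_len(nrow(cw$edge)))
      x[cw$edge[e, 2]] <- x[cw$edge[e, 1]] + steps[e]
    stats::setNames(x[seq_len(n_tip)], cw$tip.label)
  })
}

#' Pagel's delta branch-length transform
#'
#' Rescales node depths of an ultrametric tree to `T * (t/T)^delta` (T = tree
#' height). `delta < 1` concentrates divergence on basal branches: a trait
#' evolved on the transformed tree is phylogenetically conserved (clade
#' members share similar values); `delta = 1` is the identity. Root-to-tip
#' depths are unchanged, so the marginal tip variance of a Brownian trait is
#' unaffected.
#'
#' @param tree Ultrametric `phylo`.
#' @param delta Transform exponent in `(0, 1]`.
#' @return `phylo` with rescaled branch lengths.
#' @export
delta_transform <- function(tree, delta) {
  assert_phylo(tree)
  stopifnot(delta > 0, delta <= 1)
  if (delta == 1) return(tree)
  dep <- ape::node.depth.edgelength(tree)
  h <- max(dep)
  f <- function(t) h * (t / h)^delta
  out <- tree
  out$edge.length <- pmax(f(dep[tree$edge[, 2]]) - f(dep[tree$edge[, 1]]), 0)
  out
}

#' Assemble one site community
#'
#' Selects `richness` taxa from the regional pool under one of three assembly
#' models that map onto the interpretive categories of null-model community
#' phylogenetics:
#' * `filtered` — environmental filtering with ecological drift: the
#'   candidate pool is every taxon whose trait lies within `filter_width` of
#'   the site optimum (enlarged, when the window holds fewer than twice the
#'   target richness, to the `2 * richness` taxa nearest the optimum so the
#'   draw is never degenerate), and the community is a uniform draw of
#'   `richness` taxa from that pool. Narrow windows on a conserved trait
#'   select coherent clades, yielding phylogenetically clustered communities
#'   that still vary from site to site.
#' * `neutral` — uniform sampling without replacement from the whole pool.
#' * `overdispersed` — limiting similarity: greedy max-min patristic
#'   selection seeded by the taxon whose trait is nearest the optimum (ties
#'   broken by taxon label order).
#'
#' @param tree Regional-pool phylogeny.
#' @param trait Named tip trait vector ([evolve_trait_bm()]).
#' @param optimum Site trait optimum.
#' @param richness Number of taxa to select (<= number of tips).
#' @param mode Assembly mode (see above).
#' @param filter_width Trait-window half-width (filtered mode).
#' @param seed Integer seed.
#' @param dist Optional precomputed patristic matrix (overdispersed mode).
#' @return Character vector of selected taxon labels (sorted).
#' @export
assemble_community <- function(tree, trait, optimum, richness,
                               mode = c("filtered", "neutral", "overdispersed"),
                               filter_width = 0.3, seed = 1, dist = NULL) {
  mode <- match.arg(mode)
  assert_phylo(tree)
  taxa <- sort(tree$tip.label)
  trait <- trait[taxa]
  if (richness > length(taxa))
    stop("richness exceeds the number of tips", call. = FALSE)
  if (mode == "filtered") {
    dtr <- abs(trait - optimum)
    pool <- taxa[dtr <= filter_width]
    if (length(pool) < 2 * richness)
      pool <- taxa[order(dtr, taxa)][seq_len(min(length(taxa), 2 * richness))]
    sel <- with_seed(seed, sample(pool, richness))
  } else if (mode == "neutral") {
    sel <- with_seed(seed, sample(taxa, richness))
  } else {
    if (is.null(dist)) dist <- patristic_matrix(tree)
    dist <- dist[taxa, taxa]
    start <- taxa[order(abs(trait - optimum), taxa)][1]
    sel <- start
    while (length(sel) < richness) {
      rest <- setdiff(taxa, sel)
      mind <- apply(dist[rest, sel, drop = FALSE], 1, min)
      sel <- c(sel, rest[order(-mind, rest)][1])  # max-min, ties by label
    }
  }
  sort(sel)
}

#' Draw replicate read counts for a community
#'
#' Per-taxon expected abundances are log-normal (`meanlog = 0`,
#' `sdlog = lognormal_sigma`); the sample depth is Poisson around
#' `depth_mean` (at least 1) and counts are multinomial at that depth.
#'
#' @param taxa Non-empty character vector of taxon labels.
#' @param depth_mean Expected total reads.
#' @param lognormal_sigma Log-normal sd of expected abundances; larger values
#'   give steeper rank-abundance curves.
#' @param seed Integer seed.
#' @param bias Optional non-negative multiplier on each taxon's expected
#'   abundance (recycled over `taxa`); used by filtered assembly to favour
#'   taxa near the site optimum.
#' @return Named integer count vector over `taxa` (total >= 1).
#' @export
sample_abundances <- function(taxa, depth_mean, lognormal_sigma, seed,
                              bias = 1) {
  if (length(taxa) == 0) stop("taxa set is empty", call. = FALSE)
  with_seed(seed, {
    lambda <- stats::rlnorm(length(taxa), meanlog = 0,
                            sdlog = lognormal_sigma) * bias
    depth <- max(1L, stats::rpois(1, depth_mean))
    counts <- as.integer(stats::rmultinom(1, depth, prob = lambda))
    stats::setNames(counts, taxa)
  })
}

#' Place sites on the globe
#'
#' Coordinates are uniform on the sphere (longitude uniform, latitude
#' arcsine-distributed). Under `shared_optimum` every site has the same trait
#' optimum (0), so there is no distance-decay ground truth. Under
#' `autocorrelated` the optima are gradient positions in `(0, 1)` along the
#' dominant spatial axis of the layout (the first principal coordinate of
#' the great-circle distance matrix, rank-mapped to the unit interval), so
#' nearby sites get similar optima and a positive decay slope is planted;
#' [simulate_survey()] maps these positions onto the niche-trait scale
#' through the realized trait quantile function.
#'
#' @param n_sites Number of sites (>= 2).
#' @param spatial_mode `"shared_optimum"` or `"autocorrelated"`.
#' @param seed Integer seed.
#' @return List with `geo` (site coordinates data frame) and `optima`
#'   (named numeric vector; trait units under `shared_optimum`, gradient
#'   positions under `autocorrelated`).
#' @export
place_sites <- function(n_sites, spatial_mode = c("shared_optimum",
                                                  "autocorrelated"), seed) {
  spatial_mode <- match.arg(spatial_mode)
  if (n_sites < 2) stop("need at least two sites", call. = FALSE)
  with_seed(seed, {
    lon <- stats::runif(n_sites, -180, 180)
    lat <- asin(stats::runif(n_sites, -1, 1)) * 180 / pi
    geo <- data.frame(site = sprintf("site%02d", seq_len(n_sites)),
                      latitude = lat, longitude = lon,
                      stringsAsFactors = FALSE)
    optima <- if (spatial_mode == "shared_optimum") {
      rep(0, n_sites)
    } else {
      pc1 <- stats::cmdscale(great_circle_distances(geo), k = 1)[, 1]
      (rank(pc1) - 0.5) / n_sites
    }
    list(geo = geo, optima = stats::setNames(optima, geo$site))
  })
}

#' Simulate a full bloom-microbiome survey
#'
#' Ties the generators together: one regional phylogeny, a Brownian niche
#' trait, site placements and optima, one assembled taxon pool per site, and
#' per-replicate abundance redraws from the site pool (replicates of a site
#' share its taxa, mirroring triplicate field samples). All stage seeds are
#' derived deterministically from `config$seed`.
#'
#' @param config An [assembly_config()].
#' @return List of class `synthetic_survey`: `tree`, `trait`, `geo`,
#'   `site_optima`, `site_taxa`, `communities` (samples x taxa count matrix,
#'   sample ids `siteXX_rep`), `replicate_map` (sample -> site), and
#'   `config`.
#' @export
simulate_survey <- function(config) {
  stopifnot(inherits(config, "assembly_config"))
  seed <- config$seed
  tree <- simulate_tree(config$n_tips, derive_seed(seed, "tree"))
  trait <- evolve_trait_bm(delta_transform(tree, config$niche_conservatism),
                           config$trait_sigma, derive_seed(seed, "trait"))
  sites <- place_sites(config$n_sites, config$spatial_mode,
                       derive_seed(seed, "sites"))
  # gradient positions (autocorrelated mode) are mapped onto the realized
  # niche-trait scale so the planted turnover spans the trait distribution
  optima <- if (config$spatial_mode == "autocorrelated")
    stats::setNames(stats::quantile(trait, sites$optima, names = FALSE),
                    names(sites$optima))
  else sites$optima
  dist <- if (config$assembly_mode == "overdispersed") patristic_matrix(tree)
          else NULL
  site_taxa <- lapply(seq_len(config$n_sites), function(s)
    assemble_community(tree, trait, optima[s],
                       config$richness_per_site, config$assembly_mode,
                       config$filter_width,
                       derive_seed(seed, paste0("assembly", s)), dist))
  names(site_taxa) <- sites$geo$site
  sample_ids <- character(0)
  rows <- list()
  map <- character(0)
  for (s in seq_len(config$n_sites)) {
    # filtered assembly also shapes abundances: expected abundance decays
    # with trait distance from the optimum (kernel width 2 * filter_width)
    bias <- if (config$assembly_mode == "filtered")
      exp(-(trait[site_taxa[[s]]] - optima[s])^2 /
            (2 * (2 * config$filter_width)^2))
    else 1
    for (r in seq_len(config$n_replicates)) {
      id <- sprintf("%s_rep%d", sites$geo$site[s], r)
      counts <- sample_abundances(site_taxa[[s]], config$depth_mean,
                                  config$abundance_lognormal_sigma,
                                  derive_seed(seed, paste0("abund", s, "_", r)),
                                  bias = bias)
      rows[[id]] <- counts
      sample_ids <- c(sample_ids, id)
      map[id] <- sites$geo$site[s]
    }
  }
  communities <- matrix(0L, nrow = length(sample_ids), ncol = config$n_tips,
                        dimnames = list(sample_ids, sort(tree$tip.label)))
  for (id in sample_ids)
    communities[id, names(rows[[id]])] <- rows[[id]]
  communities <- communities[, colSums(communities) > 0, drop = FALSE]
  structure(list(tree = tree, trait = trait, geo = sites$geo,
                 site_optima = optima, site_taxa = site_taxa,
                 communities = communities, replicate_map = map,
                 config = config),
            class = "synthetic_survey")
}

#' Synthetic taxonomy for a phylogeny
#'
#' Assigns semicolon lineages (`Domain;Phylum;Class;Order;Family;Genus`) to
#' the tips: one clade of roughly `cyano_fraction` of the tips is labelled as
#' Cyanobacteria (so the host-removal filter has something to remove); the
#' remaining tips are spread clade-wise over `n_classes` synthetic bacterial
#' classes.
#'
#' @param tree `phylo` object.
#' @param seed Integer seed.
#' @param n_classes Number of non-cyanobacterial class labels.
#' @param cyano_fraction Target fraction of tips in the Cyanobacteria clade.
#' @return Taxonomy data frame (`taxon_id`, `lineage`, `confidence`).
#' @export
simulate_taxonomy <- function(tree, seed, n_classes = 35, cyano_fraction = 0.2) {
  assert_phylo(tree)
  n_tip <- length(tree$tip.label)
  # descendant tip sets of every internal node
  desc <- descendant_tips(tree)
  sizes <- lengths(desc)
  target <- max(2, round(cyano_fraction * n_tip))
  cyano_node <- which.min(abs(sizes - target))
  cyano <- desc[[cyano_node]]
  others <- setdiff(tree$tip.label, cyano)
  class_names <- sprintf("SynClass%02d", seq_len(n_classes))
  cls <- with_seed(seed, {
    # clade-ish assignment: order remaining tips by tree order, chunk them
    ord <- others[order(match(others, tree$tip.label))]
    stats::setNames(class_names[ceiling(seq_along(ord) / length(ord) *
                                          n_classes)], ord)
  })
  lineage <- character(n_tip)
  names(lineage) <- tree$tip.label
  lineage[cyano] <- paste("Bacteria", "Cyanobacteria", "Oxyphotobacteria",
                          "Chroococcales", "Microcystaceae", "SynGenusC",
                          sep = ";")
  lineage[others] <- paste("Bacteria", "SynPhylum", cls[others],
                           "SynOrder", "SynFamily",
                           paste0("SynGenus_", cls[others]), sep = ";")
  data.frame(taxon_id = tree$tip.label, lineage = unname(lineage[tree$tip.label]),
             confidence = 1, stringsAsFactors = FALSE)
}

# Tip labels descending from each internal node (list indexed by
# node - n_tip).
descendant_tips <- function(tree) {
  po <- stats::reorder(tree, "postorder")
  n_tip <- length(po$tip.label)
  sets <- vector("list", n_tip + po$Nnode)
  for (i in seq_len(n_tip)) sets[[i]] <- po$tip.label[i]
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets[(n_tip + 1):(n_tip + po$Nnode)]
}

#' Fixture with planted removable taxa for the filter chain
#'
#' Builds a small survey and plants, with known identity: taxa whose lineage
#' is Chloroplast, Mitochondria, Eukaryota or Archaea; taxa with total count
#' below 100; and a labelled Cyanobacteria clade — exactly the taxa the
#' standard filter chain must remove.
#'
#' @param seed Integer seed.
#' @param n_sites,n_replicates Survey shape.
#' @return List with `table`, `taxonomy`, `tree`, `replicate_map`, `geo`, and
#'   `planted` (named list of the planted taxon id sets, plus
#'   `expected_kept`).
#' @export
simulate_filter_fixture <- function(seed, n_sites = 3, n_replicates = 3) {
  cfg <- assembly_config(n_tips = 80, n_sites = n_sites,
                         n_replicates = n_replicates, richness_per_site = 30,
                         assembly_mode = "neutral", depth_mean = 5000,
                         seed = seed)
  truth <- simulate_survey(cfg)
  tax <- simulate_taxonomy(truth$tree, derive_seed(seed, "tax"),
                           n_classes = 10, cyano_fraction = 0.2)
  table <- truth$communities
  taxa <- colnames(table)
  cyano <- tax$taxon_id[grepl(";Cyanobacteria;", tax$lineage)]
  pool <- setdiff(taxa, cyano)
  planted_excl <- with_seed(derive_seed(seed, "plant"), {
    excl <- sample(pool, 8)
    split(excl, rep(c("eukaryota", "archaea", "chloroplast", "mitochondria"),
                    each = 2))
  })
  for (term in names(planted_excl)) {
    ids <- planted_excl[[term]]
    lin <- switch(term,
      eukaryota = "Eukaryota;SynAlgae;SynChlorophyceae;o;f;g",
      archaea = "Archaea;Euryarchaeota;SynMethano;o;f;g",
      chloroplast = "Bacteria;Cyanobacteria;Oxyphotobacteria;Chloroplast;f;g",
      mitochondria = "Bacteria;Proteobacteria;Alphaproteobacteria;Rickettsiales;Mitochondria;g")
    tax$lineage[tax$taxon_id %in% ids] <- lin
  }
  # plant low-count taxa: scale some remaining taxa's counts below 100 total
  rest <- setdiff(pool, unlist(planted_excl))
  low <- with_seed(derive_seed(seed, "low"), sample(rest, 5))
  for (tx in low) {
    tot <- sum(table[, tx])
    if (tot >= 100) {
      v <- table[, tx]
      table[, tx] <- as.integer(floor(v * (99 / tot)))
    }
  }
  kept <- setdiff(taxa, c(cyano, unlist(planted_excl), low))
  kept <- kept[colSums(table[, kept, drop = FALSE]) >= 100]
  list(table = table, taxonomy = tax, tree = truth$tree,
       replicate_map = truth$replicate_map, geo = truth$geo,
       planted = list(excluded = planted_excl, low_count = low,
                      cyanobacteria = intersect(cyano, taxa),
                      expected_kept = sort(kept)))
}

#' Simulate host and microbiome KO tables
#'
#' Builds two KO abundance tables (KOs x sites) from three disjoint module
#' collections: the host table carries every KO of the host and shared
#' modules, the microbiome table every KO of the microbiome and shared
#' modules. Abundances are log-normal; `noise` is an independent per-KO,
#' per-site dropout probability. With `noise = 0` the downstream
#' [venn_partition()] of complete modules recovers the three input lists
#' exactly (for modules with at least three blocks).
#'
#' @param host_modules,microbiome_modules,shared_modules Named lists of
#'   module definitions with pairwise-disjoint module ids.
#' @param n_sites Number of site columns.
#' @param noise Dropout probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return List with `host` and `microbiome` KO matrices.
#' @export
simulate_ko_tables <- function(host_modules, microbiome_modules, shared_modules,
                               n_sites, noise = 0, seed = 1) {
  ids <- c(names(host_modules), names(microbiome_modules), names(shared_modules))
  if (anyDuplicated(ids))
    stop("module ids overlap across the host/microbiome/shared lists",
         call. = FALSE)
  stopifnot(noise >= 0, noise < 1, n_sites >= 1)
  all_kos <- function(mods) unique(unlist(lapply(mods, function(m) unlist(m$blocks))))
  build <- function(mods, stream) {
    kos <- all_kos(mods)
    if (length(kos) == 0)
      return(matrix(0, 0, n_sites,
                    dimnames = list(character(0),
                                    sprintf("site%02d", seq_len(n_sites)))))
    with_seed(derive_seed(seed, stream), {
      m <- matrix(stats::rlnorm(length(kos) * n_sites, 2, 1),
                  nrow = length(kos),
                  dimnames = list(kos, sprintf("site%02d", seq_len(n_sites))))
      if (noise > 0)
        m[matrix(stats::runif(length(m)) < noise, nrow = nrow(m))] <- 0
      m
    })
  }
  list(host = build(c(host_modules, shared_modules), "host"),
       microbiome = build(c(microbiome_modules, shared_modules), "microbiome"))
}

#' Random module definitions
#'
#' Generates `n` synthetic module definitions with disjoint KO content
#' (module ids carry `prefix`; KO ids occupy a numeric range starting at
#' `ko_offset`, so collections built with different offsets are disjoint),
#' each with 3-6 blocks of 1-3 alternative KOs — enough blocks that an
#' entirely absent module is never called complete under the "at most one
#' missing block" rule.
#'
#' @param n Number of modules.
#' @param prefix Module id prefix, e.g. `"H"`.
#' @param seed Integer seed.
#' @param ko_offset Starting number for the generated KO identifiers.
#' @return Named list of module definitions.
#' @export
simulate_module_defs <- function(n, prefix, seed, ko_offset = 0) {
  with_seed(seed, {
    out <- list()
    ko_counter <- ko_offset
    for (i in seq_len(n)) {
      id <- sprintf("M%s%03d", prefix, i)
      n_blocks <- sample(3:6, 1)
      blocks <- lapply(seq_len(n_blocks), function(b) {
        n_alt <- sample(1:3, 1)
        kos <- sprintf("K%05d", ko_counter + seq_len(n_alt))
        ko_counter <<- ko_counter + n_alt
        kos
      })
      out[[id]] <- list(module_id = id, blocks = blocks)
    }
    out
  })
}

#' Write a synthetic survey to disk
#'
#' Writes the standard file set: OTU table TSV, taxonomy TSV, newick tree,
#' coordinates CSV, and a JSON truth sidecar recording the configuration,
#' site optima and site taxon pools.
#'
#' @param truth A `synthetic_survey` ([simulate_survey()]).
#' @param dir Output directory (created if needed).
#' @param taxonomy Optional taxonomy data frame; generated with
#'   [simulate_taxonomy()] if `NULL`.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_survey <- function(truth, dir, taxonomy = NULL) {
  stopifnot(inherits(truth, "synthetic_survey"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(taxonomy))
    taxonomy <- simulate_taxonomy(truth$tree,
                                  derive_seed(truth$config$seed, "tax"))
  paths <- c(otu = file.path(dir, "otu_table.tsv"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             tree = file.path(dir, "tree.nwk"),
             coordinates = file.path(dir, "coordinates.csv"),
             replicate_map = file.path(dir, "replicate_map.csv"),
             truth = file.path(dir, "truth.json"))
  write_otu_table(truth$communities, paths["otu"])
  write_taxonomy(taxonomy, paths["taxonomy"])
  ape::write.tree(truth$tree, paths["tree"])
  write_coordinates(truth$geo, paths["coordinates"])
  utils::write.csv(data.frame(sample = names(truth$replicate_map),
                              site = unname(truth$replicate_map)),
                   paths["replicate_map"], row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(config = unclass(truth$config),
                            site_optima = as.list(truth$site_optima),
                            site_taxa = truth$site_taxa),
                       paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
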