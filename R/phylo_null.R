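# Null-model community phylogenetics: MNTD and betaMNTD, with taxa-label
# randomization nulls and the standardized indices alphaNTI and betaNTI.
# Conventions follow the classic "taxa.labels" null: each null replicate
# draws one uniform permutation of the tip labels of the full phylogeny,
# applied to the patristic matrix and shared by all samples (or sample
# pairs) of that replicate. alphaNTI is the NEGATED z-score, so positive
# values mean phylogenetic clustering; betaNTI keeps the plain z-score sign.

#' Patristic distance matrix
#'
#' Tip-to-tip path lengths (sums of branch lengths) for all tip pairs.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @return Symmetric tip x tip matrix, zero diagonal.
#' @export
patristic_matrix <- function(tree) {
  assert_phylo(tree)
  m <- ape::cophenetic.phylo(tree)
  m <- m[tree$tip.label, tree$tip.label]
  assert_pairwise(m, "patristic matrix")
}

# Nearest-neighbour distances within the rows of a square distance block:
# for each of `ids` (row/col indices into `dist`), the min distance to the
# other ids. max.col on the negated block is the fast base-R row-min.
nearest_within <- function(dist, ids) {
  sub <- dist[ids, ids, drop = FALSE]
  diag(sub) <- Inf
  j <- max.col(-sub, ties.method = "first")
  sub[cbind(seq_along(ids), j)]
}

# Directed nearest-neighbour distances from rows `from` to columns `to`.
nearest_across <- function(dist, from, to) {
  sub <- dist[from, to, drop = FALSE]
  j <- max.col(-sub, ties.method = "first")
  sub[cbind(seq_along(from), j)]
}

mntd_from_ids <- function(dist, ids, weights = NULL) {
  nn <- nearest_within(dist, ids)
  if (is.null(weights)) mean(nn) else sum(nn * weights) / sum(weights)
}

beta_mntd_from_ids <- function(dist, ids_k, ids_m, w_k = NULL, w_m = NULL) {
  a <- nearest_across(dist, ids_k, ids_m)
  b <- nearest_across(dist, ids_m, ids_k)
  ma <- if (is.null(w_k)) mean(a) else sum(a * w_k) / sum(w_k)
  mb <- if (is.null(w_m)) mean(b) else sum(b * w_m) / sum(w_m)
  (ma + mb) / 2
}

#' Mean nearest taxon distance (MNTD)
#'
#' The mean, over the taxa present in a community, of the phylogenetic
#' (patristic) distance from each taxon to its closest co-occurring taxon.
#' The abundance-weighted variant weights each taxon's nearest-neighbour
#' distance by its relative abundance.
#'
#' @param community Named abundance (or presence) vector; taxa with value
#'   `> 0` are present. At least two taxa must be present.
#' @param dist Patristic matrix covering all present taxa
#'   ([patristic_matrix()]).
#' @param abundance_weighted Weight by relative abundance (default `FALSE`).
#' @return A single MNTD value.
#' @export
mntd <- function(community, dist, abundance_weighted = FALSE) {
  present <- names(community)[community > 0]
  if (length(present) < 2)
    stop("MNTD is undefined for communities with fewer than two taxa", call. = FALSE)
  miss <- setdiff(present, rownames(dist))
  if (length(miss))
    stop("taxa missing from the distance matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  ids <- match(present, rownames(dist))
  w <- if (abundance_weighted) as.numeric(community[present]) else NULL
  mntd_from_ids(dist, ids, w)
}

#' Within-sample phylogenetic structure: alphaNTI
#'
#' For every sample, compares the observed MNTD with a null distribution
#' obtained by shuffling the taxa across the tips of the phylogeny
#' (`n_null` label permutations of the patristic matrix, one permutation per
#' replicate shared across samples) and reports the nearest taxon index
#' `alphaNTI = -(observed - mean(null)) / sd(null)`; values above +2 indicate
#' phylogenetic clustering, below -2 overdispersion. Samples for which the
#' null distribution has zero variance (e.g. a sample containing every tip)
#' get `NA` with reason `"zero null variance"`, never a silent 0.
#'
#' @param table Samples x taxa abundance matrix; every sample needs at least
#'   two taxa present.
#' @param tree Phylogeny containing every table taxon as a tip; the null
#'   shuffles across all of its tips.
#' @param n_null Number of null replicates (default 999).
#' @param abundance_weighted Weight MNTD by relative abundance.
#' @param seed Integer seed; results are reproducible given it.
#' @return Data frame (one row per sample) with `sample`, `n_taxa`,
#'   `observed`, `null_mean`, `null_sd`, `nti`, `reason`, and
#'   `classification` (see [classify_structure()]). The matrix of null MNTD
#'   values (samples x replicates) is attached as attribute `"nulls"`.
#' @export
alpha_nti <- function(table, tree, n_null = 999, abundance_weighted = FALSE, seed) {
  assert_community(table, allow_real = TRUE)
  stopifnot(n_null >= 1)
  dist <- patristic_matrix(tree)
  n_tip <- nrow(dist)
  samples <- rownames(table)
  ids <- lapply(samples, function(s) {
    present <- colnames(table)[table[s, ] > 0]
    if (length(present) < 2)
      stop("sample '", s, "' has fewer than two taxa", call. = FALSE)
    match(present, rownames(dist))
  })
  if (anyNA(unlist(ids)))
    stop("table contains taxa that are not tips of the tree", call. = FALSE)
  wts <- if (abundance_weighted)
    lapply(seq_along(samples), function(k)
      as.numeric(table[samples[k], rownames(dist)[ids[[k]]]]))
  else vector("list", length(samples))
  obs <- vapply(seq_along(samples), function(k)
    mntd_from_ids(dist, ids[[k]], wts[[k]]), numeric(1))
  nulls <- with_seed(seed, {
    vapply(seq_len(n_null), function(r) {
      perm <- sample.int(n_tip)
      vapply(seq_along(samples), function(k)
        mntd_from_ids(dist, perm[ids[[k]]], wts[[k]]), numeric(1))
    }, numeric(length(samples)))
  })
  nulls <- matrix(nulls, nrow = length(samples),
                  dimnames = list(samples, NULL))
  null_mean <- rowMeans(nulls)
  null_sd <- apply(nulls, 1, stats::sd)
  nti <- ifelse(null_sd > 0, -(obs - null_mean) / null_sd, NA_real_)
  out <- data.frame(
    sample = samples,
    n_taxa = lengths(ids),
    observed = obs,
    null_mean = null_mean,
    null_sd = null_sd,
    nti = nti,
    reason = ifelse(null_sd > 0, "", "zero null variance"),
    classification = classify_structure(nti),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "nulls") <- nulls
  out
}

#' Between-sample phylogenetic turnover: betaMNTD
#'
#' `betaMNTD(k, m)` is the average of (i) the mean distance from each taxon
#' in sample `k` to its nearest relative in sample `m` and (ii) the converse;
#' the abundance-weighted variant weights each taxon's term by its relative
#' abundance within its own sample. Identical samples have betaMNTD 0.
#'
#' @inheritParams alpha_nti
#' @return Symmetric sample x sample matrix.
#' @export
beta_mntd <- function(table, tree, abundance_weighted = FALSE) {
  assert_community(table, allow_real = TRUE)
  if (nrow(table) < 2) stop("need at least two samples", call. = FALSE)
  dist <- patristic_matrix(tree)
  bm <- beta_mntd_ids(table, dist, abundance_weighted)
  pairs <- pair_index(rownames(table))
  out <- matrix(0, nrow(table), nrow(table),
                dimnames = list(rownames(table), rownames(table)))
  vals <- vapply(seq_len(nrow(pairs)), function(p)
    beta_mntd_from_ids(dist, bm$ids[[pairs$i[p]]], bm$ids[[pairs$j[p]]],
                       bm$wts[[pairs$i[p]]], bm$wts[[pairs$j[p]]]), numeric(1))
  out[cbind(pairs$i, pairs$j)] <- vals
  out[cbind(pairs$j, pairs$i)] <- vals
  assert_pairwise(out, "betaMNTD matrix")
}

# Shared set-up for beta_mntd / beta_nti: per-sample tip indices and weights.
beta_mntd_ids <- function(table, dist, abundance_weighted) {
  ids <- lapply(rownames(table), function(s) {
    present <- colnames(table)[table[s, ] > 0]
    if (length(present) < 1) stop("sample '", s, "' is empty", call. = FALSE)
    idx <- match(present, rownames(dist))
    if (anyNA(idx))
      stop("taxa of sample '", s, "' missing from the tree", call. = FALSE)
    idx
  })
  wts <- if (abundance_weighted)
    lapply(seq_len(nrow(table)), function(k)
      as.numeric(table[k, rownames(dist)[ids[[k]]]]))
  else vector("list", nrow(table))
  list(ids = ids, wts = wts)
}

#' Between-sample null-model index: betaNTI
#'
#' Standardizes the observed betaMNTD of every sample pair against a null
#' distribution generated by randomizing taxa across the phylogeny: each of
#' the `n_null` replicates draws one permutation of all tip labels (shared by
#' every pair in that replicate) and recomputes betaMNTD.
#' `betaNTI = (observed - mean(null)) / sd(null)`; values below -2 indicate
#' that two communities are more phylogenetically similar than expected by
#' chance, above +2 less similar. Pairs with zero null variance are `NA`.
#'
#' @inheritParams alpha_nti
#' @return List with `nti` (symmetric sample x sample index matrix with `NA`
#'   diagonal), `observed`, `null_mean`, `null_sd` (matrices of the same
#'   shape), and `nulls` (pairs x replicates matrix of null betaMNTD values,
#'   rows labelled `"k|m"`).
#' @export
beta_nti <- function(table, tree, n_null = 999, abundance_weighted = FALSE, seed) {
  assert_community(table, allow_real = TRUE)
  if (nrow(table) < 2) stop("need at least two samples", call. = FALSE)
  stopifnot(n_null >= 1)
  dist <- patristic_matrix(tree)
  n_tip <- nrow(dist)
  bm <- beta_mntd_ids(table, dist, abundance_weighted)
  pairs <- pair_index(rownames(table))
  n_pairs <- nrow(pairs)
  pair_val <- function(idmap) vapply(seq_len(n_pairs), function(p)
    beta_mntd_from_ids(dist,
                       idmap[bm$ids[[pairs$i[p]]]], idmap[bm$ids[[pairs$j[p]]]],
                       bm$wts[[pairs$i[p]]], bm$wts[[pairs$j[p]]]), numeric(1))
  obs <- pair_val(seq_len(n_tip))
  nulls <- with_seed(seed, {
    vapply(seq_len(n_null), function(r) pair_val(sample.int(n_tip)),
           numeric(n_pairs))
  })
  nulls <- matrix(nulls, nrow = n_pairs)
  rownames(nulls) <- paste(rownames(table)[pairs$i], rownames(table)[pairs$j],
                           sep = "|")
  nm <- rowMeans(nulls)
  nsd <- apply(nulls, 1, stats::sd)
  z <- ifelse(nsd > 0, (obs - nm) / nsd, NA_real_)
  shape <- function(v, diag_val = NA_real_) {
    m <- matrix(diag_val, nrow(table), nrow(table),
                dimnames = list(rownames(table), rownames(table)))
    m[cbind(pairs$i, pairs$j)] <- v
    m[cbind(pairs$j, pairs$i)] <- v
    m
  }
  list(nti = shape(z), observed = shape(obs, 0), null_mean = shape(nm),
       null_sd = shape(nsd), nulls = nulls)
}

#' Compare observed indices with their null expectation
#'
#' Welch two-sample t-test of a vector of observed standardized indices
#' (alphaNTI or betaNTI values) against a vector of null indices; used to ask
#' whether the mean index across communities differs from the null
#' expectation. Non-finite values are dropped.
#'
#' @param indices Observed index values (length >= 2 finite).
#' @param null_indices Null index values (length >= 2 finite), e.g. from
#'   [standardized_null_indices()].
#' @param var_equal Use the pooled-variance test instead of Welch.
#' @return List with `t` and `p` (two-sided).
#' @export
index_t_test <- function(indices, null_indices, var_equal = FALSE) {
  x <- indices[is.finite(indices)]
  y <- null_indices[is.finite(null_indices)]
  if (length(x) < 2 || length(y) < 2)
    stop("need at least two finite values in each vector", call. = FALSE)
  ht <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Standardized null indices from a null ensemble
#'
#' Converts the per-sample (or per-pair) null replicate values attached to
#' [alpha_nti()] / [beta_nti()] output into standardized indices on the same
#' scale as the observed ones — each replicate value is z-scored against its
#' own sample's null distribution (negated for alphaNTI) — then pooled.
#' Rows with zero null variance are dropped.
#'
#' @param nulls Matrix of null statistic values, rows = samples or pairs,
#'   columns = replicates (attribute `"nulls"` of [alpha_nti()], element
#'   `nulls` of [beta_nti()]).
#' @param negate Negate the z-scores (use `TRUE` for alphaNTI).
#' @return Numeric vector of pooled standardized null indices.
#' @export
standardized_null_indices <- function(nulls, negate = FALSE) {
  m <- rowMeans(nulls)
  s <- apply(nulls, 1, stats::sd)
  keep <- s > 0
  z <- (nulls[keep, , drop = FALSE] - m[keep]) / s[keep]
  if (negate) z <- -z
  as.numeric(z)
}

#' Classify phylogenetic community structure from an index
#'
#' Index above `threshold` = clustered; below `-threshold` = overdispersed;
#' otherwise random (strict inequalities, so exactly +/-2 is random);
#' `NA` (undefined index) propagates as `"undefined"`.
#'
#' @param index Numeric vector of alphaNTI (or betaNTI) values.
#' @param threshold Classification threshold (default 2).
#' @return Character vector.
#' @export
classify_structure <- function(index, threshold = 2) {
  out <- ifelse(is.na(index), "undefined",
         ifelse(index > threshold, "clustered",
         ifelse(index < -threshold, "overdispersed", "random")))
  as.character(out)
}
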