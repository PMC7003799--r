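# Pairwise dissimilarity and the distance-decay regression: Bray-Curtis,
# abundance-weighted UniFrac, great-circle distances, Gaussian-identity GLM.

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i)`, computed between all sample
#' pairs. Accepts counts or real-valued abundances (e.g. KO profiles).
#'
#' @param table Samples x taxa abundance matrix; every sample must have a
#'   positive total.
#' @return Symmetric matrix in `[0, 1]` with zero diagonal, labelled by
#'   sample.
#' @export
bray_curtis <- function(table) {
  assert_community(table, allow_real = TRUE)
  if (nrow(table) < 2) stop("need at least two samples", call. = FALSE)
  zero <- rowSums(table) <= 0
  if (any(zero))
    stop("sample with zero total abundance: ",
         paste(rownames(table)[zero], collapse = ", "), call. = FALSE)
  m <- as.matrix(vegan::vegdist(table, method = "bray"))
  diag(m) <- 0
  assert_pairwise(m, "Bray-Curtis matrix")
}

# Per-branch descendant abundance: samples x edges matrix of the proportional
# abundance flowing through each branch, plus branch lengths (postorder).
branch_weights <- function(table, tree) {
  assert_phylo(tree)
  miss <- setdiff(colnames(table), tree$tip.label)
  if (length(miss))
    stop("taxa missing from the tree: ", paste(miss, collapse = ", "), call. = FALSE)
  tot <- rowSums(table)
  if (any(tot <= 0)) stop("sample with zero total abundance", call. = FALSE)
  props <- table / tot
  po <- stats::reorder(tree, "postorder")
  n_tip <- length(po$tip.label)
  n_node <- n_tip + po$Nnode
  acc <- matrix(0, nrow = nrow(table), ncol = n_node)
  acc[, match(colnames(table), po$tip.label)] <- props
  for (e in seq_len(nrow(po$edge))) {      # postorder: children before parents
    acc[, po$edge[e, 1]] <- acc[, po$edge[e, 1]] + acc[, po$edge[e, 2]]
  }
  list(weights = acc[, po$edge[, 2], drop = FALSE], lengths = po$edge.length)
}

#' Abundance-weighted UniFrac
#'
#' For each branch `b` of length `l_b`, let `p_b` and `q_b` be the two
#' samples' proportional abundance descending through `b`. The raw weighted
#' UniFrac is `sum_b l_b * |p_b - q_b|`; the normalized variant (default)
#' divides by `sum_b l_b * (p_b + q_b)` and lies in `[0, 1]`.
#'
#' @param table Samples x taxa abundance matrix; all taxa must be tips of
#'   `tree` (tips absent from the table carry zero abundance).
#' @param tree Rooted `phylo` with branch lengths.
#' @param normalized Return the normalized (`TRUE`, default) or raw variant.
#' @return Symmetric sample x sample matrix with zero diagonal.
#' @export
weighted_unifrac <- function(table, tree, normalized = TRUE) {
  assert_community(table, allow_real = TRUE)
  if (nrow(table) < 2) stop("need at least two samples", call. = FALSE)
  bw <- branch_weights(table, tree)
  n <- nrow(table)
  out <- matrix(0, n, n, dimnames = list(rownames(table), rownames(table)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      num <- sum(bw$lengths * abs(bw$weights[i, ] - bw$weights[j, ]))
      if (normalized) {
        den <- sum(bw$lengths * (bw$weights[i, ] + bw$weights[j, ]))
        num <- if (den > 0) num / den else 0
      }
      out[i, j] <- out[j, i] <- num
    }
  }
  assert_pairwise(out, "UniFrac matrix")
}

#' Great-circle distance matrix
#'
#' Haversine distances between all site pairs on a sphere of the given
#' radius, in the units of `radius_km` (kilometres by default).
#'
#' @param geo Data frame with `site`, `latitude`, `longitude` (decimal
#'   degrees).
#' @param radius_km Sphere radius; default 6371 km.
#' @return Symmetric site x site distance matrix.
#' @export
great_circle_distances <- function(geo, radius_km = 6371) {
  assert_geo(geo)
  p <- cbind(geo$longitude, geo$latitude)
  n <- nrow(geo)
  out <- matrix(0, n, n, dimnames = list(geo$site, geo$site))
  for (i in seq_len(max(n - 1, 0))) {
    d <- geosphere::distHaversine(p[i, ], p[(i + 1):n, , drop = FALSE], r = radius_km)
    out[i, (i + 1):n] <- d
    out[(i + 1):n, i] <- d
  }
  assert_pairwise(out, "distance matrix")
}

#' Distance-decay regression
#'
#' Fits a Gaussian-identity GLM of pairwise community dissimilarity on
#' pairwise geographic distance over the `n(n-1)/2` site pairs, the standard
#' test for a distance-decay relationship. With this family/link the deviance
#' explained equals the coefficient of determination; the p-value reported is
#' the Wald p-value for the slope. Note the pairs are not independent; an
#' optional permutation p-value (Mantel-style, permuting site identities) is
#' available via `n_perm`.
#'
#' @param distance Site x site distance matrix (e.g.
#'   [great_circle_distances()]).
#' @param dissimilarity Site x site dissimilarity matrix with the same label
#'   set.
#' @param n_perm If `> 0`, also compute a permutation p-value for the slope
#'   from `n_perm` random relabelings of the dissimilarity matrix.
#' @param seed Seed for the permutation test (required when `n_perm > 0`).
#' @return Object of class `decay_fit`: list with `slope` (per distance
#'   unit), `intercept`, `deviance_explained`, `p_value`, `n_pairs`, and
#'   `p_perm` when requested.
#' @export
distance_decay_glm <- function(distance, dissimilarity, n_perm = 0, seed = NULL) {
  assert_pairwise(distance, "distance matrix")
  assert_pairwise(dissimilarity, "dissimilarity matrix")
  if (!setequal(rownames(distance), rownames(dissimilarity)))
    stop("distance and dissimilarity labels do not match", call. = FALSE)
  if (nrow(distance) < 3) stop("need at least three sites", call. = FALSE)
  dissimilarity <- dissimilarity[rownames(distance), rownames(distance)]
  ut <- upper.tri(distance)
  x <- distance[ut]
  y <- dissimilarity[ut]
  fit <- stats::glm(y ~ x, family = stats::gaussian())
  co <- stats::coef(fit)
  if (fit$null.deviance > 0) {
    de <- 1 - fit$deviance / fit$null.deviance
    p <- summary(fit)$coefficients["x", "Pr(>|t|)"]
  } else {                         # constant dissimilarity: no signal
    de <- 0
    p <- 1
  }
  out <- list(slope = unname(co["x"]), intercept = unname(co["(Intercept)"]),
              deviance_explained = de, p_value = p, n_pairs = length(x))
  if (n_perm > 0) {
    if (is.null(seed)) stop("seed required for the permutation test", call. = FALSE)
    obs <- abs(out$slope)
    exceed <- with_seed(seed, {
      vapply(seq_len(n_perm), function(r) {
        idx <- sample(nrow(dissimilarity))
        yp <- dissimilarity[idx, idx][ut]
        abs(unname(stats::coef(stats::lm(yp ~ x))["x"])) >= obs
      }, logical(1))
    })
    out$p_perm <- (sum(exceed) + 1) / (n_perm + 1)
  }
  class(out) <- "decay_fit"
  out
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("Distance-decay GLM (gaussian, identity)\n")
  cat(sprintf("  slope      : %.4g per distance unit\n", x$slope))
  cat(sprintf("  intercept  : %.4g\n", x$intercept))
  cat(sprintf("  deviance explained: %.2f%%  (p = %.3g, Wald)\n",
              100 * x$deviance_explained, x$p_value))
  if (!is.null(x$p_perm)) cat(sprintf("  permutation p     : %.3g\n", x$p_perm))
  cat(sprintf("  n pairs    : %d\n", x$n_pairs))
  invisible(x)
}
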