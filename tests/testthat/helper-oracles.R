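# Independent brute-force oracles. These deliberately avoid the package's
# computational paths (and ape's distance utilities): everything is derived
# by walking the raw edge list.

# node depths (root-to-node path lengths) and parent map from the edge list
tree_depths <- function(tree) {
  n_node <- length(tree$tip.label) + tree$Nnode
  parent <- rep(NA_integer_, n_node)
  plen <- rep(NA_real_, n_node)
  for (e in seq_len(nrow(tree$edge))) {
    parent[tree$edge[e, 2]] <- tree$edge[e, 1]
    plen[tree$edge[e, 2]] <- tree$edge.length[e]
  }
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  depth <- rep(NA_real_, n_node)
  depth[root] <- 0
  # iterate until all depths resolve (tree is small in tests)
  while (anyNA(depth)) {
    for (v in which(is.na(depth))) {
      if (!is.na(parent[v]) && !is.na(depth[parent[v]]))
        depth[v] <- depth[parent[v]] + plen[v]
    }
  }
  list(parent = parent, depth = depth, root = root)
}

ancestors_of <- function(v, parent) {
  out <- v
  while (!is.na(parent[v])) {
    v <- parent[v]
    out <- c(out, v)
  }
  out
}

# patristic distance via d(i,j) = depth(i) + depth(j) - 2 depth(mrca)
brute_patristic <- function(tree) {
  td <- tree_depths(tree)
  n <- length(tree$tip.label)
  out <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  anc <- lapply(seq_len(n), ancestors_of, parent = td$parent)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      common <- intersect(anc[[i]], anc[[j]])
      mrca <- common[which.max(td$depth[common])]
      out[i, j] <- out[j, i] <- td$depth[i] + td$depth[j] - 2 * td$depth[mrca]
    }
  }
  out
}

# exhaustive double-loop MNTD over the present taxa of a named vector
brute_mntd <- function(community, dist, abundance_weighted = FALSE) {
  present <- names(community)[community > 0]
  nn <- sapply(present, function(i)
    min(sapply(setdiff(present, i), function(j) dist[i, j])))
  if (!abundance_weighted) return(mean(nn))
  w <- as.numeric(community[present])
  sum(nn * w) / sum(w)
}

brute_beta_mntd <- function(x, y, dist, abundance_weighted = FALSE) {
  px <- names(x)[x > 0]; py <- names(y)[y > 0]
  nx <- sapply(px, function(i) min(sapply(py, function(j) dist[i, j])))
  ny <- sapply(py, function(j) min(sapply(px, function(i) dist[i, j])))
  if (!abundance_weighted) return((mean(nx) + mean(ny)) / 2)
  wx <- as.numeric(x[px]); wy <- as.numeric(y[py])
  (sum(nx * wx) / sum(wx) + sum(ny * wy) / sum(wy)) / 2
}

# weighted UniFrac by explicit per-branch enumeration: for every edge,
# collect descendant tips by ancestor walks, sum length * |p - q|
brute_weighted_unifrac <- function(x, y, tree, normalized = TRUE) {
  td <- tree_depths(tree)
  n <- length(tree$tip.label)
  px <- x / sum(x); py <- y / sum(y)
  num <- 0; den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    tips <- tree$tip.label[which(sapply(seq_len(n), function(t)
      child %in% ancestors_of(t, td$parent)))]
    p <- sum(px[tips]); q <- sum(py[tips])
    num <- num + tree$edge.length[e] * abs(p - q)
    den <- den + tree$edge.length[e] * (p + q)
  }
  if (normalized) num / den else num
}
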