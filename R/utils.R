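#' @keywords internal
#' @importFrom ape keep.tip
#' @importFrom vegan vegdist
#' @importFrom geosphere distHaversine
"_PACKAGE"

# Internal validators shared across modules. Community tables are plain
# integer/numeric matrices with rownames = sample ids and colnames = taxon
# ids (vegan orientation: rows are samples).

assert_community <- function(table, allow_real = FALSE) {
  if (!is.matrix(table)) stop("community table must be a matrix", call. = FALSE)
  if (is.null(rownames(table)) || is.null(colnames(table)))
    stop("community table must have sample rownames and taxon colnames", call. = FALSE)
  if (anyDuplicated(rownames(table)) || anyDuplicated(colnames(table)))
    stop("sample and taxon ids must be unique", call. = FALSE)
  if (any(table < 0)) stop("community table contains negative counts", call. = FALSE)
  if (!allow_real && any(table != round(table)))
    stop("community table contains non-integer counts", call. = FALSE)
  invisible(table)
}

assert_pairwise <- function(m, what = "pairwise matrix", tol = 1e-10) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (max(abs(m - t(m)), na.rm = TRUE) > tol)
    stop(what, " is not symmetric", call. = FALSE)
  if (max(abs(diag(m)), na.rm = TRUE) > tol)
    stop(what, " has a non-zero diagonal", call. = FALSE)
  invisible(m)
}

assert_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) stop("tree tip labels must be unique", call. = FALSE)
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree must have non-negative branch lengths", call. = FALSE)
  invisible(tree)
}

assert_geo <- function(geo) {
  stopifnot(is.data.frame(geo))
  need <- c("site", "latitude", "longitude")
  if (!all(need %in% names(geo)))
    stop("coordinates need columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (anyDuplicated(geo$site)) stop("site ids must be unique", call. = FALSE)
  if (any(geo$latitude < -90 | geo$latitude > 90))
    stop("latitude out of [-90, 90]", call. = FALSE)
  if (any(geo$longitude < -180 | geo$longitude > 180))
    stop("longitude out of [-180, 180]", call. = FALSE)
  invisible(geo)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards (all exported stochastic functions route
# through this so they never disturb the session RNG).
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

#' Derive a per-stage seed from one master seed
#'
#' Deterministically expands a single user-facing seed into independent
#' stream seeds (one per named stage), so pipeline stages can be rerun in
#' isolation and every run is exactly replayable. The result stays inside
#' the 32-bit integer range.
#'
#' @param seed Integer master seed.
#' @param stage Character stage label.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  # arithmetic in doubles (exact below 2^53), reduced before integer coercion
  as.integer(((as.double(seed) %% 2147483647) * 48271 + h * 7919) %% 2147483629)
}

# Upper-triangle pair index of a labelled square matrix, as a data.frame.
pair_index <- function(labels) {
  n <- length(labels)
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(seq_len(n - 1), function(k) (k + 1):n))
  data.frame(i = i, j = j)
}
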