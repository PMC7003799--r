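# Readers/writers for the survey's plain-text formats and the OTU-table
# processing chain: taxonomy-based exclusion, low-count filtering, host
# (cyanobacteria) removal, rarefaction, replicate pooling, tree pruning.

#' Read an OTU count table
#'
#' Reads a tab-separated OTU table with taxa as rows and samples as columns.
#' The header row must start with `#OTU ID`. The table is returned in the
#' orientation used throughout this package (and by vegan): a non-negative
#' integer matrix with samples as rows and taxa as columns.
#'
#' @param path Path to a TSV file.
#' @return Integer matrix, samples x taxa.
#' @export
read_otu_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("OTU table needs a header and at least one taxon row", call. = FALSE)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  if (header[1] != "#OTU ID")
    stop("OTU table header must start with '#OTU ID', got '", header[1], "'", call. = FALSE)
  samples <- header[-1]
  if (anyDuplicated(samples)) stop("duplicate sample ids in header", call. = FALSE)
  width <- length(header)
  counts <- matrix(0, nrow = length(cells) - 1, ncol = length(samples))
  taxa <- character(nrow(counts))
  for (k in seq_len(length(cells) - 1)) {
    row <- cells[[k + 1]]
    if (length(row) != width)
      stop("ragged row at line ", k + 1, ": expected ", width, " fields, got ",
           length(row), call. = FALSE)
    taxa[k] <- row[1]
    x <- suppressWarnings(as.numeric(row[-1]))
    if (anyNA(x)) stop("non-numeric count at line ", k + 1, call. = FALSE)
    if (any(x < 0)) stop("negative count at line ", k + 1, call. = FALSE)
    if (any(x != round(x))) stop("non-integer count at line ", k + 1, call. = FALSE)
    counts[k, ] <- x
  }
  if (anyDuplicated(taxa)) {
    dup <- taxa[duplicated(taxa)][1]
    stop("duplicate taxon id '", dup, "'", call. = FALSE)
  }
  out <- t(counts)
  dimnames(out) <- list(samples, taxa)
  storage.mode(out) <- "integer"
  assert_community(out)
}

#' Write an OTU count table
#'
#' Inverse of [read_otu_table()]: writes taxa as rows, samples as columns,
#' header starting with `#OTU ID`, LF line endings, UTF-8.
#'
#' @param table Samples x taxa count matrix.
#' @param path Output path.
#' @export
write_otu_table <- function(table, path) {
  assert_community(table)
  m <- t(table)
  header <- paste(c("#OTU ID", rownames(table)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], format(m[i, ], scientific = FALSE, trim = TRUE)),
          collapse = "\t"), character(1))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Read and write taxonomy assignments
#'
#' Taxonomy files are TSV with columns `taxon_id`, `lineage` (semicolon-joined
#' ranks, domain outward, SILVA style) and optionally `confidence` in `[0,1]`.
#'
#' @param path File path.
#' @return Data frame with columns `taxon_id`, `lineage`, `confidence`.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "")
  if (!all(c("taxon_id", "lineage") %in% names(df)))
    stop("taxonomy file needs 'taxon_id' and 'lineage' columns", call. = FALSE)
  if (anyDuplicated(df$taxon_id)) stop("duplicate taxon_id in taxonomy", call. = FALSE)
  if (is.null(df$confidence)) df$confidence <- NA_real_
  df[, c("taxon_id", "lineage", "confidence")]
}

#' @rdname read_taxonomy
#' @param taxonomy Data frame as returned by [read_taxonomy()].
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(taxonomy, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write site coordinates
#'
#' CSV with columns `site`, `latitude`, `longitude` (decimal degrees).
#'
#' @param path File path.
#' @return Data frame with the three columns, validated for range.
#' @export
read_coordinates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_geo(df)
  df[, c("site", "latitude", "longitude")]
}

#' @rdname read_coordinates
#' @param geo Data frame of coordinates.
#' @export
write_coordinates <- function(geo, path) {
  assert_geo(geo)
  utils::write.csv(geo, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

# Split a semicolon lineage into trimmed rank names.
lineage_ranks <- function(lineage) {
  trimws(strsplit(lineage, ";", fixed = TRUE)[[1]])
}

# Which taxa of `table` match any of `terms` at any lineage rank
# (exact-rank, case-insensitive). Returns a logical over colnames(table);
# taxa absent from the taxonomy are NA.
match_lineage_terms <- function(table, taxonomy, terms) {
  terms <- tolower(terms)
  lin <- taxonomy$lineage[match(colnames(table), taxonomy$taxon_id)]
  vapply(lin, function(l) {
    if (is.na(l)) return(NA)
    any(tolower(lineage_ranks(l)) %in% terms)
  }, logical(1), USE.NAMES = FALSE)
}

#' Remove taxa whose lineage matches excluded terms
#'
#' Drops a taxon if any of its lineage ranks equals (case-insensitively) one
#' of `excluded_terms`. Matching is exact per rank, never substring, so
#' excluding `"bacteria"` would not remove `"Melainabacteria"`. This is the
#' survey's first processing step, discarding OTUs classified as eukaryote,
#' archaea, chloroplast or mitochondria.
#'
#' @param table Samples x taxa count matrix.
#' @param taxonomy Taxonomy data frame ([read_taxonomy()]).
#' @param excluded_terms Character vector of rank names to exclude.
#' @param missing What to do with taxa that have no taxonomy record:
#'   `"drop"` (default, with a warning) or `"keep"`.
#' @return The filtered table; the sample set is unchanged.
#' @export
filter_by_taxonomy <- function(table, taxonomy,
                               excluded_terms = c("eukaryota", "eukaryote",
                                                  "archaea", "chloroplast",
                                                  "mitochondria"),
                               missing = c("drop", "keep")) {
  assert_community(table, allow_real = TRUE)
  missing <- match.arg(missing)
  if (length(excluded_terms) == 0) return(table)
  hit <- match_lineage_terms(table, taxonomy, excluded_terms)
  if (anyNA(hit)) {
    n_miss <- sum(is.na(hit))
    if (missing == "drop") {
      warning(n_miss, " taxa without taxonomy records were dropped", call. = FALSE)
      hit[is.na(hit)] <- TRUE
    } else {
      hit[is.na(hit)] <- FALSE
    }
  }
  table[, !hit, drop = FALSE]
}

#' Remove taxa below a total-count threshold
#'
#' Keeps a taxon iff its count summed across all samples is at least
#' `min_total`; the survey convention discards OTUs with fewer than 100
#' total counts.
#'
#' @param table Samples x taxa count matrix.
#' @param min_total Minimum total count (default 100).
#' @return Filtered table.
#' @export
filter_low_abundance <- function(table, min_total = 100) {
  assert_community(table, allow_real = TRUE)
  stopifnot(min_total >= 0)
  table[, colSums(table) >= min_total, drop = FALSE]
}

#' Remove a taxonomic group
#'
#' Removes every taxon whose lineage contains `group_term` at any rank
#' (exact-rank, case-insensitive). Used to strip the cyanobacterial host
#' from the community table before microbiome analyses; taxa without a
#' taxonomy record are kept (they cannot be shown to belong to the group).
#'
#' @inheritParams filter_by_taxonomy
#' @param group_term Rank name of the group to remove.
#' @return Filtered table.
#' @export
remove_group <- function(table, taxonomy, group_term = "Cyanobacteria") {
  assert_community(table, allow_real = TRUE)
  stopifnot(length(group_term) == 1)
  hit <- match_lineage_terms(table, taxonomy, group_term)
  hit[is.na(hit)] <- FALSE
  table[, !hit, drop = FALSE]
}

#' Rarefy samples to a common depth
#'
#' Subsamples each sample's counts without replacement to exactly `depth`
#' reads (a single draw per sample). `depth = "min"` resolves to the total of
#' the shallowest sample, the survey's convention. Taxa left with zero counts
#' in every sample are dropped.
#'
#' @param table Samples x taxa integer count matrix.
#' @param depth Integer target depth, or `"min"`.
#' @param seed Integer seed; the draw is deterministic given it.
#' @return Rarefied table; every row sums to `depth`.
#' @export
rarefy <- function(table, depth = "min", seed) {
  assert_community(table)
  totals <- rowSums(table)
  if (identical(depth, "min")) depth <- min(totals)
  depth <- as.integer(depth)
  if (any(totals < depth)) {
    bad <- rownames(table)[which(totals < depth)[1]]
    stop("rarefaction depth ", depth, " exceeds the total of sample '",
         bad, "' (", totals[bad], ")", call. = FALSE)
  }
  out <- with_seed(seed, vegan::rrarefy(table, depth))
  out <- out[, colSums(out) > 0, drop = FALSE]
  storage.mode(out) <- "integer"
  out
}

#' Pool replicate samples into sites
#'
#' Sums the counts of all replicates of a site elementwise; the output has
#' one row per site, in order of first appearance in `mapping`.
#'
#' @param table Samples x taxa count matrix.
#' @param mapping Named character vector, `names = sample ids`,
#'   `values = site ids`; every sample in `table` must be mapped.
#' @param fun `"sum"` (default, pooled counts) or `"mean"` (per-replicate
#'   average).
#' @return Sites x taxa matrix.
#' @export
pool_replicates <- function(table, mapping, fun = c("sum", "mean")) {
  assert_community(table, allow_real = TRUE)
  fun <- match.arg(fun)
  unmapped <- setdiff(rownames(table), names(mapping))
  if (length(unmapped))
    stop("unmapped samples: ", paste(unmapped, collapse = ", "), call. = FALSE)
  sites <- mapping[rownames(table)]
  pooled <- rowsum(table, group = sites, reorder = FALSE)
  if (fun == "mean") pooled <- pooled / as.vector(table(sites)[rownames(pooled)])
  pooled[unique(sites), , drop = FALSE]
}

#' Prune a phylogeny to the taxa of a table
#'
#' Restricts `tree` to exactly the taxa present in `table`; patristic
#' distances among the retained tips are unchanged.
#'
#' @param tree `phylo` object.
#' @param table Samples x taxa matrix whose taxa must all be tree tips.
#' @return Pruned `phylo`.
#' @export
prune_tree_to_table <- function(tree, table) {
  assert_phylo(tree)
  taxa <- colnames(table)
  miss <- setdiff(taxa, tree$tip.label)
  if (length(miss))
    stop("taxa missing from the tree: ", paste(miss, collapse = ", "), call. = FALSE)
  ape::keep.tip(tree, taxa)
}
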