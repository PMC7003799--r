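# Functional profiling: KO abundance tables, KEGG-style module completeness
# with the "at most one missing block" rule, the host/microbiome Venn
# partition, and the functional distance-decay regression.

#' Read and write KO abundance tables
#'
#' TSV with KO identifiers as rows and groups (sites or organism pools) as
#' columns; header starts with `#KO ID`. Returned as a numeric matrix with
#' KO rownames and group colnames.
#'
#' @param path File path.
#' @return Numeric matrix, KOs x groups, non-negative.
#' @export
read_ko_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          comment.char = "", stringsAsFactors = FALSE)
  if (names(df)[1] != "#KO ID")
    stop("KO table header must start with '#KO ID'", call. = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids)) stop("duplicate KO ids", call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  if (any(m < 0)) stop("negative KO abundance", call. = FALSE)
  m
}

#' @rdname read_ko_table
#' @param ko_table KOs x groups matrix.
#' @export
write_ko_table <- function(ko_table, path) {
  header <- paste(c("#KO ID", colnames(ko_table)), collapse = "\t")
  body <- vapply(seq_len(nrow(ko_table)), function(i)
    paste(c(rownames(ko_table)[i],
            format(ko_table[i, ], digits = 15, scientific = FALSE,
                   trim = TRUE)),
          collapse = "\t"), character(1))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Parse module definitions
#'
#' One module per line: `module_id<TAB>block block ...`, where each block is
#' a comma-separated set of alternative KO identifiers (any one of which
#' satisfies the block). This is the pre-flattened form of a KEGG module
#' definition; the full boolean grammar is out of scope.
#'
#' @param path Text file path.
#' @return Named list of modules; each module is a list with `module_id` and
#'   `blocks` (list of character vectors).
#' @export
parse_module_defs <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  out <- list()
  for (ln in which(keep)) {
    parts <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !nzchar(trimws(parts[1])))
      stop("malformed module definition at line ", ln, call. = FALSE)
    id <- trimws(parts[1])
    if (id %in% names(out))
      stop("duplicate module id '", id, "' at line ", ln, call. = FALSE)
    raw_blocks <- strsplit(trimws(parts[2]), "[[:space:]]+")[[1]]
    if (length(raw_blocks) == 0)
      stop("module '", id, "' has no blocks at line ", ln, call. = FALSE)
    blocks <- lapply(raw_blocks, function(b) {
      alts <- strsplit(b, ",", fixed = TRUE)[[1]]
      alts <- alts[nzchar(alts)]
      if (length(alts) == 0)
        stop("empty block in module '", id, "' at line ", ln, call. = FALSE)
      alts
    })
    out[[id]] <- list(module_id = id, blocks = blocks)
  }
  out
}

#' @rdname parse_module_defs
#' @param modules Named list of module definitions.
#' @export
write_module_defs <- function(modules, path) {
  lines <- vapply(modules, function(m)
    paste0(m$module_id, "\t",
           paste(vapply(m$blocks, paste, character(1), collapse = ","),
                 collapse = " ")), character(1))
  writeLines(unname(lines), path, useBytes = TRUE)
  invisible(path)
}

#' Score the completeness of one module
#'
#' A block is missing iff none of its alternative KOs is present. A module is
#' called complete when at most one block is missing ("complete or nearly
#' complete: no more than one gene missing"). With `strict_alternatives` a
#' block additionally requires *all* of its alternatives.
#'
#' @param present_kos Character vector of KO identifiers present.
#' @param module A module definition (element of [parse_module_defs()]).
#' @param strict_alternatives Require every alternative of a block.
#' @return List with `module_id`, `blocks_total`, `blocks_missing`,
#'   `complete`.
#' @export
module_completeness <- function(present_kos, module, strict_alternatives = FALSE) {
  hit <- vapply(module$blocks, function(b)
    if (strict_alternatives) all(b %in% present_kos) else any(b %in% present_kos),
    logical(1))
  missing <- sum(!hit)
  list(module_id = module$module_id,
       blocks_total = length(module$blocks),
       blocks_missing = missing,
       complete = missing <= 1)
}

#' Completeness of a module collection
#'
#' Applies [module_completeness()] to every module and returns a data frame;
#' `complete_module_ids()` is the convenience wrapper returning just the ids
#' of complete (or nearly complete) modules.
#'
#' @inheritParams module_completeness
#' @param modules Named list of module definitions.
#' @return Data frame with one row per module.
#' @export
completeness_table <- function(present_kos, modules, strict_alternatives = FALSE) {
  rows <- lapply(modules, module_completeness, present_kos = present_kos,
                 strict_alternatives = strict_alternatives)
  out <- do.call(rbind, lapply(rows, as.data.frame))
  rownames(out) <- NULL
  out
}

#' @rdname completeness_table
#' @export
complete_module_ids <- function(present_kos, modules, strict_alternatives = FALSE) {
  tab <- completeness_table(present_kos, modules, strict_alternatives)
  tab$module_id[tab$complete]
}

#' KOs present in a KO table
#'
#' Pools abundance across groups (the survey pools MAGs across lakes before
#' calling modules complete) and returns the KOs whose pooled abundance
#' exceeds `min_abundance`.
#'
#' @param ko_table KOs x groups matrix.
#' @param min_abundance Presence threshold on the pooled abundance
#'   (default 0, i.e. any positive abundance).
#' @param groups Optional subset of group columns to pool over.
#' @return Character vector of KO ids.
#' @export
present_kos <- function(ko_table, min_abundance = 0, groups = NULL) {
  if (!is.null(groups)) ko_table <- ko_table[, groups, drop = FALSE]
  rownames(ko_table)[rowSums(ko_table) > min_abundance]
}

#' Two-set Venn partition of complete modules
#'
#' Splits the modules called complete in the host (e.g. *Microcystis*) and in
#' the microbiome into host-only, shared, and microbiome-only sets — the
#' machine-readable form of the host/microbiome Venn diagram.
#'
#' @param host_complete,microbiome_complete Character vectors of complete
#'   module ids.
#' @return List with sorted `host_only`, `shared`, `microbiome_only`.
#' @export
venn_partition <- function(host_complete, microbiome_complete) {
  list(host_only = sort(setdiff(host_complete, microbiome_complete)),
       shared = sort(intersect(host_complete, microbiome_complete)),
       microbiome_only = sort(setdiff(microbiome_complete, host_complete)))
}

#' Functional distance-decay
#'
#' Bray-Curtis dissimilarity between sites' KO abundance profiles, regressed
#' on great-circle distance with the same Gaussian-identity GLM used for the
#' taxonomic decay.
#'
#' @param ko_table KOs x sites abundance matrix; column names must match
#'   `geo$site`.
#' @param geo Site coordinates data frame.
#' @param radius_km Sphere radius for the distances.
#' @return List with `fit` (a `decay_fit`), `dissimilarity` and `distance`
#'   matrices.
#' @export
functional_decay <- function(ko_table, geo, radius_km = 6371) {
  assert_geo(geo)
  if (!setequal(colnames(ko_table), geo$site))
    stop("KO table sites do not match the coordinates", call. = FALSE)
  profiles <- t(ko_table)[geo$site, , drop = FALSE]
  bc <- bray_curtis(profiles)
  gd <- great_circle_distances(geo, radius_km)
  list(fit = distance_decay_glm(gd, bc), dissimilarity = bc, distance = gd)
}
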