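# End-to-end orchestration: the standard filter chain, the full analysis
# (dissimilarity + decay, alphaNTI/betaNTI, functional comparison) from a
# config list or YAML file, with per-stage derived seeds and a manifest.

#' Apply the standard OTU-table filter chain
#'
#' In order: taxonomy-based exclusion (eukaryotes, archaea, chloroplasts,
#' mitochondria), removal of taxa with fewer than `min_total` total counts,
#' removal of the host group (cyanobacteria), rarefaction to the shallowest
#' sample, replicate pooling. Counts of surviving taxa are reported in the
#' attached `"log"` attribute.
#'
#' @param table Samples x taxa count matrix.
#' @param taxonomy Taxonomy data frame.
#' @param mapping Named sample -> site vector (or `NULL` to skip pooling).
#' @param excluded_terms,min_total,group_term Filter settings (defaults as in
#'   the survey protocol).
#' @param depth Rarefaction depth (`"min"` or integer).
#' @param seed Integer seed for the rarefaction draw.
#' @return Filtered, rarefied, pooled sites x taxa matrix.
#' @export
apply_filter_chain <- function(table, taxonomy, mapping = NULL,
                               excluded_terms = c("eukaryota", "eukaryote",
                                                  "archaea", "chloroplast",
                                                  "mitochondria"),
                               min_total = 100,
                               group_term = "Cyanobacteria",
                               depth = "min", seed) {
  log <- c(input = ncol(table))
  table <- filter_by_taxonomy(table, taxonomy, excluded_terms, missing = "keep")
  log["after_taxonomy_exclusion"] <- ncol(table)
  table <- filter_low_abundance(table, min_total)
  log["after_low_count_filter"] <- ncol(table)
  table <- remove_group(table, taxonomy, group_term)
  log["after_host_removal"] <- ncol(table)
  table <- rarefy(table, depth, seed)
  log["after_rarefaction"] <- ncol(table)
  if (!is.null(mapping)) {
    table <- pool_replicates(table, mapping)
    log["after_pooling"] <- ncol(table)
  }
  attr(table, "log") <- log
  table
}

#' Validate the cross-consistency of pipeline inputs
#'
#' Checks that every table taxon has a taxonomy record and a tree tip, and
#' that every (pooled) site has coordinates. Issues are returned, not
#' raised; an empty character vector means the bundle is consistent.
#'
#' @param table Samples x taxa matrix.
#' @param taxonomy Taxonomy data frame (or `NULL` to skip).
#' @param tree `phylo` (or `NULL` to skip).
#' @param geo Coordinates data frame (or `NULL` to skip).
#' @param mapping Sample -> site vector (or `NULL` if samples are sites).
#' @return Character vector of human-readable issues.
#' @export
validate_inputs <- function(table, taxonomy = NULL, tree = NULL, geo = NULL,
                            mapping = NULL) {
  issues <- character(0)
  taxa <- colnames(table)
  if (!is.null(taxonomy)) {
    miss <- setdiff(taxa, taxonomy$taxon_id)
    if (length(miss))
      issues <- c(issues, paste0("taxa without taxonomy records: ",
                                 paste(miss, collapse = ", ")))
  }
  if (!is.null(tree)) {
    miss <- setdiff(taxa, tree$tip.label)
    if (length(miss))
      issues <- c(issues, paste0("taxa missing from the tree: ",
                                 paste(miss, collapse = ", ")))
  }
  if (!is.null(mapping)) {
    un <- setdiff(rownames(table), names(mapping))
    if (length(un))
      issues <- c(issues, paste0("samples without a site mapping: ",
                                 paste(un, collapse = ", ")))
  }
  if (!is.null(geo)) {
    sites <- if (is.null(mapping)) rownames(table) else unique(unname(mapping))
    miss <- setdiff(sites, geo$site)
    if (length(miss))
      issues <- c(issues, paste0("sites without coordinates: ",
                                 paste(miss, collapse = ", ")))
  }
  issues
}

#' Run the full bloom-microbiome analysis
#'
#' Orchestrates every stage on either simulated or on-disk inputs:
#' filter chain -> Bray-Curtis / weighted UniFrac -> great-circle
#' distance-decay GLMs -> alphaNTI (with t-test and classification) ->
#' betaNTI (with t-test) -> optional functional stage (KO Bray-Curtis decay
#' and the host/microbiome module Venn). Each stage's tables are written
#' under `output_dir` together with a JSON manifest of all parameters and
#' derived seeds; a rerun with the same config is bit-identical.
#'
#' @param config Either a named list or a path to a YAML file. Recognised
#'   fields: `seed` (mandatory), `n_null` (default 999),
#'   `abundance_weighted`, `unifrac_normalized`, `radius_km`, filter settings
#'   (`excluded_terms`, `min_total`, `group_term`), `output_dir`, and either
#'   `simulate:` (fields of [assembly_config()]) or `inputs:` with paths
#'   `otu_table`, `taxonomy`, `tree`, `coordinates`, optional
#'   `replicate_map` (CSV sample,site), `ko_table` (KOs x sites), and
#'   `module_defs` + `host_ko_table` + `microbiome_ko_table` for the Venn.
#' @return List of class `run_report` with the per-stage results; also
#'   written to `output_dir` when given.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config$seed is mandatory", call. = FALSE)
  seed <- as.integer(config$seed)
  n_null <- if (is.null(config$n_null)) 999 else config$n_null
  weighted <- isTRUE(config$abundance_weighted)
  normalized <- if (is.null(config$unifrac_normalized)) TRUE
                else isTRUE(config$unifrac_normalized)
  radius <- if (is.null(config$radius_km)) 6371 else config$radius_km
  excluded <- if (is.null(config$excluded_terms))
    c("eukaryota", "eukaryote", "archaea", "chloroplast", "mitochondria")
  else config$excluded_terms
  min_total <- if (is.null(config$min_total)) 100 else config$min_total
  group_term <- if (is.null(config$group_term)) "Cyanobacteria"
                else config$group_term

  stage <- "load inputs"
  report <- tryCatch({
    if (!is.null(config$simulate)) {
      sim_args <- config$simulate
      sim_args$seed <- if (is.null(sim_args$seed)) derive_seed(seed, "simulate")
                       else sim_args$seed
      cfg <- do.call(assembly_config, sim_args)
      truth <- simulate_survey(cfg)
      table <- truth$communities
      taxonomy <- simulate_taxonomy(truth$tree, derive_seed(seed, "tax"))
      tree <- truth$tree
      geo <- truth$geo
      mapping <- truth$replicate_map
      ko <- NULL; venn_in <- NULL
    } else if (!is.null(config$inputs)) {
      paths <- config$inputs
      table <- read_otu_table(paths$otu_table)
      taxonomy <- read_taxonomy(paths$taxonomy)
      tree <- ape::read.tree(paths$tree)
      geo <- read_coordinates(paths$coordinates)
      mapping <- if (!is.null(paths$replicate_map)) {
        rm_df <- utils::read.csv(paths$replicate_map, stringsAsFactors = FALSE)
        stats::setNames(rm_df$site, rm_df$sample)
      } else NULL
      ko <- if (!is.null(paths$ko_table)) read_ko_table(paths$ko_table) else NULL
      venn_in <- if (!is.null(paths$module_defs)) {
        list(modules = parse_module_defs(paths$module_defs),
             host = read_ko_table(paths$host_ko_table),
             microbiome = read_ko_table(paths$microbiome_ko_table))
      } else NULL
    } else stop("config needs either a 'simulate' or an 'inputs' block",
                call. = FALSE)

    stage <- "validate inputs"
    issues <- validate_inputs(table, taxonomy, tree, geo, mapping)
    if (length(issues))
      stop("inconsistent inputs:\n  ", paste(issues, collapse = "\n  "),
           call. = FALSE)

    stage <- "filter chain"
    filtered <- apply_filter_chain(table, taxonomy, mapping, excluded,
                                   min_total, group_term, "min",
                                   derive_seed(seed, "rarefy"))
    filter_log <- attr(filtered, "log")
    attr(filtered, "log") <- NULL
    geo_f <- geo[match(rownames(filtered), geo$site), ]
    # the supplied tree defines the null pool: taxa-shuffle nulls randomize
    # across all of its tips (prune beforehand for a restricted null)

    stage <- "dissimilarity and decay"
    bc <- bray_curtis(filtered)
    uf <- weighted_unifrac(filtered, tree, normalized = normalized)
    gd <- great_circle_distances(geo_f, radius)
    decay_bc <- distance_decay_glm(gd, bc)
    decay_uf <- distance_decay_glm(gd, uf)

    stage <- "alphaNTI"
    alpha <- alpha_nti(filtered, tree, n_null, weighted,
                       derive_seed(seed, "alpha"))
    alpha_test <- index_t_test(alpha$nti,
                               standardized_null_indices(attr(alpha, "nulls"),
                                                         negate = TRUE))

    stage <- "betaNTI"
    beta <- beta_nti(filtered, tree, n_null, weighted,
                     derive_seed(seed, "beta"))
    beta_vals <- beta$nti[upper.tri(beta$nti)]
    beta_test <- index_t_test(beta_vals,
                              standardized_null_indices(beta$nulls))

    stage <- "functional"
    func <- if (!is.null(ko)) functional_decay(ko, geo_f, radius) else NULL
    venn <- if (!is.null(venn_in)) {
      venn_partition(
        complete_module_ids(present_kos(venn_in$host), venn_in$modules),
        complete_module_ids(present_kos(venn_in$microbiome), venn_in$modules))
    } else NULL

    list(filter_log = filter_log, filtered = filtered,
         bray_curtis = bc, weighted_unifrac = uf, distances = gd,
         decay_bray_curtis = decay_bc, decay_unifrac = decay_uf,
         alpha = alpha, alpha_t_test = alpha_test,
         beta_nti = beta$nti, beta_t_test = beta_test,
         mean_alpha_nti = mean(alpha$nti, na.rm = TRUE),
         mean_beta_nti = mean(beta_vals, na.rm = TRUE),
         functional = func, venn = venn,
         seed = seed, n_null = n_null)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(config$output_dir)) write_report(report, config, config$output_dir)
  class(report) <- "run_report"
  report
}

# Write the per-stage outputs and a manifest; plain text only.
write_report <- function(report, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wm <- function(m, f) utils::write.table(
    cbind(id = rownames(m), as.data.frame(m)), file.path(dir, f),
    sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  write_otu_table(report$filtered, file.path(dir, "filtered_table.tsv"))
  wm(report$bray_curtis, "bray_curtis.tsv")
  wm(report$weighted_unifrac, "weighted_unifrac.tsv")
  wm(report$distances, "distances_km.tsv")
  wm(report$beta_nti, "beta_nti.tsv")
  utils::write.table(report$alpha, file.path(dir, "alpha_nti.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  summary <- list(
    filter_log = as.list(report$filter_log),
    decay_bray_curtis = unclass(report$decay_bray_curtis),
    decay_unifrac = unclass(report$decay_unifrac),
    mean_alpha_nti = report$mean_alpha_nti,
    mean_beta_nti = report$mean_beta_nti,
    alpha_t_test = report$alpha_t_test,
    beta_t_test = report$beta_t_test,
    functional_decay = if (!is.null(report$functional))
      unclass(report$functional$fit) else NULL,
    venn = report$venn)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- list(package_version = as.character(utils::packageVersion("interactome")),
                   config = config,
                   derived_seeds = list(
                     rarefy = derive_seed(config$seed, "rarefy"),
                     alpha = derive_seed(config$seed, "alpha"),
                     beta = derive_seed(config$seed, "beta")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Bloom-microbiome analysis report\n")
  cat("  taxa surviving the filter chain:",
      x$filter_log[["after_rarefaction"]], "\n")
  cat(sprintf("  Bray-Curtis decay : DE = %.2f%%, p = %.3g\n",
              100 * x$decay_bray_curtis$deviance_explained,
              x$decay_bray_curtis$p_value))
  cat(sprintf("  UniFrac decay     : DE = %.2f%%, p = %.3g\n",
              100 * x$decay_unifrac$deviance_explained,
              x$decay_unifrac$p_value))
  cat(sprintf("  mean alphaNTI = %.2f (t = %.2f, p = %.3g)\n",
              x$mean_alpha_nti, x$alpha_t_test$t, x$alpha_t_test$p))
  cat(sprintf("  mean betaNTI  = %.2f (t = %.2f, p = %.3g)\n",
              x$mean_beta_nti, x$beta_t_test$t, x$beta_t_test$p))
  if (!is.null(x$functional))
    cat(sprintf("  functional decay  : DE = %.2f%%, p = %.3g\n",
                100 * x$functional$fit$deviance_explained,
                x$functional$fit$p_value))
  if (!is.null(x$venn))
    cat(sprintf("  modules: %d host-only, %d shared, %d microbiome-only\n",
                length(x$venn$host_only), length(x$venn$shared),
                length(x$venn$microbiome_only)))
  invisible(x)
}
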