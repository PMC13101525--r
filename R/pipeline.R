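## Deterministic per-stage seed derived from the global seed and the
## stage name, so inserting a stage never perturbs another stage's
## randomness. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131)
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Taxonomy-function decoupling analysis
#'
#' Quantifies whether taxonomic turnover is mirrored in functional
#' profiles: Bray-Curtis distance matrices on both tables; a paired
#' Wilcoxon signed-rank comparison of the matched off-diagonal distances
#' (are function-space distances systematically smaller?); a Mantel test
#' between the two matrices (is there any correlation at all?); and
#' ANOSIM + PERMANOVA on both tables when groups are given. Functional
#' redundancy shows up as function distances below taxon distances with
#' a non-significant Mantel correlation.
#'
#' @param taxon_table,function_table abundance matrices over the same
#'   samples (functions as columns in the second).
#' @param groups optional group labels per sample.
#' @param n_perm permutations for Mantel/ANOSIM/PERMANOVA (default 999).
#' @param seed integer seed.
#' @return list with `bc_taxa`, `bc_function` (distance matrices),
#'   `median_bc_taxa`, `median_bc_function`, `wilcoxon_p`, `mantel`, and
#'   (when groups are given) `anosim_taxa`, `anosim_function`,
#'   `permanova_taxa`, `permanova_function`.
#' @export
decoupling_analysis <- function(taxon_table, function_table, groups = NULL,
                                n_perm = 999, seed = NULL) {
  if (!identical(rownames(taxon_table), rownames(function_table)))
    stop("taxon and function tables must cover identical samples in order")
  bc_t <- beta_diversity(taxon_table, "bray_curtis")
  bc_f <- beta_diversity(function_table, "bray_curtis")
  lt <- lower.tri(bc_t)
  wil <- stats::wilcox.test(bc_f[lt], bc_t[lt], paired = TRUE,
                            exact = FALSE)
  man <- mantel_test(bc_t, bc_f, method = "spearman", n_perm = n_perm,
                     seed = if (is.null(seed)) NULL else stage_seed(seed, "mantel"))
  out <- list(bc_taxa = bc_t, bc_function = bc_f,
              median_bc_taxa = stats::median(bc_t[lt]),
              median_bc_function = stats::median(bc_f[lt]),
              wilcoxon_p = wil$p.value, mantel = man)
  if (!is.null(groups)) {
    out$anosim_taxa <- anosim_test(bc_t, groups, n_perm,
                                   stage_seed(seed %||% 0, "anosim_taxa"))
    out$anosim_function <- anosim_test(bc_f, groups, n_perm,
                                       stage_seed(seed %||% 0, "anosim_fun"))
    out$permanova_taxa <- permanova_test(bc_t, groups, n_perm,
                                         stage_seed(seed %||% 0, "permanova_taxa"))
    out$permanova_function <- permanova_test(bc_f, groups, n_perm,
                                             stage_seed(seed %||% 0, "permanova_fun"))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full community-assembly analysis pipeline
#'
#' Orchestrates every stage from a single config: load or simulate data;
#' alpha/beta diversity and PCoA; group statistics; taxonomy-function
#' decoupling; co-occurrence network with stability metrics; neutral
#' community model; core/accessory/specific partitioning. Stage seeds are
#' derived deterministically from the global seed, so the same config and
#' seed reproduce every number bit-identically. Results are written to
#' `outdir` (per-stage TSVs plus a JSON report) and returned invisibly.
#'
#' @param config a named list (or path to a YAML file) with entries:
#'   * `input`: list with `abundance`, optional `functions`, `metadata`
#'     TSV paths; or `synthetic`: list of [generate_redundant_strains()]
#'     arguments — exactly one of the two;
#'   * `stages`: character vector among `diversity`, `ordination`,
#'     `compare`, `decoupling`, `network`, `ncm`, `partition`
#'     (default all applicable);
#'   * optional stage parameter lists `network` (`r_threshold`,
#'     `p_threshold`, `min_prevalence`, `robustness_fraction`,
#'     `robustness_reps`), `ncm` (`N`, `d`, `n_boot`), `compare`
#'     (`n_perm`, `metric`), `partition` (`min_samples`).
#' @param seed global integer seed.
#' @param outdir output directory; `NULL` to skip writing files.
#' @return list of per-stage results, class `assembly_report`.
#' @export
run_pipeline <- function(config, seed = 1, outdir = NULL) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  has_input <- !is.null(config$input)
  has_synth <- !is.null(config$synthetic)
  if (has_input == has_synth)
    stop("config must contain exactly one of 'input' or 'synthetic'")

  report <- list(provenance = list(seed = seed,
                                   package_version = as.character(utils::packageVersion("phycoassembly"))))
  log_stage <- function(...) message("[phycoassembly] ", sprintf(...))

  if (has_synth) {
    args <- config$synthetic
    args$seed <- stage_seed(seed, "synthetic")
    ds <- do.call(generate_redundant_strains, args)
    x <- ds$abundance
    fx <- ds$function_table
    meta <- ds$metadata
    report$synthetic_truth <- ds$truth[c("n_strains", "n_guilds", "redundancy",
                                         "samples_per_strain", "depth")]
  } else {
    x <- read_abundance_table(config$input$abundance,
                              config$input$orientation %||% "samples")
    fx <- if (!is.null(config$input$functions))
      read_abundance_table(config$input$functions,
                           config$input$orientation %||% "samples")
    meta <- if (!is.null(config$input$metadata))
      read_metadata(config$input$metadata)
  }
  groups <- if (!is.null(meta)) stats::setNames(meta$group, rownames(meta))
  log_stage("input: %d samples x %d taxa", nrow(x), ncol(x))

  stages <- config$stages %||%
    c("diversity", "ordination", "compare", if (!is.null(fx)) "decoupling",
      "network", "ncm", "partition")

  run_stage <- function(name, fun) {
    if (!(name %in% stages)) return(NULL)
    log_stage("stage: %s", name)
    tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  report$diversity <- run_stage("diversity", function() {
    alpha_diversity(x)
  })
  bc <- NULL
  if (any(c("ordination", "compare") %in% stages))
    bc <- beta_diversity(x, config$compare$metric %||% "bray_curtis")
  report$ordination <- run_stage("ordination", function() {
    ord <- pcoa_ordination(bc)
    ord$coordinates <- ord$coordinates[, seq_len(min(3, ncol(ord$coordinates))),
                                       drop = FALSE]
    ord
  })
  report$compare <- run_stage("compare", function() {
    if (is.null(groups)) stop("group metadata required")
    n_perm <- config$compare$n_perm %||% 9999
    list(anosim = anosim_test(bc, groups, n_perm, stage_seed(seed, "anosim")),
         permanova = permanova_test(bc, groups, n_perm,
                                    stage_seed(seed, "permanova")))
  })
  report$decoupling <- run_stage("decoupling", function() {
    if (is.null(fx)) stop("function table required for the decoupling stage")
    res <- decoupling_analysis(x, fx, groups,
                               n_perm = config$compare$n_perm %||% 999,
                               seed = seed)
    res[c("median_bc_taxa", "median_bc_function", "wilcoxon_p", "mantel",
          "anosim_taxa", "anosim_function", "permanova_taxa",
          "permanova_function")]
  })
  report$network <- run_stage("network", function() {
    nc <- config$network
    net <- correlation_network(x, nc$r_threshold %||% 0.75,
                               nc$p_threshold %||% 0.01,
                               nc$min_prevalence %||% 0.2)
    m <- network_metrics(net, allow_small = TRUE)
    stab <- if (length(net$nodes) >= 3 && nrow(net$edges) > 0)
      list(robustness = robustness(net, nc$robustness_fraction %||% 0.5,
                                   nc$robustness_reps %||% 100,
                                   stage_seed(seed, "robustness")),
           vulnerability = vulnerability(net)$vulnerability,
           global_efficiency = vulnerability(net)$global_efficiency)
    pos_frac <- if (nrow(net$edges) > 0) mean(net$edges$sign > 0) else NA_real_
    list(metrics = m, stability = stab, positive_edge_fraction = pos_frac,
         network = net)
  })
  report$ncm <- run_stage("ncm", function() {
    nc <- config$ncm
    fit <- fit_ncm(x, N = nc$N, d = nc$d)
    fit <- bootstrap_ncm(fit, nc$n_boot %||% 1000, stage_seed(seed, "ncm_boot"))
    fit
  })
  report$partition <- run_stage("partition", function() {
    if (is.null(groups)) stop("group metadata required")
    part <- partition_taxa(x, groups, config$partition$min_samples %||% 1)
    list(n_core = length(part$core), n_accessory = length(part$accessory),
         n_specific = sum(lengths(part$specific)),
         abundance_share = part$abundance_share,
         intersections = intersection_counts(x, groups,
                                             config$partition$min_samples %||% 1))
  })

  class(report) <- "assembly_report"
  if (!is.null(outdir)) write_report(report, outdir)
  invisible(report)
}

## serialise an assembly_report: JSON summary plus per-stage TSVs
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$diversity))
    utils::write.table(data.frame(sample_id = rownames(report$diversity),
                                  report$diversity),
                       file.path(outdir, "alpha_diversity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$ordination))
    utils::write.table(data.frame(sample_id = rownames(report$ordination$coordinates),
                                  report$ordination$coordinates),
                       file.path(outdir, "pcoa_coordinates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$network$network))
    write_edge_list(report$network$network, file.path(outdir, "edges.tsv"))
  if (!is.null(report$ncm)) {
    fit <- report$ncm
    utils::write.table(data.frame(taxon = rownames(fit$per_taxon),
                                  classify_partitions(fit)),
                       file.path(outdir, "ncm_per_taxon.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$partition))
    utils::write.table(report$partition$intersections,
                       file.path(outdir, "intersections.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report_summary(report),
                       file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

## flatten the report into plain JSON-serialisable scalars
report_summary <- function(report) {
  out <- list(provenance = report$provenance)
  if (!is.null(report$compare))
    out$compare <- list(
      anosim_r = report$compare$anosim$statistic,
      anosim_p = report$compare$anosim$p_value,
      permanova_f = report$compare$permanova$statistic,
      permanova_r2 = report$compare$permanova$r_squared,
      permanova_p = report$compare$permanova$p_value)
  if (!is.null(report$decoupling))
    out$decoupling <- list(
      median_bc_taxa = report$decoupling$median_bc_taxa,
      median_bc_function = report$decoupling$median_bc_function,
      wilcoxon_p = report$decoupling$wilcoxon_p,
      mantel_r = report$decoupling$mantel$r,
      mantel_p = report$decoupling$mantel$p_value)
  if (!is.null(report$network))
    out$network <- c(report$network$metrics, report$network$stability,
                     list(positive_edge_fraction = report$network$positive_edge_fraction))
  if (!is.null(report$ncm))
    out$ncm <- list(Nm = report$ncm$Nm, m = report$ncm$m, N = report$ncm$N,
                    d = report$ncm$d, r_squared = report$ncm$r_squared,
                    ci_low = report$ncm$ci_low, ci_high = report$ncm$ci_high,
                    n_boot = report$ncm$n_boot)
  if (!is.null(report$partition))
    out$partition <- list(n_core = report$partition$n_core,
                          n_accessory = report$partition$n_accessory,
                          n_specific = report$partition$n_specific)
  out
}

#' @export
print.assembly_report <- function(x, ...) {
  cat("Community-assembly analysis report\n")
  s <- report_summary(x)
  if (!is.null(s$compare))
    cat(sprintf("  ANOSIM R = %.3f (p = %.4g); PERMANOVA R2 = %.3f, F = %.2f (p = %.4g)\n",
                s$compare$anosim_r, s$compare$anosim_p, s$compare$permanova_r2,
                s$compare$permanova_f, s$compare$permanova_p))
  if (!is.null(s$decoupling))
    cat(sprintf("  decoupling: median BC taxa %.3f vs functions %.3f; Mantel p = %.3g\n",
                s$decoupling$median_bc_taxa, s$decoupling$median_bc_function,
                s$decoupling$mantel_p))
  if (!is.null(s$network))
    cat(sprintf("  network: %d nodes, %d edges, density %.3f\n",
                s$network$n_nodes, s$network$n_edges, s$network$density))
  if (!is.null(s$ncm))
    cat(sprintf("  NCM: Nm = %.4g [%.4g, %.4g], R2 = %.3f\n",
                s$ncm$Nm, s$ncm$ci_low, s$ncm$ci_high, s$ncm$r_squared))
  if (!is.null(s$partition))
    cat(sprintf("  partition: %d core / %d accessory / %d specific taxa\n",
                s$partition$n_core, s$partition$n_accessory, s$partition$n_specific))
  invisible(x)
}
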