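pipeline_defaults <- function() {
  list(max_distance = 500000, pseudocount = 1.0, expressed_threshold = 3.0,
       anova_alpha = 0.01, delta = 0.2, fc_up = 2.0, fc_down = 0.5,
       pathway_alpha = 0.05, scales = seq(0.5, 1.4, by = 0.1),
       n_boot = 1000, k_min = 2, k_max = 20, linkage = "average",
       seed = 1)
}

#' Validate and complete a pipeline configuration
#'
#' Fills defaults for every stage parameter (the analysis thresholds:
#' 500 kb pair distance, pseudocount 1, expressed threshold 3, ANOVA
#' alpha 0.01, z-value delta 0.2, fold-change cutoffs 2 and 0.5, pathway
#' alpha 0.05) and checks ranges and, in real mode, input paths.
#'
#' @param config Named list. `mode` is `"real"` (requires `sam_paths`
#'   named by sample, `gtf`, `gmt`, `design_tsv`) or `"synthetic"`
#'   (optional `sim` list of [sim_design()] arguments). `outdir` is
#'   required for [run_pipeline()]. Any default may be overridden.
#' @return The completed config (class `rgcflow_config`).
#' @export
validate_config <- function(config) {
  defaults <- pipeline_defaults()
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (is.null(config$mode)) config$mode <- "synthetic"
  if (!config$mode %in% c("real", "synthetic"))
    stop("mode must be 'real' or 'synthetic'")
  bad <- character(0)
  chk <- function(ok, field) if (!ok) bad <<- c(bad, field)
  chk(config$max_distance > 0, "max_distance")
  chk(config$pseudocount >= 0, "pseudocount")
  chk(config$anova_alpha > 0 && config$anova_alpha < 1, "anova_alpha")
  chk(config$pathway_alpha > 0 && config$pathway_alpha < 1, "pathway_alpha")
  chk(config$fc_up > 1, "fc_up")
  chk(config$fc_down > 0 && config$fc_down < 1, "fc_down")
  chk(config$delta > 0, "delta")
  chk(config$n_boot >= 100, "n_boot")
  chk(config$k_min >= 1 && config$k_max >= config$k_min, "k_min/k_max")
  if (length(bad))
    stop("invalid configuration field(s): ", paste(bad, collapse = ", "))
  if (config$mode == "real") {
    need <- c("sam_paths", "gtf", "gmt", "design_tsv")
    miss <- need[vapply(need, function(f) is.null(config[[f]]), TRUE)]
    if (length(miss))
      stop("real mode requires: ", paste(miss, collapse = ", "))
    paths <- c(unlist(config$sam_paths), config$gtf, config$gmt,
               config$design_tsv)
    absent <- paths[!file.exists(paths)]
    if (length(absent))
      stop("missing input file(s): ", paste(absent, collapse = ", "))
    cond <- read_design_tsv(config$design_tsv)
    nosam <- setdiff(names(cond), names(config$sam_paths))
    if (length(nosam))
      stop("design sample(s) without a SAM path: ",
           paste(nosam, collapse = ", "))
  }
  structure(config, class = "rgcflow_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys as in [validate_config()].
#' @return Validated config.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' Run the full expression-profiling pipeline
#'
#' Stages, in order: pair-validity filter, terminal-exon counting, RPK10M,
#' log2, expressed-gene filter, quantile normalization, per-gene ANOVA
#' screen, z-scoring, sample dendrogram with multiscale-bootstrap AU/BP,
#' x-means clustering of gene profiles, hyper-cluster labelling,
#' fold-change gene lists, gene-set over-representation of the hyper
#' clusters, per-comparison pathway screens and the two three-comparison
#' intersection reports. All artifacts are written under `config$outdir`
#' with deterministic names; a rerun with the same config and seed
#' reproduces them byte-identically.
#'
#' @param config List accepted by [validate_config()]; must include
#'   `outdir`. In synthetic mode, `config$sim` (a list of [sim_design()]
#'   arguments) controls the generated inputs, which are written under
#'   `outdir/inputs`.
#' @return A run report (list): per-stage cardinalities, filter stats,
#'   cluster summary, enrichment summary, config echo. Also written as
#'   `report.json`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(unclass(config))
  if (is.null(config$outdir)) stop("config$outdir is required")
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(version = as.character(utils::packageVersion("rgcflow")),
                 mode = config$mode, seed = config$seed)

  if (config$mode == "synthetic") {
    sim_args <- config$sim
    if (is.null(sim_args)) sim_args <- list()
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    design <- do.call(sim_design, sim_args)
    message("stage simulate: generating synthetic inputs")
    inputs <- simulate_inputs(design, file.path(outdir, "inputs"))
    models <- inputs$models
    sets <- inputs$sets
    condition <- inputs$condition
    sam_paths <- inputs$sam_paths
    report$sim_design <- design[setdiff(names(design), "conditions")]
  } else {
    models <- read_gene_models(config$gtf)
    sets <- read_gmt(config$gmt)
    condition <- read_design_tsv(config$design_tsv)
    sam_paths <- unlist(config$sam_paths)
    inputs <- NULL
  }

  message("stage quantify: ", length(sam_paths), " samples, ",
          nrow(models), " genes")
  quant <- quantify_samples(sam_paths, models,
                            max_distance = config$max_distance)
  report$filter_stats <- lapply(quant$filter_stats, function(s)
    s[c("total_pairs", "valid_pairs", "fraction_valid")])
  report$mean_fraction_valid <- mean(vapply(quant$filter_stats,
                                            `[[`, 0, "fraction_valid"))
  write_filter_stats(quant$filter_stats, file.path(outdir, "filter_stats.tsv"))
  write_matrix_tsv(quant$counts, file.path(outdir, "counts.tsv"))

  rpk <- compute_rpk10m(quant$counts, models, quant$mapped_read_total)
  write_matrix_tsv(rpk, file.path(outdir, "rpk10m.tsv"))
  lg <- expr_matrix(log_transform(rpk, config$pseudocount), condition)
  write_matrix_tsv(lg, file.path(outdir, "log2_rpk10m.tsv"),
                   design_path = file.path(outdir, "design.tsv"))

  expressed <- filter_expressed(lg, config$expressed_threshold)
  report$n_genes_total <- nrow(lg$values)
  report$n_genes_expressed <- nrow(expressed$values)
  message("stage expressed filter: ", report$n_genes_expressed, " of ",
          report$n_genes_total, " genes kept")
  if (nrow(expressed$values) == 0L) {
    warning("no expressed genes; downstream stages skipped")
    report$n_genes_selected <- 0L
    return(finish_report(report, config, outdir))
  }
  normalized <- quantile_normalize(expressed)
  write_matrix_tsv(normalized, file.path(outdir, "normalized.tsv"))

  scr <- anova_screen(normalized, alpha = config$anova_alpha)
  utils::write.table(scr$table, file.path(outdir, "anova.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(scr$selected, file.path(outdir, "selected_genes.txt"))
  report$n_genes_selected <- length(scr$selected)
  message("stage ANOVA: ", report$n_genes_selected, " genes at p < ",
          config$anova_alpha)

  fc <- group_fold_change(normalized,
                          default_comparisons(unique(unname(condition))),
                          fc_up = config$fc_up, fc_down = config$fc_down)
  utils::write.table(fc, file.path(outdir, "fold_changes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  lists <- fold_change_gene_lists(fc)
  for (nm in names(lists))
    writeLines(lists[[nm]], file.path(outdir, paste0("genes_", nm, ".txt")))
  report$fold_change_list_sizes <- lengths(lists)

  if (length(scr$selected) < 2L) {
    warning("fewer than two ANOVA-selected genes; clustering skipped")
    return(finish_report(report, config, outdir))
  }
  selected <- with_values(normalized,
                          normalized$values[scr$selected, , drop = FALSE])
  hc <- hcluster_samples(selected, linkage = config$linkage)
  support <- multiscale_bootstrap_support(selected, hc,
                                          scales = config$scales,
                                          n_boot = config$n_boot,
                                          seed = config$seed,
                                          linkage = config$linkage)
  utils::write.table(support, file.path(outdir, "dendrogram_support.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(dendrogram_newick(hc, support),
             file.path(outdir, "dendrogram.nwk"))

  z <- zscore_rows(selected)
  write_matrix_tsv(z, file.path(outdir, "zscores.tsv"))
  xm <- xmeans_cluster(z, k_min = config$k_min, k_max = config$k_max,
                       seed = config$seed)
  centers <- cluster_condition_centers(xm, z)
  hyper <- assign_hyperclusters(centers, delta = config$delta,
                                conditions = unique(unname(condition)))
  report$k <- xm$k
  report$hyper_labels <- stats::setNames(hyper, paste0("cluster", seq_len(xm$k)))
  assign_tab <- data.frame(gene_id = names(xm$assignment),
                           cluster = unname(xm$assignment),
                           hyper_label = hyper[xm$assignment],
                           stringsAsFactors = FALSE)
  utils::write.table(assign_tab, file.path(outdir, "clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(cluster = seq_len(xm$k), hyper_label = hyper, centers,
               check.names = FALSE),
    file.path(outdir, "cluster_centers.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  hm <- export_heatmap_data(z, hc, xm)
  write_matrix_tsv(hm$values, file.path(outdir, "heatmap.tsv"))
  hyperA_genes <- assign_tab$gene_id[assign_tab$hyper_label == "A"]
  hyperB_genes <- assign_tab$gene_id[assign_tab$hyper_label == "B"]
  report$n_hyperA_genes <- length(hyperA_genes)
  report$n_hyperB_genes <- length(hyperB_genes)
  message("stage x-means: k = ", xm$k, "; hyper A ", length(hyperA_genes),
          " genes, hyper B ", length(hyperB_genes), " genes")

  expressed_ids <- rownames(expressed$values)
  annotated <- unique(unlist(lapply(sets, as.character)))
  universe <- intersect(expressed_ids, annotated)
  report$universe_size <- length(universe)
  report$universe_rule <-
    "expressed genes carrying at least one gene-set annotation"
  for (grp in c("A", "B")) {
    genes <- if (grp == "A") hyperA_genes else hyperB_genes
    tab <- if (length(genes) && length(universe))
      suppressWarnings(enrich_gene_list(genes, sets, universe))
    else enrich_gene_list(character(0), sets,
                          if (length(universe)) universe else "placeholder")
    utils::write.table(tab,
                       file.path(outdir, paste0("enrichment_hyper", grp, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report[[paste0("top_enrichment_hyper", grp)]] <-
      if (nrow(tab)) tab$set_id[1L] else NA_character_
  }

  screens <- pathway_screen(lists, sets, universe,
                            alpha = config$pathway_alpha)
  for (nm in names(screens))
    utils::write.table(screens[[nm]]$table,
                       file.path(outdir, paste0("pathways_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  common <- intersect_common_pathways(screens, unique(unname(condition)))
  utils::write.table(common$restored_up,
                     file.path(outdir, "common_restored_up.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(common$restored_down,
                     file.path(outdir, "common_restored_down.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report$n_common_restored_up <- nrow(common$restored_up)
  report$n_common_restored_down <- nrow(common$restored_down)

  if (!is.null(inputs)) {
    truth <- inputs$truth
    planted_A <- truth$gene_id[truth$class == "hyperA"]
    screened_A <- intersect(planted_A, scr$selected)
    recovered <- intersect(planted_A, hyperA_genes)
    report$planted_hyperA <- length(planted_A)
    report$screened_hyperA <- length(screened_A)
    report$recovered_hyperA <- length(recovered)
    report$hyperA_recovery <- if (length(planted_A))
      length(recovered) / length(planted_A) else NA_real_
    # recovery within the population the clustering stage receives
    report$hyperA_recovery_screened <- if (length(screened_A))
      length(intersect(screened_A, hyperA_genes)) / length(screened_A)
    else NA_real_
  }
  finish_report(report, config, outdir)
}

finish_report <- function(report, config, outdir) {
  cfg <- unclass(config)
  cfg$sim <- NULL
  report$config <- cfg[setdiff(names(cfg), c("sam_paths"))]
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}

write_filter_stats <- function(filter_stats, path) {
  rows <- lapply(names(filter_stats), function(s) {
    st <- filter_stats[[s]]
    data.frame(sample = s,
               reason = c("valid", names(st$rejected_by_reason)),
               count = c(st$valid_pairs, unname(st$rejected_by_reason)),
               fraction = c(st$valid_pairs, unname(st$rejected_by_reason)) /
                 max(st$total_pairs, 1L),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Newick serialization of a sample dendrogram with AU/BP node comments
#'
#' @param hc `hclust` from [hcluster_samples()].
#' @param support Optional support table from
#'   [multiscale_bootstrap_support()]; when given, each internal node
#'   carries a `[au=..,bp=..]` comment.
#' @return A single Newick string.
#' @export
dendrogram_newick <- function(hc, support = NULL) {
  clades <- dendrogram_clades(hc)
  lab <- function(i) {
    if (is.null(support)) return("")
    key <- names(clades)[i]
    row <- match(key, support$clade)
    if (is.na(row)) return("")
    sprintf("[au=%.3f,bp=%.3f]", support$au[row], support$bp[row])
  }
  render <- function(i) {
    m <- hc$merge[i, ]
    kid <- function(j) if (j < 0) hc$labels[-j] else render(j)
    sprintf("(%s,%s)%s:%g", kid(m[1]), kid(m[2]), lab(i),
            hc$height[i])
  }
  paste0(sub(":[^:]*$", "", render(nrow(hc$merge))), ";")
}
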