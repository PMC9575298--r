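# End-to-end orchestration: QC -> prevalence filter -> relative -> CLR ->
# nuisance adjustment -> joint Bayesian edges -> thresholded network ->
# triangle motifs, plus the diversity/marker analyses and a stage-count log.

#' Pipeline configuration
#'
#' Collects the analysis constants. The defaults are the study settings:
#' features must be present in at least 15 patients, samples need at least
#' 50 annotated features per table, the JZS prior width is 0.354, and edges
#' enter the network at `log10(BF10) >= 0.5`.
#'
#' @param prevalence_min Minimum feature prevalence in samples (default 15).
#' @param qc_min_features Minimum nonzero features per sample and table
#'   (default 50).
#' @param rscale JZS prior scale (default 0.354).
#' @param bf_log10_threshold Network evidence threshold (default 0.5).
#' @param pseudocount_policy Zero-replacement policy for the CLR step
#'   (see [clr_transform()]).
#' @param covariates Ordered character vector of exactly 10 nuisance
#'   covariate column names (see [default_covariates()]).
#' @param bf_method `"regression"` (default) or `"stretched-beta"`; see
#'   [jzs_log10_bf_from_r()].
#' @param edge_strategy `"screen"` (default; computes feature-score edges
#'   plus the taxon-module edges that can close a triangle, see
#'   [screen_motif_edges()]) or `"full"` (every pairwise edge of the joint
#'   matrix).
#' @param seed Integer seed recorded in the provenance.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(prevalence_min = 15L, qc_min_features = 50L,
                            rscale = 0.354, bf_log10_threshold = 0.5,
                            pseudocount_policy = "half-min-nonzero",
                            covariates = default_covariates(),
                            bf_method = c("regression", "stretched-beta"),
                            edge_strategy = c("screen", "full"),
                            seed = 1L) {
  if (prevalence_min < 1L) stop("prevalence_min must be >= 1")
  if (rscale <= 0) stop("rscale must be positive")
  if (bf_log10_threshold < 0) stop("bf_log10_threshold must be >= 0")
  if (length(covariates) != 10L)
    stop("exactly 10 nuisance covariates must be named (got ",
         length(covariates), ")")
  cfg <- list(prevalence_min = as.integer(prevalence_min),
              qc_min_features = as.integer(qc_min_features),
              rscale = rscale, bf_log10_threshold = bf_log10_threshold,
              pseudocount_policy = pseudocount_policy,
              covariates = covariates,
              bf_method = match.arg(bf_method),
              edge_strategy = match.arg(edge_strategy),
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

maybe_read <- function(x, reader, ...) {
  if (is.character(x) && length(x) == 1L) reader(x, ...) else x
}

#' Run the full association pipeline
#'
#' Executes sample QC, prevalence filtering, conversion to relative
#' abundances, CLR transformation and nuisance adjustment per modality, then
#' the joint Bayesian edge computation, network thresholding, tripartite
#' triangle enumeration for both symptom scores, the marker-symptom
#' associations and the covariate-effect report. Deterministic given inputs
#' and configuration.
#'
#' @param taxa Genus-level count `abundance_table` or path to its TSV.
#' @param modules Module- or KO-level count `abundance_table` or path; if
#'   KO-level, supply `module_defs` to aggregate.
#' @param metadata A `sample_metadata` data frame or path to its TSV.
#' @param config A `pipeline_config`.
#' @param module_defs Optional `module_definitions` (or path) to aggregate a
#'   KO-level table into module abundances first.
#' @param output_dir Optional directory; when given, all artefacts (edge
#'   list, GraphML network, motif/marker/covariate reports, provenance
#'   JSON) are written there.
#' @return A list of class `run_result` with elements `edges`, `network`,
#'   `motifs` (named list per symptom node), `motif_summary`, `markers`,
#'   `covariate_report`, `adjusted` (the residual matrices) and
#'   `provenance` (stage-by-stage sample and feature counts).
#' @export
run_pipeline <- function(taxa, modules, metadata, config = pipeline_config(),
                         module_defs = NULL, output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  taxa <- maybe_read(taxa, read_abundance_table, modality = "taxon")
  modules <- maybe_read(modules, read_abundance_table, modality = "module")
  metadata <- maybe_read(metadata, read_sample_metadata)
  if (!is.null(module_defs)) {
    module_defs <- maybe_read(module_defs, read_module_definitions)
    modules <- aggregate_ko_counts(modules, module_defs)
  }
  missing_cov <- setdiff(config$covariates, colnames(metadata))
  if (length(missing_cov) > 0L)
    stop("configuration error: metadata lacks covariate column(s): ",
         paste(missing_cov, collapse = ", "))

  prov <- list(config = unclass(config),
               input = list(n_samples_taxa = nrow(taxa$values),
                            n_samples_modules = nrow(modules$values),
                            n_taxa = ncol(taxa$values),
                            n_modules = ncol(modules$values)))

  # stage 1: sample QC on annotation richness
  keep <- qc_filter_samples(taxa, modules, config$qc_min_features)
  if (length(keep) == 0L)
    stop("stage qc: no sample passes the annotation-richness QC")
  # stage 1b: covariate completeness (residuals are undefined otherwise)
  meta_keep <- metadata[match(keep, metadata$sample_id), , drop = FALSE]
  if (any(is.na(meta_keep$sample_id)))
    stop("stage qc: metadata is missing sample(s): ",
         paste(keep[is.na(meta_keep$sample_id)], collapse = ", "))
  X <- covariate_design(sample_metadata(meta_keep), config$covariates)
  complete <- rowSums(is.na(X)) == 0L
  if (!all(complete))
    message("stage qc: ", sum(!complete),
            " sample(s) dropped for missing covariates: ",
            paste(keep[!complete], collapse = ", "))
  keep <- keep[complete]
  taxa <- taxa[keep, ]
  modules <- modules[keep, ]
  metadata <- sample_metadata(
    metadata[match(keep, metadata$sample_id), , drop = FALSE])
  prov$qc <- list(n_samples = length(keep), min_features = config$qc_min_features)

  # diversity uses the QC-passed, pre-prevalence-filter genus composition
  taxa_rel_full <- to_relative(taxa)

  # stage 2: prevalence filtering on the retained sample set
  taxa_f <- prevalence_filter(taxa, config$prevalence_min)
  modules_f <- prevalence_filter(modules, config$prevalence_min)
  prov$prevalence <- list(
    min_prevalence = config$prevalence_min,
    n_taxa = ncol(taxa_f$values),
    n_taxa_removed = ncol(taxa$values) - ncol(taxa_f$values),
    n_modules = ncol(modules_f$values),
    n_modules_removed = ncol(modules$values) - ncol(modules_f$values))

  # stage 3: CLR per modality
  taxa_clr <- clr_transform(to_relative(taxa_f), config$pseudocount_policy)
  modules_clr <- clr_transform(to_relative(modules_f),
                               config$pseudocount_policy)

  # stage 4: nuisance adjustment (psychometric scores stay raw)
  taxa_adj <- adjust_nuisance(taxa_clr, metadata, config$covariates)
  modules_adj <- adjust_nuisance(modules_clr, metadata, config$covariates)
  prov$adjustment <- list(covariates = config$covariates,
                          df_resid = taxa_adj$provenance$df_resid)

  cov_report <- rbind(
    cbind(modality = "taxon",
          covariate_effect_report(taxa_clr, metadata, config$covariates)),
    cbind(modality = "module",
          covariate_effect_report(modules_clr, metadata, config$covariates)))

  # stage 5: joint Bayesian edges
  pp <- cbind(HADS_D = metadata$hads_d, WEIMuS = metadata$weimus)
  rownames(pp) <- metadata$sample_id
  edges <- if (config$edge_strategy == "full") {
    joint_edge_matrix(list(taxa_adj, modules_adj, node_block(pp, "PP")),
                      rscale = config$rscale, method = config$bf_method)
  } else {
    screen_motif_edges(taxa_adj, modules_adj, pp, rscale = config$rscale,
                       method = config$bf_method,
                       threshold = config$bf_log10_threshold)
  }
  prov$edges <- list(strategy = config$edge_strategy, n_edges = nrow(edges),
                     n_nodes = ncol(taxa_adj$values) +
                       ncol(modules_adj$values) + 2L)

  # stage 6: network and motifs
  net <- build_network(edges, config$bf_log10_threshold)
  motifs <- list()
  for (s in c("HADS_D", "WEIMuS"))
    motifs[[s]] <- if (s %in% net$nodes$id)
      enumerate_tripartite_triangles(net, s) else empty_motif_df()
  all_motifs <- do.call(rbind, motifs)
  rownames(all_motifs) <- NULL
  summary <- summarize_motifs(all_motifs)
  prov$network <- list(threshold = config$bf_log10_threshold,
                       n_edges_kept = nrow(net$edges),
                       n_motifs = nrow(all_motifs))

  # stage 7: markers and diversity
  markers <- marker_associations(marker_panel(taxa_rel_full, metadata),
                                 rscale = config$rscale,
                                 method = config$bf_method)

  result <- structure(
    list(edges = edges, network = net, motifs = motifs,
         motif_summary = summary, markers = markers,
         covariate_report = cov_report,
         adjusted = list(taxa = taxa_adj, modules = modules_adj),
         provenance = prov),
    class = "run_result")
  if (!is.null(output_dir)) write_run_result(result, output_dir)
  result
}

#' @export
print.run_result <- function(x, ...) {
  cat("run_result:\n")
  print(x$network)
  if (nrow(x$motif_summary) == 0L) {
    cat("  no triangle motifs\n")
  } else {
    for (i in seq_len(nrow(x$motif_summary)))
      cat(sprintf("  %s: %d motifs, %d distinct taxa, %d distinct modules\n",
                  x$motif_summary$pp[i], x$motif_summary$n_motifs[i],
                  x$motif_summary$n_taxa[i], x$motif_summary$n_modules[i]))
  }
  invisible(x)
}

#' Write the artefacts of a pipeline run
#'
#' @param result A `run_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_result <- function(result, dir) {
  stopifnot(inherits(result, "run_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_edge_list(result$edges, file.path(dir, "edges.tsv"))
  write_network_graphml(result$network, file.path(dir, "network.graphml"))
  all_motifs <- do.call(rbind, result$motifs)
  utils::write.table(motif_table(all_motifs),
                     file.path(dir, "motif_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$motif_summary,
                     file.path(dir, "motif_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$markers, file.path(dir, "markers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$covariate_report,
                     file.path(dir, "covariate_effects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(result$provenance,
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Motif analysis from a published edge list
#'
#' Re-runs the network and motif stages on a hand-curated association edge
#' list, such as the transcription of a published motif table. Duplicate
#' rows are deduplicated on unordered pairs; conflicting duplicates (same
#' pair, different Bayes factor) keep the maximum with a warning (see
#' [dedup_edges()]).
#'
#' @param path Path to an edge-list TSV with columns `node_a`,
#'   `modality_a`, `node_b`, `modality_b`, `log10_bf`, `rho`. Defaults to
#'   the packaged transcription of the published depression/fatigue motif
#'   table.
#' @param threshold Network threshold (default 0.5).
#' @return A list with `edges` (deduplicated), `network`, `motifs` (named
#'   list per PP node) and `summary`.
#' @export
run_from_table2 <- function(path = NULL, threshold = 0.5) {
  if (is.null(path))
    path <- system.file("extdata", "table2_edges.tsv", package = "triadnet",
                        mustWork = TRUE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  req <- c("node_a", "modality_a", "node_b", "modality_b", "log10_bf", "rho")
  missing_cols <- setdiff(req, colnames(raw))
  if (length(missing_cols) > 0L)
    stop("edge list lacks column(s): ", paste(missing_cols, collapse = ", "))
  edges <- dedup_edges(raw)
  net <- build_network(edges, threshold)
  pp_nodes <- net$nodes$id[net$nodes$modality == "PP"]
  motifs <- stats::setNames(
    lapply(pp_nodes, function(s) enumerate_tripartite_triangles(net, s)),
    pp_nodes)
  all_motifs <- if (length(motifs) > 0L) do.call(rbind, motifs) else
    empty_motif_df()
  rownames(all_motifs) <- NULL
  list(edges = edges, network = net, motifs = motifs,
       summary = summarize_motifs(all_motifs))
}
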