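#' Pipeline configuration
#'
#' Collects the input paths, thresholds and options of a full scoring
#' run. The threshold defaults are the conventional operating point of
#' this comparative design: enrichment p < 0.05 with positive fold
#' change and >= 2 unique peptides for the comparative route, and SINQ
#' score >= 1e-7 with more than 1 summed spectral count for the
#' exclusivity rescue.
#'
#' @param quant_table,sample_sheet,fasta required input paths.
#' @param contaminants,annotations,prior_edges optional input paths.
#' @param alpha p-value cutoff for the HCIP filter.
#' @param min_unique_peptides unique-peptide cutoff.
#' @param min_sinq minimum per-sample SINQ score for exclusives.
#' @param min_sc exclusives need summed spectral count strictly above
#'   this.
#' @param background_threshold detection fraction defining the
#'   background proteome.
#' @param test `"moderated"` or `"welch"` (see [bscg_statistics()]).
#' @param linkage,metric heat-map clustering options.
#' @param seed seed for the control-group imputation draws.
#' @param out_dir output directory.
#' @return list of class `PipelineConfig`.
#' @export
pipeline_config <- function(quant_table, sample_sheet, fasta,
                            contaminants = NULL, annotations = NULL,
                            prior_edges = NULL,
                            alpha = 0.05, min_unique_peptides = 2L,
                            min_sinq = 1e-7, min_sc = 1L,
                            background_threshold = 0.9,
                            test = "moderated",
                            linkage = "average", metric = "euclidean",
                            seed = 1L, out_dir = "apmscore_out") {
  stopifnot(alpha > 0, alpha < 1, min_unique_peptides >= 0,
            min_sinq >= 0, min_sc >= 0,
            background_threshold > 0, background_threshold <= 1)
  structure(list(quant_table = quant_table, sample_sheet = sample_sheet,
                 fasta = fasta, contaminants = contaminants,
                 annotations = annotations, prior_edges = prior_edges,
                 alpha = alpha,
                 min_unique_peptides = as.integer(min_unique_peptides),
                 min_sinq = min_sinq, min_sc = as.integer(min_sc),
                 background_threshold = background_threshold,
                 test = match.arg(test, c("moderated", "welch")),
                 linkage = linkage, metric = metric,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file's keys are the arguments of [pipeline_config()]; arguments
#' given to `...` override the file.
#'
#' @param path YAML file.
#' @param ... overrides.
#' @return a `PipelineConfig`.
#' @export
pipeline_config_from_yaml <- function(path, ...) {
  cfg <- yaml::read_yaml(path)
  dots <- list(...)
  cfg[names(dots)] <- dots
  do.call(pipeline_config, cfg)
}

.stage <- function(fmt, ...) message(sprintf(paste0("[apmscore] ", fmt), ...))

#' Run the full scoring pipeline
#'
#' read -> background -> normalize -> comparative scoring -> SINQ ->
#' HCIP filter -> exclusivity rescue -> merge -> network summaries ->
#' write. Every stage logs its record counts to the message stream;
#' outputs land under `config$out_dir` (`bscg_results.tsv`,
#' `sinq_scores.tsv`, `exclusives.tsv`, `hcips.tsv`, `edges.tsv`,
#' `heatmap_matrix.tsv`, `summary.json`); identical inputs, config and
#' seed give identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with all intermediate objects (`quant`,
#'   `background`, `normalized`, `bscg`, `sinq`, `exclusives`, `hcips`,
#'   `network`, `report` components).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  .stage("reading quant table %s", config$quant_table)
  qm <- read_quant_table(config$quant_table, config$sample_sheet)
  .stage("%d proteins x %d samples", nrow(qm$intensity), ncol(qm$intensity))
  lengths <- read_fasta_lengths(config$fasta)
  contaminants <- if (!is.null(config$contaminants))
    read_contaminant_list(config$contaminants) else character(0)

  bg <- define_background(qm, contaminants, config$background_threshold)
  .stage("background proteome: %d members at threshold %.2f",
         length(bg$members), config$background_threshold)
  nm <- normalize_to_background(qm, bg)
  .stage("scale factors in [%.3g, %.3g]", min(nm$scale_factors),
         max(nm$scale_factors))

  bscg <- score_all_baits(nm, test = config$test, seed = config$seed)
  .stage("comparative scoring: %d (bait, protein) records", nrow(bscg))
  sinq <- sinq_table(qm, lengths)
  excl <- find_exclusives(sinq, qm$samples, contaminants,
                          config$min_sinq, config$min_sc)
  .stage("SINQ: %d rows, %d exclusive rescues", nrow(sinq), nrow(excl))

  calls <- call_hcips(bscg, qm, contaminants, config$alpha,
                      config$min_unique_peptides, sinq = sinq)
  hcips <- merge_hcips(calls, excl, qm)
  .stage("HCIPs: %d of %d records pass", sum(hcips$passed_filters),
         nrow(hcips))

  net <- build_network(hcips, qm)
  overlap <- NULL
  if (!is.null(config$prior_edges))
    overlap <- known_overlap(hcips, read_prior_edges(config$prior_edges))
  secretory <- NULL
  if (!is.null(config$annotations))
    secretory <- classify_secretory(hcips, read_annotations(config$annotations))
  heat <- if (sum(hcips$passed_filters) >= 2)
    cluster_pvalue_heatmap(hcips, config$linkage, config$metric) else NULL

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- list(alpha = config$alpha,
               min_unique_peptides = config$min_unique_peptides,
               min_sinq = config$min_sinq, min_sc = config$min_sc,
               background_threshold = config$background_threshold,
               test = config$test, seed = config$seed)
  write_outputs(hcips, config$out_dir, network = net, overlap = overlap,
                provenance = prov)
  b <- bscg
  for (cc in c("log2fc", "p_value", "q_value")) b[[cc]] <- .fmt_num(b[[cc]])
  utils::write.table(b, file.path(config$out_dir, "bscg_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sinq, file.path(config$out_dir, "sinq_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(excl, file.path(config$out_dir, "exclusives.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(heat))
    utils::write.table(heat$matrix,
                       file.path(config$out_dir, "heatmap_matrix.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
  .stage("outputs written to %s", config$out_dir)
  invisible(list(quant = qm, background = bg, normalized = nm,
                 bscg = bscg, sinq = sinq, exclusives = excl,
                 hcips = hcips, network = net, overlap = overlap,
                 secretory = secretory, heatmap = heat,
                 config = config))
}
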