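# End-to-end orchestration: normalize -> detect -> test -> classify ->
# cluster -> target multiplicity -> summaries, with every stage output
# written under a run directory.

#' Pipeline configuration
#'
#' @param expression,design paths to the expression and design TSVs
#'   (see [read_expression_table()]).
#' @param interactions optional path to a miRNA-gene interaction TSV;
#'   enables the target-multiplicity stage.
#' @param ct optional path to a qPCR Ct TSV; enables the qPCR concordance
#'   stage.
#' @param reference_assay housekeeping assay name for the Ct table.
#' @param out_dir output directory (created if missing).
#' @param analysis an [analysis_config()].
#' @param contrasts list of [contrast()] objects (default the five
#'   published treatment-group contrasts).
#' @param min_multiplicity candidate threshold for the target stage.
#' @param truth optional planted-truth list from [simulate_expression()];
#'   when given, a truth-vs-called comparison table is emitted.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(expression, design, interactions = NULL,
                            ct = NULL, reference_assay = "sno202",
                            out_dir, analysis = analysis_config(),
                            contrasts = aad_contrasts(),
                            min_multiplicity = 6, truth = NULL) {
  structure(list(expression = expression, design = design,
                 interactions = interactions, ct = ct,
                 reference_assay = reference_assay, out_dir = out_dir,
                 analysis = analysis, contrasts = contrasts,
                 min_multiplicity = min_multiplicity, truth = truth),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes normalization, detection calling, per-contrast testing,
#' classification, clustering and (when inputs are configured) target
#' multiplicity and qPCR concordance, writing each stage's TSV/JSON output
#' plus a manifest under `config$out_dir`. Deterministic given the inputs
#' and configuration.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest of written files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (p in c(config$expression, config$design, config$interactions,
              config$ct)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  manifest <- list()
  cfg <- config$analysis

  inp <- stage("read", read_expression_table(config$expression,
                                             config$design))
  norm <- stage("normalize",
                percentile_normalize(inp$matrix,
                                     cfg$normalization_percentile))
  write_expression_table(norm, out("normalized.tsv"))
  manifest$normalized <- "normalized.tsv"

  detected <- stage("detect", detection_call(norm, inp$design, cfg))
  writeLines(detected, out("detected_probes.txt"))
  manifest$detected <- "detected_probes.txt"

  kept <- expression_matrix(
    norm$values[detected, , drop = FALSE],
    detected = if (!is.null(norm$detected))
      norm$detected[detected, , drop = FALSE])
  de <- stage("differential-expression",
              run_contrasts(kept, inp$design, config$contrasts, cfg))
  write_de_table(de, out("de_table.tsv"))
  manifest$de_table <- "de_table.tsv"

  canonical <- all(c("OVA/OVA", "PBS/PBS", "OVA/OVA DEX") %in%
                     group_levels(inp$design))
  cls <- NULL
  if (canonical) {
    cls <- stage("classify", classify_mirnas(de, cfg))
    summary <- summarize_calls(cls, contrast("OVA/OVA", "PBS/PBS"))
    jsonlite::write_json(summary, out("classification_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$classification_summary <- "classification_summary.json"
  }

  de_ids <- if (!is.null(cls)) rownames(cls$fc)[cls$de_any] else character(0)
  if (length(de_ids) >= 2) {
    sub <- log2(kept$values[de_ids, , drop = FALSE])
    hm <- stage("cluster", zscore_rows(sub))
    col_tree <- stage("cluster", hierarchical_cluster(t(sub)))
    row_tree <- stage("cluster", hierarchical_cluster(sub))
    write_heatmap_matrix(hm, out("heatmap.tsv"), row_tree, col_tree)
    write_tree_newick(col_tree, out("sample_tree.nwk"))
    centroids <- group_centroids(
      expression_matrix(kept$values[de_ids, , drop = FALSE]), inp$design)
    grp_tree <- stage("cluster", hierarchical_cluster(centroids))
    write_tree_newick(grp_tree, out("group_tree.nwk"))
    utils::write.table(group_similarity_order(grp_tree),
                       out("group_similarity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest$heatmap <- "heatmap.tsv"
    manifest$group_similarity <- "group_similarity.tsv"
  }

  if (!is.null(config$interactions) && !is.null(cls)) {
    inter <- stage("targets", read_interactions(config$interactions))
    scores <- stage("targets", multiplicity_scores(inter, cls))
    cand <- candidate_table(scores, config$min_multiplicity)
    write_candidates(cand, out("candidates.tsv"))
    jsonlite::write_json(unclass(summarize_candidates(
      if (nrow(cand)) cand else scores)),
      out("multiplicity_summary.json"), auto_unbox = TRUE, digits = NA)
    manifest$candidates <- "candidates.tsv"
    manifest$multiplicity_summary <- "multiplicity_summary.json"
  }

  if (!is.null(config$ct)) {
    ctab <- stage("qpcr", read_ct_table(config$ct, config$reference_assay))
    rel <- stage("qpcr", relative_expression(ctab))
    utils::write.table(
      data.frame(sample_id = rownames(rel), rel, check.names = FALSE),
      out("qpcr_relative.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    manifest$qpcr_relative <- "qpcr_relative.tsv"
  }

  if (!is.null(config$truth) && !is.null(cls)) {
    truth <- config$truth
    called <- rownames(cls$fc)[cls$de_any]
    comp <- data.frame(
      mirna_id = truth$planted_de$mirna_id,
      true_fc = truth$planted_de$fc,
      called = truth$planted_de$mirna_id %in% called,
      stringsAsFactors = FALSE)
    utils::write.table(comp, out("truth_vs_called.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest$truth_vs_called <- "truth_vs_called.tsv"
  }

  jsonlite::write_json(
    list(analysis = unclass(cfg),
         contrasts = vapply(config$contrasts, contrast_id, character(1)),
         inputs = list(expression = config$expression,
                       design = config$design,
                       interactions = config$interactions,
                       ct = config$ct),
         files = manifest),
    out("manifest.json"), auto_unbox = TRUE, null = "null")
  invisible(list(normalized = norm, detected = detected, de = de,
                 classification = cls, manifest = manifest,
                 out_dir = config$out_dir))
}
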