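# Combinatorial target prioritization: genes predicted to be targeted by
# many differentially expressed miRNAs at once are the most plausible
# genuine targets. "Multiplicity" counts distinct targeting DE miRNAs per
# gene (multiple predicted sites for one miRNA on one gene collapse to a
# single edge), decomposed into up- and downregulated contributors.

de_directions <- function(de, contrast) {
  stopifnot(inherits(de, "de_classification"))
  id <- contrast_id(contrast)
  if (!id %in% colnames(de$fc))
    stop("contrast not in classification: ", id)
  mirnas <- rownames(de$fc)[de$de_any]
  fc <- de$fc[mirnas, id]
  if (any(fc == 1))
    stop("DE miRNA(s) with no direction in ", id, ": ",
         paste(mirnas[fc == 1], collapse = ", "))
  stats::setNames(ifelse(fc > 1, "up", "down"), mirnas)
}

#' Per-gene multiplicity of targeting DE miRNAs
#'
#' For every gene with at least one targeting differentially expressed
#' miRNA: the number of distinct DE miRNAs predicted to target it
#' (`n_total`), split by the direction of change of the targeting miRNA in
#' the stated contrast (`n_up`, `n_down`; the allergic-vs-control contrast
#' by default) and their difference (`diff`). Edges from miRNAs outside the
#' DE set are ignored.
#'
#' @param interactions an [interaction_table()].
#' @param de a `de_classification` from [classify_mirnas()], or a named
#'   character vector of directions ("up"/"down") keyed by DE miRNA id.
#' @param contrast contrast supplying the direction of each DE miRNA
#'   (default OVA/OVA vs PBS/PBS); ignored when `de` is already a
#'   direction vector.
#' @return A `gene_multiplicity` data.frame with columns `gene_id`,
#'   `n_total`, `n_up`, `n_down`, `diff`, sorted by `gene_id`.
#' @export
multiplicity_scores <- function(interactions, de,
                                contrast = lungmir::contrast("OVA/OVA",
                                                             "PBS/PBS")) {
  dir <- if (is.character(de) && !is.null(names(de))) {
    if (!all(de %in% c("up", "down")))
      stop("directions must be 'up' or 'down'")
    de
  } else de_directions(de, contrast)
  keep <- interactions$mirna_id %in% names(dir)
  edges <- interactions[keep, , drop = FALSE]
  if (!nrow(edges)) {
    out <- data.frame(gene_id = character(0), n_total = integer(0),
                      n_up = integer(0), n_down = integer(0),
                      diff = integer(0), stringsAsFactors = FALSE)
    class(out) <- c("gene_multiplicity", "data.frame")
    return(out)
  }
  up_edge <- dir[edges$mirna_id] == "up"
  n_up <- tapply(up_edge, edges$gene_id, sum)
  n_total <- tapply(up_edge, edges$gene_id, length)
  genes <- sort(names(n_total))
  out <- data.frame(gene_id = genes,
                    n_total = as.integer(n_total[genes]),
                    n_up = as.integer(n_up[genes]),
                    stringsAsFactors = FALSE)
  out$n_down <- out$n_total - out$n_up
  out$diff <- out$n_up - out$n_down
  rownames(out) <- NULL
  class(out) <- c("gene_multiplicity", "data.frame")
  out
}

#' Thresholded candidate-gene table
#'
#' Genes targeted by at least `min_multiplicity` distinct DE miRNAs (the
#' published filter uses 6 of the 29), sorted by `n_total` descending with
#' ties broken by gene id.
#'
#' @param scores a `gene_multiplicity` data.frame.
#' @param min_multiplicity minimum `n_total` (>= 1; default 6).
#' @return The filtered, ordered `gene_multiplicity` data.frame.
#' @export
candidate_table <- function(scores, min_multiplicity = 6) {
  stopifnot(min_multiplicity >= 1)
  out <- scores[scores$n_total >= min_multiplicity, , drop = FALSE]
  out <- out[order(-out$n_total, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cumulative multiplicity distribution
#'
#' Fraction of scored genes targeted by at least k DE miRNAs, for
#' k = 1 .. max multiplicity. Every scored gene has at least one targeting
#' DE miRNA, so the k = 1 fraction is 1 and the curve is non-increasing.
#'
#' @param scores a nonempty `gene_multiplicity` data.frame.
#' @return Data.frame with columns `k` and `fraction`.
#' @export
multiplicity_distribution <- function(scores) {
  if (!nrow(scores)) stop("no scored genes")
  ks <- seq_len(max(scores$n_total))
  data.frame(k = ks,
             fraction = vapply(ks, function(k) mean(scores$n_total >= k),
                               numeric(1)))
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Summary of a candidate-gene table
#'
#' Arithmetic means of the four multiplicity columns over the candidates,
#' with nearest-integer roundings (half away from zero) matching the
#' printed "Average" row convention.
#'
#' @param candidates a nonempty `gene_multiplicity` data.frame.
#' @return A `multiplicity_summary` list: `n_candidates`, `mean_total`,
#'   `mean_up`, `mean_down`, `mean_diff`, their `rounded` counterparts and
#'   `max_total`.
#' @export
summarize_candidates <- function(candidates) {
  if (!nrow(candidates)) stop("no candidate genes")
  means <- colMeans(candidates[, c("n_total", "n_up", "n_down", "diff")])
  structure(list(n_candidates = nrow(candidates),
                 mean_total = unname(means["n_total"]),
                 mean_up = unname(means["n_up"]),
                 mean_down = unname(means["n_down"]),
                 mean_diff = unname(means["diff"]),
                 rounded = round_half_away(unname(means)),
                 max_total = max(candidates$n_total)),
            class = "multiplicity_summary")
}

#' @export
print.multiplicity_summary <- function(x, ...) {
  cat(sprintf("%d candidate genes; mean targeting miRNAs %.2f (up %.2f, down %.2f, diff %+.2f); rounded (%d, %d, %d, %+d); max %d\n",
              x$n_candidates, x$mean_total, x$mean_up, x$mean_down,
              x$mean_diff, x$rounded[1], x$rounded[2], x$rounded[3],
              x$rounded[4], x$max_total))
  invisible(x)
}

#' Permutation test for multiplicity enrichment
#'
#' Tests whether the observed number of genes at or above a multiplicity
#' threshold under the true DE miRNA set exceeds what random miRNA subsets
#' of the same size produce. This formalizes the synergy hypothesis as an
#' optional extension; it is not part of the published analysis.
#'
#' @param interactions an [interaction_table()].
#' @param de_set character vector of DE miRNA ids (subset of the table's
#'   miRNAs, or at most its size).
#' @param min_multiplicity candidate threshold (default 6).
#' @param n_perm number of permutations (>= 1; default 999).
#' @param seed integer seed.
#' @return List with `statistic` (observed candidate count), `p_value`
#'   (`(1 + #\{null >= observed\}) / (n_perm + 1)`), `null` (the permuted
#'   counts) and the call parameters.
#' @export
multiplicity_enrichment_test <- function(interactions, de_set,
                                         min_multiplicity = 6,
                                         n_perm = 999, seed) {
  if (n_perm < 1) stop("'n_perm' must be at least 1")
  universe <- unique(interactions$mirna_id)
  de_set <- unique(as.character(de_set))
  if (length(de_set) > length(universe))
    stop("DE set larger than the miRNA universe of the table")
  count_at <- function(set) {
    keep <- interactions$mirna_id %in% set
    if (!any(keep)) return(0L)
    sum(table(interactions$gene_id[keep]) >= min_multiplicity)
  }
  observed <- count_at(de_set)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i)
      count_at(sample(universe, length(de_set))), integer(1))
  })
  list(statistic = observed,
       p_value = (1 + sum(null >= observed)) / (n_perm + 1),
       null = null, min_multiplicity = min_multiplicity,
       n_perm = n_perm, de_set = de_set)
}

#' Write a candidate table as TSV
#' @param x a `gene_multiplicity` data.frame.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_candidates <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
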