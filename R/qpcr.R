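# qPCR relative quantification against a housekeeping assay (2^-dCt) and
# array-vs-qPCR fold-change concordance.

#' qPCR cycle-threshold table
#'
#' @param ct numeric matrix of Ct values, samples in rows (rownames =
#'   sample ids), assays in columns; must contain the reference assay.
#' @param reference_assay name of the housekeeping assay column (e.g.
#'   sno202 for miRNA assays, HPRT for mRNA).
#' @return An object of class `ct_table`.
#' @export
ct_table <- function(ct, reference_assay) {
  stopifnot(is.matrix(ct), is.numeric(ct))
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stop("'ct' must carry sample ids as rownames and assay ids as colnames")
  if (!reference_assay %in% colnames(ct))
    stop("reference assay not in table: ", reference_assay)
  if (any(is.infinite(ct)))
    stop("Ct values must be finite")
  structure(list(ct = ct, reference_assay = reference_assay),
            class = "ct_table")
}

#' @export
print.ct_table <- function(x, ...) {
  cat(sprintf("ct_table: %d samples x %d assays (reference: %s)\n",
              nrow(x$ct), ncol(x$ct), x$reference_assay))
  invisible(x)
}

#' Relative expression by the 2^-dCt method
#'
#' For every sample and assay, `2^-(Ct_assay - Ct_reference)`: expression
#' relative to the housekeeping assay, assuming doubling per cycle. The
#' reference column itself maps to 1 for all samples. No calibrator sample
#' is used.
#'
#' @param ct a [ct_table()].
#' @return Numeric matrix of relative expression values, samples x assays.
#' @export
relative_expression <- function(ct) {
  stopifnot(inherits(ct, "ct_table"))
  ref <- ct$ct[, ct$reference_assay]
  bad <- rownames(ct$ct)[is.na(ref)]
  if (length(bad))
    stop("missing reference Ct for sample(s): ", paste(bad, collapse = ", "))
  2^-(ct$ct - ref)
}

#' Group fold change from qPCR relative expression
#'
#' Signed fold change of the group geometric means of 2^-dCt values, per
#' assay, for one contrast.
#'
#' @param rel relative-expression matrix from [relative_expression()].
#' @param design a [group_design()] covering the rows of `rel`.
#' @param contrast a [contrast()].
#' @return Named numeric vector of signed fold changes, one per assay.
#' @export
group_fold_change_qpcr <- function(rel, design, contrast) {
  for (g in c(contrast$numerator, contrast$denominator)) {
    if (!g %in% group_levels(design)) stop("group absent from design: ", g)
  }
  num <- intersect(group_samples(design, contrast$numerator),
                   rownames(rel))
  den <- intersect(group_samples(design, contrast$denominator),
                   rownames(rel))
  if (!length(num) || !length(den))
    stop("empty group in contrast ", contrast_id(contrast))
  gm <- function(rows) 2^colMeans(log2(rel[rows, , drop = FALSE]))
  signed_fold_change(gm(num), gm(den))
}

#' Cross-platform fold-change concordance
#'
#' Compares per-miRNA signed fold changes from two platforms (e.g.
#' microarray vs qPCR) over their shared labels: fraction of label pairs
#' with agreeing direction of change, and the Spearman rank correlation of
#' the signed fold changes.
#'
#' @param fc_a,fc_b named numeric vectors of signed fold changes.
#' @return A `concordance_report`: list with `labels`, `fc_a`, `fc_b`
#'   (aligned), `sign_concordance` and `rank_correlation`.
#' @export
platform_concordance <- function(fc_a, fc_b) {
  shared <- intersect(names(fc_a), names(fc_b))
  if (length(shared) < 2)
    stop("need at least 2 shared labels, got ", length(shared))
  a <- fc_a[shared]; b <- fc_b[shared]
  # direction of a signed fold change: fc > 1 up, fc < 0 down, fc = 1 flat
  dir <- function(fc) ifelse(fc > 1, 1L, ifelse(fc < 0, -1L, 0L))
  structure(list(labels = shared, fc_a = a, fc_b = b,
                 sign_concordance = mean(dir(a) == dir(b)),
                 rank_correlation = stats::cor(a, b, method = "spearman")),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("concordance over %d miRNAs: sign %.2f, Spearman rho %.2f\n",
              length(x$labels), x$sign_concordance, x$rank_correlation))
  invisible(x)
}
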