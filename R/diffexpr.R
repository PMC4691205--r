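# Differential-expression core: normalization, detection, signed fold
# changes, exact Mann-Whitney testing, per-contrast calling and
# classification over the four-group design.

#' Percentile-shift normalization
#'
#' Aligns samples on the log2 scale so that each sample's chosen intensity
#' percentile equals the across-sample median of that percentile. The shift
#' is multiplicative on the raw scale, so within-sample order is preserved
#' and zeros stay zero. Percentiles are computed over each sample's positive
#' intensities.
#'
#' @param matrix an [expression_matrix()].
#' @param percentile percentile in (0, 100) to align (default 75).
#' @return A normalized [expression_matrix()].
#' @export
percentile_normalize <- function(matrix, percentile = 75) {
  stopifnot(inherits(matrix, "expression_matrix"),
            percentile > 0, percentile < 100)
  v <- matrix$values
  q <- vapply(seq_len(ncol(v)), function(j) {
    pos <- v[, j][v[, j] > 0]
    if (!length(pos))
      stop("sample has no positive intensities: ", colnames(v)[j])
    stats::quantile(log2(pos), percentile / 100, names = FALSE)
  }, numeric(1))
  shift <- stats::median(q) - q
  out <- sweep(v, 2, 2^shift, `*`)
  expression_matrix(out, detected = matrix$detected)
}

#' Group-level detection calling
#'
#' A probe is called detected when, in at least one treatment group, at
#' least `detection_fraction` of the replicates exceed the detection floor
#' (strictly). When the matrix carries scanner detection flags those are
#' used in place of the floor comparison.
#'
#' @param matrix a normalized [expression_matrix()].
#' @param design a [group_design()].
#' @param config an [analysis_config()] supplying `detection_fraction` and
#'   `detection_floor`.
#' @return Character vector of detected probe ids (subset of the matrix's
#'   probes, input order preserved).
#' @export
detection_call <- function(matrix, design, config = analysis_config()) {
  stopifnot(inherits(matrix, "expression_matrix"),
            inherits(design, "group_design"))
  above <- if (!is.null(matrix$detected)) matrix$detected
           else matrix$values > config$detection_floor
  hit <- rep(FALSE, nrow(above))
  for (g in group_levels(design)) {
    cols <- group_samples(design, g)
    frac <- rowMeans(above[, cols, drop = FALSE])
    hit <- hit | frac >= config$detection_fraction
  }
  probe_ids(matrix)[hit]
}

#' Signed fold change
#'
#' Ratio convention in which downregulation is reported as a negative
#' reciprocal: for r = num/den, the result is r when r >= 1 and -1/r
#' otherwise, so every value satisfies |fc| >= 1 and a two-fold decrease
#' reads -2.
#'
#' @param mean_num,mean_den positive group summary values (vectorized).
#' @return Signed fold change(s), |fc| >= 1.
#' @export
signed_fold_change <- function(mean_num, mean_den) {
  if (any(mean_num <= 0) || any(mean_den <= 0))
    stop("group means must be positive")
  r <- mean_num / mean_den
  ifelse(r >= 1, r, -1 / r)
}

# cache of exact null rank-sum distributions, keyed by "n1:n2" (untied case)
.mw_cache <- new.env(parent = emptyenv())

# Null distribution of the rank-sum of the first sample over all
# choose(N, n1) assignments of the pooled ranks.
mw_null_ranksums <- function(ranks, n1, tied) {
  N <- length(ranks)
  key <- paste0(n1, ":", N - n1)
  if (!tied && !is.null(.mw_cache[[key]])) return(.mw_cache[[key]])
  idx <- utils::combn(N, n1)
  w <- colSums(array(ranks[idx], dim = dim(idx)))
  if (!tied) .mw_cache[[key]] <- w
  w
}

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact by full enumeration of all rank assignments when the pooled size is
#' at most 20 (the study's 6 vs 6 comparisons are exact), with mid-ranks for
#' ties; for larger samples the normal approximation with tie correction is
#' used. The two-sided p-value is the null probability of a rank-sum at
#' least as far from its expectation as the observed one.
#'
#' @param xs,ys numeric samples (both nonempty).
#' @return Two-sided p-value in (0, 1].
#' @export
mann_whitney_exact <- function(xs, ys) {
  if (!length(xs) || !length(ys))
    stop("both samples must be nonempty")
  n1 <- length(xs); n2 <- length(ys); N <- n1 + n2
  ranks <- rank(c(xs, ys))
  w <- sum(ranks[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  if (N <= 20) {
    tied <- anyDuplicated(c(xs, ys)) > 0
    null_w <- mw_null_ranksums(ranks, n1, tied)
    return(mean(abs(null_w - mu) >= abs(w - mu) - 1e-12))
  }
  ties <- table(ranks)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  z <- (w - mu) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (wraps [stats::p.adjust()] after
#' validating the inputs). Offered as an option; the default analysis uses
#' raw p-values at 0.05.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

group_log2_means <- function(values, design) {
  lv <- group_levels(design)
  out <- matrix(NA_real_, nrow(values), length(lv),
                dimnames = list(rownames(values), lv))
  for (g in lv) {
    cols <- group_samples(design, g)
    out[, g] <- rowMeans(log2(values[, cols, drop = FALSE]))
  }
  out
}

#' Per-contrast differential-expression table
#'
#' For every probe of a normalized, detection-filtered matrix and every
#' contrast: the signed fold change of the group geometric means, the
#' two-sided Mann-Whitney p-value on the replicate intensities, an optional
#' BH-adjusted p-value, and the call
#' (`up` when fc >= fc_threshold and p < alpha, `down` when
#' fc <= -fc_threshold and p < alpha, else `ns`; the adjusted p is used when
#' `adjust_method = "BH"`).
#'
#' @param matrix a normalized [expression_matrix()] restricted to detected
#'   probes (all intensities positive).
#' @param design a [group_design()].
#' @param contrasts list of [contrast()] objects.
#' @param config an [analysis_config()].
#' @return A `de_table` data.frame with columns `mirna_id`, `contrast`,
#'   `fc`, `p_raw`, `p_adj`, `call`; the contrast list is kept in
#'   `attr(, "contrasts")`.
#' @export
run_contrasts <- function(matrix, design, contrasts = aad_contrasts(),
                          config = analysis_config()) {
  stopifnot(inherits(matrix, "expression_matrix"))
  v <- matrix$values
  if (any(v <= 0))
    stop("run_contrasts expects positive (normalized, detected) intensities")
  for (ct in contrasts) {
    miss <- setdiff(c(ct$numerator, ct$denominator), group_levels(design))
    if (length(miss))
      stop("contrast group(s) absent from design: ",
           paste(miss, collapse = ", "))
  }
  gm <- group_log2_means(v, design)  # probes x groups, log2 geometric means
  out <- lapply(contrasts, function(ct) {
    fc <- signed_fold_change(2^gm[, ct$numerator], 2^gm[, ct$denominator])
    num_cols <- group_samples(design, ct$numerator)
    den_cols <- group_samples(design, ct$denominator)
    p <- vapply(seq_len(nrow(v)), function(i)
      mann_whitney_exact(v[i, num_cols], v[i, den_cols]), numeric(1))
    data.frame(mirna_id = rownames(v), contrast = contrast_id(ct),
               fc = fc, p_raw = p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  if (config$adjust_method == "BH") {
    tab$p_adj <- stats::ave(tab$p_raw, tab$contrast, FUN = bh_adjust)
    p_use <- tab$p_adj
  } else {
    tab$p_adj <- NA_real_
    p_use <- tab$p_raw
  }
  tab$call <- ifelse(tab$fc >= config$fc_threshold & p_use < config$alpha,
                     "up",
              ifelse(tab$fc <= -config$fc_threshold & p_use < config$alpha,
                     "down", "ns"))
  structure(tab, contrasts = contrasts,
            class = c("de_table", "data.frame"))
}

#' Write a differential-expression table as TSV
#' @param de a `de_table` from [run_contrasts()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(as.data.frame(de), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Normalize the two accepted inputs of classify_mirnas into matrices:
# fc (always) and p (NULL in fold-change-only mode).
de_matrices <- function(de) {
  if (inherits(de, "fold_change_table")) {
    list(fc = de$fc, p = NULL, contrasts = de$contrasts)
  } else if (inherits(de, "de_table")) {
    contrasts <- attr(de, "contrasts")
    ids <- unique(de$mirna_id)
    cts <- vapply(contrasts, contrast_id, character(1))
    fc <- matrix(NA_real_, length(ids), length(cts),
                 dimnames = list(ids, cts))
    p <- fc
    use_adj <- !all(is.na(de$p_adj))
    fc[cbind(match(de$mirna_id, ids), match(de$contrast, cts))] <- de$fc
    p[cbind(match(de$mirna_id, ids), match(de$contrast, cts))] <-
      if (use_adj) de$p_adj else de$p_raw
    list(fc = fc, p = p, contrasts = contrasts)
  } else stop("'de' must be a de_table or a fold_change_table")
}

#' Classify miRNAs: calls, any-contrast alteration, steroid sensitivity, Venn
#'
#' Applies the dual criterion per contrast (|fc| >= `fc_threshold`, and
#' p < `alpha` when p-values are available; with a [fold_change_table()]
#' input the classification is fold-change-only, which is how the published
#' printed table is exercised). Derives:
#' \describe{
#'   \item{de_any}{altered (non-`ns` call) in at least one contrast;}
#'   \item{steroid_sensitive}{|fc| >= threshold in the steroid contrast
#'     (allergic vs dexamethasone-treated), i.e. the allergic alteration is
#'     reverted by steroid treatment;}
#'   \item{venn_region}{membership pattern of each altered miRNA over the
#'     three headline comparisons (allergic vs control, steroid-treated vs
#'     control, allergic vs steroid-treated).}
#' }
#'
#' @param de a `de_table` (from [run_contrasts()]) or a
#'   [fold_change_table()].
#' @param config an [analysis_config()].
#' @param steroid_contrast the contrast defining steroid sensitivity
#'   (default OVA/OVA vs OVA/OVA DEX).
#' @param venn_contrasts list of the three contrasts spanning the Venn
#'   partition.
#' @return A `de_classification`: list with `calls` (miRNA x contrast
#'   character matrix of up/down/ns), `fc`, `p` (or NULL), `de_any`,
#'   `steroid_sensitive` (logical vectors named by miRNA), `venn_region`
#'   (character, `"none"` when an altered miRNA falls outside all three
#'   comparisons), `contrasts`, `config`.
#' @export
classify_mirnas <- function(de, config = analysis_config(),
                            steroid_contrast = contrast("OVA/OVA",
                                                        "OVA/OVA DEX"),
                            venn_contrasts = list(
                              contrast("OVA/OVA", "PBS/PBS"),
                              contrast("OVA/OVA DEX", "PBS/PBS"),
                              contrast("OVA/OVA", "OVA/OVA DEX"))) {
  m <- de_matrices(de)
  have <- colnames(m$fc)
  need <- c(contrast_id(steroid_contrast),
            vapply(venn_contrasts, contrast_id, character(1)))
  miss <- setdiff(need, have)
  if (length(miss))
    stop("required contrast(s) missing: ", paste(miss, collapse = "; "))
  sig <- if (is.null(m$p)) TRUE else m$p < config$alpha
  calls <- ifelse(m$fc >= config$fc_threshold & sig, "up",
           ifelse(m$fc <= -config$fc_threshold & sig, "down", "ns"))
  de_any <- apply(calls != "ns", 1, any)
  steroid <- abs(m$fc[, contrast_id(steroid_contrast)]) >=
    config$fc_threshold
  venn_ids <- vapply(venn_contrasts, contrast_id, character(1))
  venn_region <- apply(calls[, venn_ids, drop = FALSE] != "ns", 1,
                       function(hit) {
                         if (!any(hit)) "none"
                         else paste(venn_ids[hit], collapse = " & ")
                       })
  venn_region[!de_any] <- NA_character_
  structure(list(calls = calls, fc = m$fc, p = m$p,
                 de_any = de_any, steroid_sensitive = steroid,
                 venn_region = venn_region,
                 contrasts = m$contrasts, config = config),
            class = "de_classification")
}

#' @export
print.de_classification <- function(x, ...) {
  cat(sprintf("de_classification: %d miRNAs, %d contrasts; %d altered, %d steroid-sensitive\n",
              nrow(x$calls), ncol(x$calls), sum(x$de_any),
              sum(x$steroid_sensitive[x$de_any])))
  invisible(x)
}

#' Summary counts over the differentially expressed set
#'
#' Counts over the miRNAs altered in at least one contrast (`de_any`):
#' direction of change in the stated contrast by fold-change sign
#' (`n_up`: fc > 1, `n_down`: fc < 0, `n_unchanged`: fc = 1 exactly), the
#' number altered in that contrast under the full calling criterion
#' (`n_altered`), the steroid-sensitive count, and the size of the
#' `de_any` set.
#'
#' @param cls a `de_classification`.
#' @param contrast a [contrast()] present in the classification.
#' @return Named list of counts: `n_up`, `n_down`, `n_unchanged`,
#'   `n_altered`, `n_steroid_sensitive`, `n_de_any`.
#' @export
summarize_calls <- function(cls, contrast) {
  stopifnot(inherits(cls, "de_classification"))
  id <- contrast_id(contrast)
  if (!id %in% colnames(cls$fc))
    stop("contrast not in classification: ", id)
  fc <- cls$fc[cls$de_any, id]
  list(n_up = sum(fc > 1),
       n_down = sum(fc < 0),
       n_unchanged = sum(fc == 1),
       n_altered = sum(cls$calls[cls$de_any, id] != "ns"),
       n_steroid_sensitive = sum(cls$steroid_sensitive[cls$de_any]),
       n_de_any = sum(cls$de_any))
}
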