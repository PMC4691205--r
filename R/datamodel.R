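#' @keywords internal
"_PACKAGE"

# Canonical treatment groups of the four-arm ovalbumin model:
# PBS-sensitised/PBS-challenged, PBS-sensitised/OVA-challenged,
# OVA-sensitised/challenged, and OVA-sensitised/challenged + dexamethasone.
AAD_GROUPS <- c("PBS/PBS", "PBS/OVA", "OVA/OVA", "OVA/OVA DEX")

#' Expression matrix of probe intensities
#'
#' Container for a probes x samples grid of nonnegative microarray
#' intensities, with optional per-cell detection flags (same shape).
#' Probe and sample identifiers are opaque, case-sensitive and unique.
#'
#' @param values numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids); all values must be >= 0.
#' @param detected optional logical matrix of the same dimensions marking
#'   per-cell detection calls from the scanner software.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, detected = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry probe ids as rownames and sample ids as colnames")
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup))
    stop("duplicate probe id(s): ", paste(dup, collapse = ", "))
  dup <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup))
    stop("duplicate sample id(s): ", paste(dup, collapse = ", "))
  if (anyNA(values) || any(values < 0))
    stop("intensities must be nonnegative and non-missing")
  if (!is.null(detected)) {
    if (!is.logical(detected) || !identical(dim(detected), dim(values)))
      stop("'detected' must be a logical matrix with the shape of 'values'")
    dimnames(detected) <- dimnames(values)
  }
  structure(list(values = values, detected = detected),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d probes x %d samples%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$detected)) "" else " (with detection flags)"))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

probe_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

#' Sample-to-group design
#'
#' @param sample_id character vector of sample identifiers.
#' @param group character vector (same length) of group labels. Group order
#'   follows first appearance unless `groups` is given.
#' @param groups optional character vector fixing the group order.
#' @return An object of class `group_design`: a data.frame with columns
#'   `sample_id` and `group` (a factor with the stated level order).
#' @export
group_design <- function(sample_id, group, groups = NULL) {
  sample_id <- as.character(sample_id)
  group <- as.character(group)
  if (length(sample_id) != length(group))
    stop("'sample_id' and 'group' must have equal length")
  dup <- unique(sample_id[duplicated(sample_id)])
  if (length(dup))
    stop("duplicate sample id(s) in design: ", paste(dup, collapse = ", "))
  if (is.null(groups)) groups <- unique(group)
  if (!all(group %in% groups))
    stop("group label(s) outside the declared set: ",
         paste(setdiff(group, groups), collapse = ", "))
  if (!all(groups %in% group))
    stop("empty group(s): ", paste(setdiff(groups, group), collapse = ", "))
  structure(data.frame(sample_id = sample_id,
                       group = factor(group, levels = groups),
                       stringsAsFactors = FALSE),
            class = c("group_design", "data.frame"))
}

group_levels <- function(design) levels(design$group)

#' Samples belonging to one group
#' @param design a `group_design`.
#' @param group a group label.
#' @return Character vector of sample ids.
#' @export
group_samples <- function(design, group) {
  if (!group %in% group_levels(design))
    stop("unknown group: ", group)
  design$sample_id[design$group == group]
}

#' A two-group contrast (numerator vs denominator)
#'
#' Fold changes are reported for `numerator` relative to `denominator`,
#' e.g. `contrast("OVA/OVA", "PBS/PBS")` for the allergic-vs-control
#' comparison.
#'
#' @param numerator,denominator distinct group labels.
#' @return An object of class `contrast`.
#' @export
contrast <- function(numerator, denominator) {
  if (identical(numerator, denominator))
    stop("numerator and denominator must differ")
  structure(list(numerator = numerator, denominator = denominator),
            class = "contrast")
}

#' @export
format.contrast <- function(x, ...) paste(x$numerator, "vs", x$denominator)

#' @export
print.contrast <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

contrast_id <- function(x) {
  if (inherits(x, "contrast")) format(x) else as.character(x)
}

# Parse "A vs B" back into a contrast; used when contrasts arrive as the
# column headers of a printed fold-change table.
parse_contrast <- function(id) {
  parts <- strsplit(id, " vs ", fixed = TRUE)[[1]]
  if (length(parts) != 2)
    stop("cannot parse contrast id: ", id)
  contrast(parts[1], parts[2])
}

#' The five printed treatment-group contrasts
#'
#' The contrasts of the published fold-change table, in printed order:
#' PBS/OVA vs PBS/PBS; OVA/OVA vs PBS/PBS; OVA/OVA vs PBS/OVA;
#' OVA/OVA vs OVA/OVA DEX; OVA/OVA DEX vs PBS/PBS.
#'
#' @return List of `contrast` objects.
#' @export
aad_contrasts <- function() {
  list(contrast("PBS/OVA", "PBS/PBS"),
       contrast("OVA/OVA", "PBS/PBS"),
       contrast("OVA/OVA", "PBS/OVA"),
       contrast("OVA/OVA", "OVA/OVA DEX"),
       contrast("OVA/OVA DEX", "PBS/PBS"))
}

#' Signed fold-change table
#'
#' Stores signed fold changes (see [signed_fold_change()] for the sign
#' convention: every value satisfies |fc| >= 1) for a set of miRNAs over an
#' ordered list of contrasts.
#'
#' @param fc numeric matrix, miRNAs in rows (rownames = miRNA ids), one
#'   column per contrast.
#' @param contrasts list of `contrast` objects, one per column.
#' @return An object of class `fold_change_table`.
#' @export
fold_change_table <- function(fc, contrasts) {
  if (!is.matrix(fc) || !is.numeric(fc))
    stop("'fc' must be a numeric matrix")
  if (is.null(rownames(fc)))
    stop("'fc' must carry miRNA ids as rownames")
  if (anyDuplicated(rownames(fc)))
    stop("duplicate miRNA ids")
  if (length(contrasts) != ncol(fc))
    stop("number of contrasts must match the number of fc columns")
  contrasts <- lapply(contrasts, function(ct)
    if (inherits(ct, "contrast")) ct else parse_contrast(ct))
  if (any(abs(fc) < 1))
    stop("signed fold changes must satisfy |fc| >= 1")
  colnames(fc) <- vapply(contrasts, contrast_id, character(1))
  structure(list(fc = fc, contrasts = contrasts),
            class = "fold_change_table")
}

#' @export
print.fold_change_table <- function(x, ...) {
  cat(sprintf("fold_change_table: %d miRNAs x %d contrasts\n",
              nrow(x$fc), ncol(x$fc)))
  invisible(x)
}

#' Analysis configuration
#'
#' Thresholds and options shared across the differential-expression stages.
#'
#' @param fc_threshold minimum absolute signed fold change for an
#'   up/down call (default 2, the published cut-off).
#' @param alpha significance level on the (raw or adjusted) p-value
#'   (default 0.05).
#' @param normalization_percentile percentile (0-100, exclusive) aligned
#'   across samples by [percentile_normalize()] (default 75).
#' @param detection_fraction fraction of replicates in a group that must
#'   exceed the detection floor for a group-level detection call
#'   (default 0.6, i.e. at least 4 of 6 replicates at the study size).
#' @param detection_floor intensity below or at which a probe is considered
#'   not expressed (default 4).
#' @param adjust_method multiple-testing adjustment: `"none"` (raw p-values,
#'   matching the published analysis) or `"BH"` (Benjamini-Hochberg).
#' @param rng_seed integer seed recorded for stochastic stages.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(fc_threshold = 2, alpha = 0.05,
                            normalization_percentile = 75,
                            detection_fraction = 0.6,
                            detection_floor = 4,
                            adjust_method = c("none", "BH"),
                            rng_seed = 1L) {
  adjust_method <- match.arg(adjust_method)
  stopifnot(is.numeric(fc_threshold), length(fc_threshold) == 1,
            fc_threshold > 0,
            is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha < 1,
            normalization_percentile > 0, normalization_percentile < 100,
            detection_fraction > 0, detection_fraction <= 1,
            detection_floor >= 0)
  structure(list(fc_threshold = fc_threshold, alpha = alpha,
                 normalization_percentile = as.integer(normalization_percentile),
                 detection_fraction = detection_fraction,
                 detection_floor = detection_floor,
                 adjust_method = adjust_method,
                 rng_seed = as.integer(rng_seed)),
            class = "analysis_config")
}

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's .Random.seed afterwards: generators must not leak global state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
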