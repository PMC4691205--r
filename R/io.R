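# Readers and writers for the package's tab-separated interchange formats.
# All files are UTF-8 TSV with '.' as the decimal separator.

#' Read an expression matrix and its sample design
#'
#' The expression file is a TSV whose first column (`id`) holds probe ids and
#' whose remaining column headers are sample ids; the design file is a TSV
#' with columns `sample_id` and `group`. Every sample column must appear in
#' the design.
#'
#' @param path path to the expression TSV.
#' @param design_path path to the design TSV.
#' @return A list with elements `matrix` (an [expression_matrix()]) and
#'   `design` (a [group_design()]), orders preserved from the files.
#' @export
read_expression_table <- function(path, design_path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2)
    stop("expression table needs an id column and at least one sample")
  probe <- as.character(tab[[1]])
  values <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(values))
    stop("non-numeric intensity values in ", path)
  storage.mode(values) <- "double"
  rownames(values) <- probe
  des <- utils::read.delim(design_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(des)))
    stop("design file must have columns 'sample_id' and 'group'")
  missing <- setdiff(colnames(values), des$sample_id)
  if (length(missing))
    stop("sample(s) in expression table absent from design: ",
         paste(missing, collapse = ", "))
  design <- group_design(des$sample_id, des$group)
  list(matrix = expression_matrix(values), design = design)
}

#' Write an expression matrix (and optionally its design) as TSV
#'
#' @param x an [expression_matrix()].
#' @param path output path for the expression TSV.
#' @param design optional [group_design()] to write alongside.
#' @param design_path output path for the design TSV (required when
#'   `design` is given).
#' @return Invisibly, `path`.
#' @export
write_expression_table <- function(x, path, design = NULL,
                                   design_path = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  tab <- data.frame(id = probe_ids(x), x$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(design)) {
    if (is.null(design_path))
      stop("'design_path' required when writing a design")
    utils::write.table(
      data.frame(sample_id = design$sample_id,
                 group = as.character(design$group)),
      design_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "lungmir")
  if (p == "") stop("packaged fixture not found: ", file)
  p
}

#' Published fold changes of the 29 differentially expressed miRNAs
#'
#' Loads the packaged transcription of the published whole-lung
#' differential-expression table: 29 miRNAs by 5 treatment-group contrasts,
#' signed fold changes exactly as printed (two decimals), contrasts in
#' printed order (see [aad_contrasts()]).
#'
#' @return A [fold_change_table()] with 29 rows and 5 contrasts.
#' @export
load_table2_fixture <- function() {
  tab <- utils::read.delim(fixture_path("table2_foldchanges.tsv"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  fc <- as.matrix(tab[, -1])
  rownames(fc) <- tab$mirna_id
  fold_change_table(fc, lapply(colnames(fc), parse_contrast))
}

#' Published multi-miRNA target genes (multiplicity >= 6)
#'
#' Loads the packaged transcription of the published candidate-gene table:
#' the 44 genes predicted to carry binding sites for 6 or more of the 29
#' differentially expressed miRNAs, with the number of targeting miRNAs
#' split into up- and downregulated contributors.
#'
#' @return A `gene_multiplicity` data.frame with columns `gene_id`,
#'   `description`, `n_total`, `n_up`, `n_down`, `diff`, in printed order.
#' @export
load_table3_fixture <- function() {
  tab <- utils::read.delim(fixture_path("table3_multiplicity.tsv"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(all(tab$n_up + tab$n_down == tab$n_total),
            all(tab$n_up - tab$n_down == tab$diff))
  class(tab) <- c("gene_multiplicity", "data.frame")
  tab
}

#' Read a miRNA-to-gene interaction table
#'
#' Accepts a TSV with columns `mirna_id`, `gene_id` and optionally `score`
#' (e.g. the number of agreeing prediction algorithms). Duplicate
#' (miRNA, gene) rows are collapsed, keeping the maximum score.
#'
#' @param path path to the interaction TSV.
#' @return An `interaction_table` data.frame with columns `mirna_id`,
#'   `gene_id` and (if present in the file) `score`; no duplicate pairs.
#' @export
read_interactions <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("mirna_id", "gene_id")
  if (!all(need %in% names(tab)))
    stop("interaction table must have columns 'mirna_id' and 'gene_id'")
  interaction_table(tab$mirna_id, tab$gene_id,
                    score = if ("score" %in% names(tab)) tab$score)
}

#' Construct a deduplicated miRNA-to-gene interaction table
#'
#' @param mirna_id,gene_id character vectors of equal length; one directed
#'   miRNA-targets-gene edge per element.
#' @param score optional numeric per-edge support; duplicates collapse to
#'   the maximum.
#' @return An `interaction_table` data.frame.
#' @export
interaction_table <- function(mirna_id, gene_id, score = NULL) {
  mirna_id <- as.character(mirna_id)
  gene_id <- as.character(gene_id)
  if (length(mirna_id) != length(gene_id))
    stop("'mirna_id' and 'gene_id' must have equal length")
  if (length(mirna_id) && (any(!nzchar(mirna_id)) || any(!nzchar(gene_id))))
    stop("empty identifiers are not allowed")
  tab <- data.frame(mirna_id = mirna_id, gene_id = gene_id,
                    stringsAsFactors = FALSE)
  if (!is.null(score)) tab$score <- as.numeric(score)
  if (nrow(tab)) {
    key <- paste(tab$mirna_id, tab$gene_id, sep = "\r")
    if (is.null(score)) {
      tab <- tab[!duplicated(key), , drop = FALSE]
    } else {
      ord <- order(key, -tab$score)
      tab <- tab[ord, , drop = FALSE]
      tab <- tab[!duplicated(key[ord]), , drop = FALSE]
      tab <- tab[order(match(paste(tab$mirna_id, tab$gene_id, sep = "\r"),
                             unique(key))), , drop = FALSE]
    }
    rownames(tab) <- NULL
  }
  class(tab) <- c("interaction_table", "data.frame")
  tab
}

#' Write an interaction table as TSV
#' @param x an `interaction_table`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_interactions <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a qPCR Ct table
#'
#' TSV with rows = samples (first column `sample_id`) and columns = assays;
#' `reference_assay` names the housekeeping assay column (e.g. sno202 for
#' miRNA, HPRT for mRNA).
#'
#' @param path path to the Ct TSV.
#' @param reference_assay name of the housekeeping assay column.
#' @return A [ct_table()].
#' @export
read_ct_table <- function(path, reference_assay) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "sample_id")
    stop("Ct table must have 'sample_id' as its first column")
  ct <- as.matrix(tab[, -1, drop = FALSE])
  rownames(ct) <- tab$sample_id
  ct_table(ct, reference_assay)
}

#' Write a Ct table as TSV
#' @param x a [ct_table()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_ct_table <- function(x, path) {
  tab <- data.frame(sample_id = rownames(x$ct), x$ct,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
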