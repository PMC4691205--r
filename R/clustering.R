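# Hierarchical clustering of samples / miRNAs / group centroids on the
# differentially expressed set, and the row-standardized heatmap matrix.

#' Row-standardize an expression matrix for heatmap display
#'
#' Each row (miRNA) is centred and scaled to unit variance, using the
#' population (1/n) standard deviation as is conventional for heatmap
#' display scaling. Rows with zero variance cannot be standardized: they
#' are filled with zeros and flagged.
#'
#' @param values numeric matrix (typically normalized log2 intensities of
#'   the DE miRNAs) with at least 2 columns.
#' @return A `heatmap_matrix`: list with `values` (standardized matrix) and
#'   `constant_rows` (named logical).
#' @export
zscore_rows <- function(values) {
  if (inherits(values, "expression_matrix")) values <- values$values
  stopifnot(is.matrix(values), ncol(values) >= 2)
  mu <- rowMeans(values)
  sd <- sqrt(rowMeans((values - mu)^2))
  constant <- sd == 0
  z <- (values - mu) / ifelse(constant, 1, sd)
  z[constant, ] <- 0
  structure(list(values = z,
                 constant_rows = stats::setNames(constant,
                                                 rownames(values))),
            class = "heatmap_matrix")
}

#' Hierarchical clustering with deterministic ordering
#'
#' Agglomerative clustering of labeled row vectors under
#' 1 - Pearson-correlation or Euclidean distance with average or complete
#' linkage (the conventional expression-heatmap defaults). Rows are sorted
#' by label before clustering so that ties are broken lexicographically and
#' the result does not depend on input order.
#'
#' @param vectors numeric matrix, one labeled row per item (>= 2 rows).
#' @param distance `"correlation"` (1 - Pearson r) or `"euclidean"`.
#' @param linkage `"average"` or `"complete"`.
#' @return An object of classes `linkage_tree` and `hclust`.
#' @export
hierarchical_cluster <- function(vectors,
                                 distance = c("correlation", "euclidean"),
                                 linkage = c("average", "complete")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  stopifnot(is.matrix(vectors))
  if (nrow(vectors) < 2)
    stop("need at least 2 vectors to cluster")
  if (is.null(rownames(vectors)))
    stop("'vectors' must carry row labels")
  vectors <- vectors[order(rownames(vectors)), , drop = FALSE]
  d <- if (distance == "correlation") {
    stats::as.dist(1 - stats::cor(t(vectors)))
  } else {
    stats::dist(vectors)
  }
  tree <- stats::hclust(d, method = linkage)
  class(tree) <- c("linkage_tree", "hclust")
  tree
}

#' Rank group pairs by clustering similarity
#'
#' Reads the cophenetic (merge) height of every leaf pair off a linkage
#' tree over group-centroid profiles and sorts pairs by that height,
#' ascending: the first row names the two most similar groups. Equal
#' heights are ordered lexicographically by label pair.
#'
#' @param tree a `linkage_tree`/`hclust` over group centroids.
#' @return A data.frame with columns `group1`, `group2`, `merge_height`,
#'   sorted by `merge_height` then labels.
#' @export
group_similarity_order <- function(tree) {
  stopifnot(inherits(tree, "hclust"))
  coph <- as.matrix(stats::cophenetic(tree))
  labs <- sort(rownames(coph))
  pairs <- utils::combn(labs, 2)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    merge_height = coph[cbind(pairs[1, ], pairs[2, ])],
                    stringsAsFactors = FALSE)
  out <- out[order(out$merge_height, out$group1, out$group2), ]
  rownames(out) <- NULL
  out
}

#' Per-group centroid profiles (log2 means)
#'
#' @param matrix a normalized [expression_matrix()] (positive values).
#' @param design a [group_design()].
#' @return Matrix with one row per group, one column per probe.
#' @export
group_centroids <- function(matrix, design) {
  stopifnot(inherits(matrix, "expression_matrix"))
  t(group_log2_means(matrix$values, design))
}

#' Export a linkage tree in Newick format
#' @param tree a `linkage_tree`/`hclust`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' Export a heatmap matrix with leaf orders as TSV
#'
#' Rows and columns are reordered by the supplied trees' leaf orders (when
#' given) so the written table matches the rendered dendrogram layout.
#'
#' @param hm a `heatmap_matrix` from [zscore_rows()].
#' @param path output path.
#' @param row_tree,col_tree optional `linkage_tree`s over rows / columns.
#' @return Invisibly, `path`.
#' @export
write_heatmap_matrix <- function(hm, path, row_tree = NULL,
                                 col_tree = NULL) {
  v <- hm$values
  if (!is.null(row_tree)) v <- v[row_tree$labels[row_tree$order], ,
                                 drop = FALSE]
  if (!is.null(col_tree)) v <- v[, col_tree$labels[col_tree$order],
                                 drop = FALSE]
  tab <- data.frame(id = rownames(v), v, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
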