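# Independent oracles used to cross-check the package's implementations.
# These deliberately use different formulations than the package code.

# Two-sided Mann-Whitney p by brute-force enumeration over all splits of
# the pooled VALUES, with the U statistic computed from pairwise
# comparisons (not rank sums).
oracle_mw_p <- function(xs, ys) {
  u_stat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  pooled <- c(xs, ys)
  n1 <- length(xs)
  mu <- n1 * length(ys) / 2
  obs <- abs(u_stat(xs, ys) - mu)
  splits <- combn(length(pooled), n1)
  devs <- apply(splits, 2, function(ix)
    abs(u_stat(pooled[ix], pooled[-ix]) - mu))
  mean(devs >= obs - 1e-9)
}

# Per-gene multiplicity by explicit set intersection, gene by gene.
oracle_multiplicity <- function(interactions, directions) {
  genes <- sort(unique(interactions$gene_id))
  rows <- lapply(genes, function(g) {
    mirnas <- unique(interactions$mirna_id[interactions$gene_id == g])
    de_hit <- intersect(mirnas, names(directions))
    if (!length(de_hit)) return(NULL)
    n_up <- sum(directions[de_hit] == "up")
    n_down <- length(de_hit) - n_up
    data.frame(gene_id = g, n_total = length(de_hit), n_up = n_up,
               n_down = n_down, diff = n_up - n_down,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), n_total = integer(0),
                      n_up = integer(0), n_down = integer(0),
                      diff = integer(0), stringsAsFactors = FALSE)
  out
}

# Rand index between two partitions given as label vectors.
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}

# Small deterministic expression matrix for IO / normalization tests.
toy_matrix <- function() {
  v <- matrix(c(1, 2, 4, 8, 16, 32), nrow = 3,
              dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  expression_matrix(v)
}
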