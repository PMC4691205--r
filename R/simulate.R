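# Seeded generators with planted ground truth: expression matrices with
# planted fold changes, bipartite miRNA-gene networks with planted hub
# genes, and qPCR Ct tables. Every generator takes an explicit seed and
# restores the caller's RNG state.

#' Specification of a synthetic expression experiment
#'
#' Emulates the study design: four treatment groups with n replicates each,
#' log-normal intensities, a subset of arrayed probes actually expressed in
#' lung, and differential effects planted in a single (allergic) group.
#'
#' @param n_mirnas number of arrayed probes (default 611).
#' @param n_expressed number of probes expressed above the detection floor
#'   (default 228).
#' @param n_planted_de number of expressed probes carrying a planted fold
#'   change (default 29).
#' @param planted_fc signed fold changes for the planted probes
#'   (|fc| >= 1); by default magnitudes are drawn uniformly in \[2, 6\]
#'   (the observed effect range) with upregulation three times as likely as
#'   downregulation, mirroring the predominance of increased miRNAs.
#' @param n_per_group replicates per group (default 6 animals/group).
#' @param groups ordered group labels (default the four study groups).
#' @param de_group group receiving the planted effects (default "OVA/OVA").
#' @param log2_noise_sd replicate noise SD on the log2 scale (default 0.5;
#'   the study reports no replicate variance, this is a stand-in).
#' @param baseline_log2_mean,baseline_log2_sd distribution of expressed
#'   probes' baseline log2 intensity (defaults 7 and 1).
#' @param detection_floor intensity at/below which non-expressed probes are
#'   emitted (default 4).
#' @param seed integer seed (required).
#' @return An `expression_sim_spec` list.
#' @export
expression_sim_spec <- function(n_mirnas = 611, n_expressed = 228,
                                n_planted_de = 29, planted_fc = NULL,
                                n_per_group = 6, groups = AAD_GROUPS,
                                de_group = "OVA/OVA",
                                log2_noise_sd = 0.5,
                                baseline_log2_mean = 7,
                                baseline_log2_sd = 1,
                                detection_floor = 4, seed) {
  stopifnot(n_mirnas >= 1, n_expressed <= n_mirnas, n_expressed >= 0,
            n_planted_de <= n_expressed, n_planted_de >= 0,
            n_per_group >= 1, length(groups) >= 2,
            de_group %in% groups,
            log2_noise_sd > 0, baseline_log2_sd >= 0, detection_floor >= 0)
  if (!is.null(planted_fc)) {
    if (length(planted_fc) != n_planted_de)
      stop("'planted_fc' must have length n_planted_de")
    if (any(abs(planted_fc) < 1))
      stop("planted fold changes must satisfy |fc| >= 1")
  }
  structure(list(n_mirnas = n_mirnas, n_expressed = n_expressed,
                 n_planted_de = n_planted_de, planted_fc = planted_fc,
                 n_per_group = n_per_group, groups = groups,
                 de_group = de_group, log2_noise_sd = log2_noise_sd,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 detection_floor = detection_floor, seed = seed),
            class = "expression_sim_spec")
}

#' Simulate a miRNA expression experiment with planted effects
#'
#' Intensities are `2^(baseline_i + effect_{i,g} + eps)` with
#' `eps ~ N(0, log2_noise_sd)`; a planted probe's effect is
#' `sign(fc) * log2|fc|` in `de_group` and zero elsewhere. Non-expressed
#' probes are emitted at or below the detection floor (dropouts are
#' modelled as floor-level signal, not missing values). Same seed, same
#' output, bit for bit.
#'
#' @param spec an [expression_sim_spec()].
#' @return List with `matrix` (an [expression_matrix()]), `design`
#'   (a [group_design()]) and `truth` (planted DE probes with true signed
#'   fc, expressed probe ids, the per-group log2 mean surface and the
#'   affected group).
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "expression_sim_spec"))
  with_seed(spec$seed, {
    probes <- sprintf("mir-%04d", seq_len(spec$n_mirnas))
    n_samp <- spec$n_per_group * length(spec$groups)
    samples <- sprintf("s%02d", seq_len(n_samp))
    design <- group_design(samples,
                           rep(spec$groups, each = spec$n_per_group),
                           groups = spec$groups)
    expressed <- sort(sample.int(spec$n_mirnas, spec$n_expressed))
    planted <- sort(sample(expressed, spec$n_planted_de))
    fc <- spec$planted_fc
    if (is.null(fc) && spec$n_planted_de > 0) {
      mag <- stats::runif(spec$n_planted_de, 2, 6)
      sgn <- ifelse(stats::runif(spec$n_planted_de) < 0.75, 1, -1)
      fc <- sgn * mag
    }
    baseline <- rep(NA_real_, spec$n_mirnas)
    baseline[expressed] <- stats::rnorm(spec$n_expressed,
                                        spec$baseline_log2_mean,
                                        spec$baseline_log2_sd)
    # per-probe per-group log2 mean surface (expressed probes only)
    mu <- matrix(baseline, spec$n_mirnas, length(spec$groups))
    colnames(mu) <- spec$groups; rownames(mu) <- probes
    if (spec$n_planted_de > 0)
      mu[planted, spec$de_group] <- mu[planted, spec$de_group] +
        sign(fc) * log2(abs(fc))
    values <- matrix(0, spec$n_mirnas, n_samp,
                     dimnames = list(probes, samples))
    grp_of <- as.character(design$group)
    eps <- matrix(stats::rnorm(spec$n_mirnas * n_samp, 0,
                               spec$log2_noise_sd),
                  spec$n_mirnas, n_samp)
    for (j in seq_len(n_samp))
      values[expressed, j] <- 2^(mu[expressed, grp_of[j]] +
                                   eps[expressed, j])
    not_exp <- setdiff(seq_len(spec$n_mirnas), expressed)
    if (length(not_exp) && spec$detection_floor > 0) {
      # floor-level background, always at or below the floor
      values[not_exp, ] <- spec$detection_floor *
        2^(-abs(eps[not_exp, , drop = FALSE]))
    }
    truth <- list(
      planted_de = data.frame(
        mirna_id = probes[planted],
        fc = if (spec$n_planted_de > 0) fc else numeric(0),
        stringsAsFactors = FALSE),
      expressed_ids = probes[expressed],
      group_log2_means = mu[expressed, , drop = FALSE],
      de_group = spec$de_group)
    list(matrix = expression_matrix(values), design = design, truth = truth)
  })
}

#' Specification of a synthetic miRNA-gene interaction network
#'
#' Bipartite networks with planted "hub" genes wired to many
#' differentially expressed miRNAs (the structure the multiplicity filter
#' is meant to find) over a Bernoulli background.
#'
#' @param n_mirnas,n_genes universe sizes.
#' @param n_hubs number of planted hub genes (<= n_genes).
#' @param hub_degree_range integer interval of hub degrees (default
#'   c(6, 12), the observed candidate multiplicity range); degrees are
#'   drawn per hub and wired exclusively to DE miRNAs.
#' @param background_edge_prob probability of each background miRNA-gene
#'   edge (default 0.02).
#' @param de_set character vector of DE miRNA ids, or a named character
#'   vector of directions ("up"/"down") whose names are the miRNA ids; by
#'   default the first `min(29, n_mirnas)` miRNAs, 22 up and 7 down.
#' @param mirna_ids,gene_ids optional identifier vectors.
#' @param seed integer seed (required).
#' @return An `interaction_sim_spec` list.
#' @export
interaction_sim_spec <- function(n_mirnas = 29, n_genes = 400,
                                 n_hubs = 44, hub_degree_range = c(6, 12),
                                 background_edge_prob = 0.02,
                                 de_set = NULL, mirna_ids = NULL,
                                 gene_ids = NULL, seed) {
  stopifnot(n_mirnas >= 1, n_genes >= 1, n_hubs >= 0, n_hubs <= n_genes,
            length(hub_degree_range) == 2,
            hub_degree_range[1] >= 1, hub_degree_range[2] <= n_mirnas,
            hub_degree_range[1] <= hub_degree_range[2],
            background_edge_prob >= 0, background_edge_prob <= 1)
  if (is.null(mirna_ids)) mirna_ids <- sprintf("mir-%04d", seq_len(n_mirnas))
  if (is.null(gene_ids)) gene_ids <- sprintf("gene-%04d", seq_len(n_genes))
  stopifnot(length(mirna_ids) == n_mirnas, length(gene_ids) == n_genes,
            !anyDuplicated(mirna_ids), !anyDuplicated(gene_ids))
  if (is.null(de_set)) {
    k <- min(29L, n_mirnas)
    de_set <- stats::setNames(rep(c("up", "down"),
                                  c(ceiling(k * 22 / 29),
                                    k - ceiling(k * 22 / 29))),
                              mirna_ids[seq_len(k)])
  }
  if (is.null(names(de_set))) {
    de_set <- stats::setNames(rep("up", length(de_set)), de_set)
  }
  if (!all(names(de_set) %in% mirna_ids))
    stop("de_set contains miRNAs outside the universe")
  if (!all(de_set %in% c("up", "down")))
    stop("de_set directions must be 'up' or 'down'")
  if (n_hubs > 0 && hub_degree_range[2] > length(de_set))
    stop("hub degrees cannot exceed the DE set size")
  structure(list(n_mirnas = n_mirnas, n_genes = n_genes, n_hubs = n_hubs,
                 hub_degree_range = as.integer(hub_degree_range),
                 background_edge_prob = background_edge_prob,
                 de_set = de_set, mirna_ids = mirna_ids,
                 gene_ids = gene_ids, seed = seed),
            class = "interaction_sim_spec")
}

#' Simulate a bipartite miRNA-gene interaction network
#'
#' Hub genes receive a degree drawn uniformly from `hub_degree_range`,
#' wired to distinct miRNAs sampled from the DE set; every other
#' (miRNA, gene) pair carries an independent Bernoulli background edge.
#' Duplicate edges are impossible by construction.
#'
#' @param spec an [interaction_sim_spec()].
#' @return List with `interactions` (an [interaction_table()]) and `truth`
#'   (hub gene ids with their planted degrees, and the DE set).
#' @export
simulate_interactions <- function(spec) {
  stopifnot(inherits(spec, "interaction_sim_spec"))
  with_seed(spec$seed, {
    hubs <- if (spec$n_hubs > 0)
      sort(sample(spec$gene_ids, spec$n_hubs)) else character(0)
    de_mirnas <- names(spec$de_set)
    edges_m <- character(0); edges_g <- character(0)
    deg <- integer(0)
    for (h in hubs) {
      d <- if (spec$hub_degree_range[1] == spec$hub_degree_range[2])
        spec$hub_degree_range[1]
      else sample(spec$hub_degree_range[1]:spec$hub_degree_range[2], 1)
      targets <- sample(de_mirnas, d)
      edges_m <- c(edges_m, targets)
      edges_g <- c(edges_g, rep(h, d))
      deg <- c(deg, d)
    }
    if (spec$background_edge_prob > 0) {
      keep <- which(stats::runif(spec$n_mirnas * spec$n_genes) <
                      spec$background_edge_prob)
      if (length(keep)) {
        mi <- ((keep - 1) %% spec$n_mirnas) + 1
        gi <- ((keep - 1) %/% spec$n_mirnas) + 1
        edges_m <- c(edges_m, spec$mirna_ids[mi])
        edges_g <- c(edges_g, spec$gene_ids[gi])
      }
    }
    tab <- interaction_table(edges_m, edges_g)
    truth <- list(hub_genes = data.frame(gene_id = hubs, degree = deg,
                                         stringsAsFactors = FALSE),
                  de_set = spec$de_set)
    list(interactions = tab, truth = truth)
  })
}

#' Simulate a qPCR Ct table
#'
#' Each sample gets a housekeeping (reference) Ct near 20 cycles; each
#' target assay's Ct is `Ct_ref - log2(true_rel_expression) + noise`, so
#' the planted relative expression is exactly `2^-dCt` in the noiseless
#' limit.
#'
#' @param n_samples number of samples.
#' @param true_rel_expression positive relative expression per target
#'   assay (named vector; unnamed vectors get assay1, assay2, ...).
#' @param ct_noise_sd SD of the cycle-threshold noise added to target
#'   assays (0 for a deterministic table).
#' @param seed integer seed.
#' @param reference_assay name of the housekeeping column (default
#'   "sno202", the small nucleolar reference RNA used for miRNA assays).
#' @param sample_ids optional sample identifiers.
#' @return A [ct_table()] containing the reference column and one column
#'   per target assay.
#' @export
simulate_ct <- function(n_samples, true_rel_expression, ct_noise_sd = 0,
                        seed, reference_assay = "sno202",
                        sample_ids = NULL) {
  stopifnot(n_samples >= 1, ct_noise_sd >= 0)
  if (any(true_rel_expression <= 0))
    stop("relative expression must be positive")
  if (is.null(names(true_rel_expression)))
    names(true_rel_expression) <-
      paste0("assay", seq_along(true_rel_expression))
  if (is.null(sample_ids)) sample_ids <- sprintf("s%02d", seq_len(n_samples))
  with_seed(seed, {
    ct_ref <- stats::rnorm(n_samples, 20, 0.5)
    ct <- sapply(true_rel_expression, function(rel)
      ct_ref - log2(rel) +
        if (ct_noise_sd > 0) stats::rnorm(n_samples, 0, ct_noise_sd) else 0)
    ct <- cbind(ct_ref, matrix(ct, nrow = n_samples))
    dimnames(ct) <- list(sample_ids,
                         c(reference_assay, names(true_rel_expression)))
    ct_table(ct, reference_assay)
  })
}
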