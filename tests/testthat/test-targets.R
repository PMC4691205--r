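random_network <- function(n_mirnas, n_genes, p = 0.3) {
  mirnas <- sprintf("m%02d", seq_len(n_mirnas))
  genes <- sprintf("g%02d", seq_len(n_genes))
  hit <- which(runif(n_mirnas * n_genes) < p)
  interaction_table(mirnas[((hit - 1) %% n_mirnas) + 1],
                    genes[((hit - 1) %/% n_mirnas) + 1])
}

test_that("multiplicity counting handles the base cases", {
  tab <- interaction_table("m1", "g1")
  s <- multiplicity_scores(tab, c(m1 = "up"))
  expect_equal(as.data.frame(s),
               data.frame(gene_id = "g1", n_total = 1L, n_up = 1L,
                          n_down = 0L, diff = 1L,
                          stringsAsFactors = FALSE))
  # edges from miRNAs outside the DE set are ignored
  tab <- interaction_table(c("m1", "m2"), c("g1", "g1"))
  s <- multiplicity_scores(tab, c(m1 = "down"))
  expect_equal(s$n_total, 1)
  expect_equal(s$n_down, 1)
})

test_that("multiplicity matches the brute-force oracle on random networks", {
  set.seed(13)
  for (i in 1:25) {
    net <- random_network(sample(3:15, 1), sample(5:30, 1))
    mirnas <- unique(net$mirna_id)
    k <- sample(seq_along(mirnas), 1)
    de <- setNames(sample(c("up", "down"), k, replace = TRUE),
                   sample(mirnas, k))
    got <- multiplicity_scores(net, de)
    want <- oracle_multiplicity(net, de)
    expect_equal(as.data.frame(got), want)
    expect_true(all(got$n_up + got$n_down == got$n_total))
    expect_true(all(got$n_up - got$n_down == got$diff))
  }
})

test_that("direction comes from the stated contrast and must exist", {
  t2 <- load_table2_fixture()
  cls <- classify_mirnas(t2)
  net <- interaction_table(c("mmu-miR-155-5p", "mmu-miR-193b-3p"),
                           c("geneA", "geneA"))
  s <- multiplicity_scores(net, cls)  # default OVA/OVA vs PBS/PBS
  expect_equal(s$n_up, 1)    # miR-155-5p up (4.04)
  expect_equal(s$n_down, 1)  # miR-193b-3p down (-2.29)
  # a DE miRNA with fc exactly 1 has no direction in that contrast
  fc <- t2$fc
  fc["mmu-miR-155-5p", "OVA/OVA vs PBS/PBS"] <- 1
  cls1 <- classify_mirnas(fold_change_table(fc, t2$contrasts))
  expect_error(multiplicity_scores(net, cls1), "mmu-miR-155-5p")
})

test_that("candidate tables are thresholded, ordered and nested", {
  t3 <- load_table3_fixture()
  cand6 <- candidate_table(t3, 6)
  expect_equal(nrow(cand6), 44)
  expect_equal(cand6$n_total[1], 12)
  expect_true(all(diff(cand6$n_total) <= 0))
  expect_equal(nrow(candidate_table(t3, 13)), 0)
  expect_equal(nrow(candidate_table(t3, 1)), nrow(t3))
  for (k in 6:12) {
    expect_true(all(candidate_table(t3, k + 1)$gene_id %in%
                      candidate_table(t3, k)$gene_id))
  }
})

test_that("cumulative multiplicity distribution is a survival curve", {
  s <- data.frame(gene_id = c("a", "b", "c"), n_total = c(1, 2, 2),
                  n_up = c(1, 2, 2), n_down = 0, diff = c(1, 2, 2))
  d <- multiplicity_distribution(s)
  expect_equal(d$fraction[d$k == 1], 1)
  expect_equal(d$fraction[d$k == 2], 2 / 3)
  flat <- data.frame(gene_id = "a", n_total = 1, n_up = 1, n_down = 0,
                     diff = 1)
  expect_equal(multiplicity_distribution(flat)$fraction, 1)
  set.seed(3)
  net <- random_network(10, 25)
  de <- setNames(rep("up", 10), unique(net$mirna_id))
  d <- multiplicity_distribution(multiplicity_scores(net, de))
  expect_true(all(diff(d$fraction) <= 0))
  expect_error(multiplicity_distribution(s[0, ]), "no scored")
})

test_that("candidate summaries agree with direct column summation", {
  t3 <- load_table3_fixture()
  sm <- summarize_candidates(candidate_table(t3, 6))
  expect_equal(sm$mean_total, sum(t3$n_total) / 44, tolerance = 1e-12)
  expect_equal(sm$mean_up, sum(t3$n_up) / 44, tolerance = 1e-12)
  expect_equal(sm$mean_down, sum(t3$n_down) / 44, tolerance = 1e-12)
  expect_equal(sm$mean_diff, sum(t3$diff) / 44, tolerance = 1e-12)
  one <- summarize_candidates(t3[1, ])
  expect_equal(one$mean_total, 12)
  expect_equal(one$rounded, c(12, 8, 4, 4))
  expect_error(summarize_candidates(t3[0, ]), "no candidate")
})

test_that("permutation enrichment behaves at its boundaries", {
  set.seed(19)
  net <- random_network(12, 30)
  all_m <- unique(net$mirna_id)
  # the whole universe: every null draw equals the observed statistic
  res <- multiplicity_enrichment_test(net, all_m, min_multiplicity = 2,
                                      n_perm = 99, seed = 2)
  expect_equal(res$p_value, 1)
  res <- multiplicity_enrichment_test(net, all_m[1:4],
                                      min_multiplicity = 1,
                                      n_perm = 9, seed = 2)
  expect_gte(res$p_value, 1 / 10)
  expect_error(multiplicity_enrichment_test(net, all_m, 2, n_perm = 0,
                                            seed = 1), "n_perm")
})

test_that("planted hub wiring is detected as enrichment", {
  spec <- interaction_sim_spec(n_mirnas = 30, n_genes = 120, n_hubs = 12,
                               hub_degree_range = c(6, 8),
                               background_edge_prob = 0.02,
                               de_set = sprintf("mir-%04d", 1:10),
                               seed = 23)
  sim <- simulate_interactions(spec)
  res <- multiplicity_enrichment_test(sim$interactions,
                                      names(sim$truth$de_set),
                                      min_multiplicity = 6,
                                      n_perm = 999, seed = 29)
  expect_lte(res$p_value, 0.01)
})

test_that("permutation p-values are uniform under an exchangeable null", {
  # fixed dense background network, no hubs; the "true" DE set is drawn
  # from the same distribution as the permuted sets, so p must be uniform
  # on (0, 1] up to permutation granularity; checked against the DKW band
  spec <- interaction_sim_spec(n_mirnas = 40, n_genes = 250, n_hubs = 0,
                               hub_degree_range = c(1, 1),
                               background_edge_prob = 0.25,
                               de_set = character(0), seed = 11)
  net <- simulate_interactions(spec)$interactions
  universe <- sprintf("mir-%04d", 1:40)
  set.seed(1100)
  ps <- vapply(1:200, function(i)
    multiplicity_enrichment_test(net, sample(universe, 10),
                                 min_multiplicity = 3, n_perm = 199,
                                 seed = 11000 + i)$p_value, numeric(1))
  expect_true(all(ps >= 1 / 200) && all(ps <= 1))
  grid <- seq(0.005, 1, by = 0.005)
  D <- max(abs(ecdf(ps)(grid) - grid))
  dkw <- sqrt(log(2 / 0.05) / (2 * 200))
  expect_lte(D, dkw)
})
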