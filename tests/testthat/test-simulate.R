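test_that("expression simulation is seed-reproducible and seed-sensitive", {
  spec <- expression_sim_spec(n_mirnas = 50, n_expressed = 30,
                              n_planted_de = 5, seed = 1)
  a <- simulate_expression(spec)
  b <- simulate_expression(spec)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$truth$planted_de, b$truth$planted_de)
  c <- simulate_expression(expression_sim_spec(n_mirnas = 50,
                                               n_expressed = 30,
                                               n_planted_de = 5, seed = 2))
  expect_false(identical(a$matrix$values, c$matrix$values))
  # generators must not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(simulate_expression(spec)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("simulation spec invariants are enforced", {
  expect_error(expression_sim_spec(n_mirnas = 10, n_expressed = 20,
                                   seed = 1))
  expect_error(expression_sim_spec(n_planted_de = 3,
                                   planted_fc = c(2, 3), seed = 1),
               "length")
  expect_error(expression_sim_spec(n_planted_de = 1, planted_fc = 0.5,
                                   n_mirnas = 10, n_expressed = 5,
                                   seed = 1), "fc")
})

test_that("planted group means converge to baseline + log2|fc|", {
  spec <- expression_sim_spec(n_mirnas = 20, n_expressed = 20,
                              n_planted_de = 5,
                              planted_fc = c(4, 4, -4, 6, 2),
                              n_per_group = 200, log2_noise_sd = 0.5,
                              seed = 31)
  sim <- simulate_expression(spec)
  planted <- sim$truth$planted_de
  se <- spec$log2_noise_sd / sqrt(spec$n_per_group)
  cols <- group_samples(sim$design, "OVA/OVA")
  for (i in seq_len(nrow(planted))) {
    emp <- mean(log2(sim$matrix$values[planted$mirna_id[i], cols]))
    expected <- sim$truth$group_log2_means[planted$mirna_id[i], "OVA/OVA"]
    expect_lt(abs(emp - expected), 3 * se)
  }
})

test_that("estimated fold changes recover planted values within 20%", {
  errs <- vapply(1:100, function(r) {
    spec <- expression_sim_spec(n_mirnas = 1, n_expressed = 1,
                                n_planted_de = 1, planted_fc = 4,
                                n_per_group = 6, log2_noise_sd = 0.5,
                                seed = 5000 + r)
    sim <- simulate_expression(spec)
    gm <- 2^tapply(log2(sim$matrix$values[1, ]), sim$design$group, mean)
    fc <- signed_fold_change(gm[["OVA/OVA"]], gm[["PBS/PBS"]])
    abs(fc - 4) / 4
  }, numeric(1))
  expect_lte(median(errs), 0.20)
})

test_that("interaction simulation plants exact hub structure", {
  spec <- interaction_sim_spec(n_mirnas = 10, n_genes = 20, n_hubs = 3,
                               hub_degree_range = c(6, 6),
                               background_edge_prob = 0,
                               de_set = sprintf("mir-%04d", 1:8),
                               seed = 7)
  expect_error(interaction_sim_spec(n_mirnas = 10, n_genes = 20,
                                    n_hubs = 3,
                                    hub_degree_range = c(6, 6),
                                    background_edge_prob = 0,
                                    de_set = sprintf("mir-%04d", 1:5),
                                    seed = 7),
               "DE set")
  sim <- simulate_interactions(spec)
  expect_identical(sim$interactions,
                   simulate_interactions(spec)$interactions)
  # background-free: edge count equals the sum of planted hub degrees
  expect_equal(nrow(sim$interactions), sum(sim$truth$hub_genes$degree))
  scores <- multiplicity_scores(sim$interactions, sim$truth$de_set)
  cand <- candidate_table(scores, 6)
  expect_setequal(cand$gene_id, sim$truth$hub_genes$gene_id)
})

test_that("Ct simulation reproduces planted relative expression exactly", {
  ct <- simulate_ct(4, c(a = 1), ct_noise_sd = 0, seed = 3)
  expect_equal(ct$ct[, "a"], ct$ct[, "sno202"])
  ct <- simulate_ct(4, c(a = 0.25), ct_noise_sd = 0, seed = 3)
  expect_equal(unname(ct$ct[, "a"] - ct$ct[, "sno202"]), rep(2, 4))
  expect_identical(simulate_ct(6, c(a = 2), 0.3, seed = 5)$ct,
                   simulate_ct(6, c(a = 2), 0.3, seed = 5)$ct)
  expect_error(simulate_ct(4, c(a = -1), 0, seed = 1), "positive")
})
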