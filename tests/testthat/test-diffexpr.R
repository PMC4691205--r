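test_that("percentile normalization aligns samples and is idempotent", {
  v <- matrix(c(1, 2, 4, 8, 4, 8, 16, 32), nrow = 4,
              dimnames = list(paste0("p", 1:4), c("s1", "s2")))
  m <- expression_matrix(v)
  norm <- percentile_normalize(m, 75)
  q75 <- apply(log2(norm$values), 2, quantile, 0.75)
  expect_equal(unname(diff(q75)), 0)
  # second sample is exactly 4x the first: it must shift by -1 on log2
  # (both meet at the median of the two percentiles), i.e. 2 log2 units
  # closer to sample 1
  shift <- log2(norm$values[1, ] / v[1, ])
  expect_equal(unname(shift[2] - shift[1]), -2)
  # within-sample order preserved
  expect_identical(order(norm$values[, 1]), order(v[, 1]))
  # idempotent
  expect_equal(percentile_normalize(norm, 75)$values, norm$values)

  single <- expression_matrix(v[, 1, drop = FALSE])
  expect_equal(percentile_normalize(single, 75)$values, v[, 1, drop = FALSE])

  zero <- expression_matrix(matrix(c(1, 1, 0, 0), 2,
                                   dimnames = list(c("p1", "p2"),
                                                   c("s1", "s2"))))
  expect_error(percentile_normalize(zero), "positive")
})

test_that("detection requires a within-group majority above the floor", {
  design <- group_design(paste0("s", 1:12),
                         rep(c("A", "B"), each = 6))
  v <- matrix(0, 3, 12, dimnames = list(c("silent", "groupB", "partial"),
                                        paste0("s", 1:12)))
  v["groupB", 7:12] <- 100          # above floor in every B replicate
  v["partial", 7:9] <- 100          # only half of B
  m <- expression_matrix(v)
  cfg <- analysis_config(detection_floor = 4, detection_fraction = 0.6)
  expect_identical(detection_call(m, design, cfg), "groupB")
})

test_that("signed fold change follows the negative-reciprocal convention", {
  expect_equal(signed_fold_change(4, 2), 2)
  expect_equal(signed_fold_change(2, 4), -2)
  expect_equal(signed_fold_change(pi, pi), 1)
  expect_error(signed_fold_change(0, 1), "positive")
  set.seed(11)
  a <- runif(200, 0.01, 100); b <- runif(200, 0.01, 100)
  fc_ab <- signed_fold_change(a, b)
  fc_ba <- signed_fold_change(b, a)
  expect_true(all(abs(fc_ab) >= 1))
  neq <- a != b
  expect_equal(fc_ab[neq], -fc_ba[neq])
})

test_that("exact Mann-Whitney matches its definition and symmetries", {
  expect_equal(mann_whitney_exact(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(mann_whitney_exact(1:3, 4:6), 0.1)
  expect_error(mann_whitney_exact(numeric(0), 1:3), "nonempty")
  set.seed(4)
  for (i in 1:20) {
    xs <- rnorm(sample(2:6, 1)); ys <- rnorm(sample(2:6, 1))
    p <- mann_whitney_exact(xs, ys)
    expect_equal(p, mann_whitney_exact(ys, xs))
    # invariant under strictly monotone transforms of the pooled data
    expect_equal(p, mann_whitney_exact(exp(xs), exp(ys)))
    expect_gt(p, 0); expect_lte(p, 1)
  }
})

test_that("large-sample Mann-Whitney agrees with the classical normal
           approximation with tie correction", {
  set.seed(9)
  for (i in 1:10) {
    xs <- round(rnorm(15), 1)  # rounding induces ties
    ys <- round(rnorm(12, 0.5), 1)
    expect_equal(mann_whitney_exact(xs, ys),
                 wilcox.test(xs, ys, exact = FALSE,
                             correct = FALSE)$p.value,
                 tolerance = 1e-10)
  }
})

test_that("BH adjustment applies the step-up rule", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.2, 0.04)
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("run_contrasts recovers an exact noiseless fold change", {
  design <- group_design(paste0("s", 1:12), rep(c("A", "B"), each = 6))
  v <- matrix(rep(c(10, 40), each = 6), 1,
              dimnames = list("probe", paste0("s", 1:12)))
  # tiny jitter so replicate ranks are well-defined but fc is ~exact
  v <- v * rep(2^seq(-1e-9, 1e-9, length.out = 6), 2)
  de <- run_contrasts(expression_matrix(v), design,
                      list(contrast("B", "A")), analysis_config())
  expect_equal(de$fc, 4, tolerance = 1e-6)
  expect_equal(de$p_raw, 2 / 924)
  expect_identical(de$call, "up")
  expect_error(run_contrasts(expression_matrix(v), design,
                             list(contrast("C", "A"))), "C")
})

test_that("classification reproduces the printed patterns", {
  t2 <- load_table2_fixture()
  cls <- classify_mirnas(t2)
  expect_identical(unname(cls$calls["mmu-miR-155-5p",
                                    "OVA/OVA vs PBS/PBS"]), "up")
  expect_true(cls$steroid_sensitive["mmu-miR-155-5p"])
  expect_false(cls$steroid_sensitive["mmu-miR-223-3p"])
  # threshold is inclusive: printed 2.01 / 2.02 entries count as altered
  expect_identical(unname(cls$calls["mmu-miR-449a-5p",
                                    "OVA/OVA vs PBS/PBS"]), "up")
  # Venn regions partition the altered set
  expect_true(all(!is.na(cls$venn_region[cls$de_any])))
  expect_true(all(is.na(cls$venn_region[!cls$de_any])))

  flat <- fold_change_table(
    matrix(1, 3, 5, dimnames = list(paste0("m", 1:3),
                                    colnames(t2$fc))),
    t2$contrasts)
  cls0 <- classify_mirnas(flat)
  expect_false(any(cls0$de_any))
  s <- summarize_calls(cls0, contrast("OVA/OVA", "PBS/PBS"))
  expect_true(all(unlist(s) == 0))

  expect_error(classify_mirnas(fold_change_table(
    matrix(2, 2, 1, dimnames = list(c("a", "b"), NULL)),
    list(contrast("X", "Y")))), "missing")
})

test_that("summary counts are invariant to row permutation", {
  t2 <- load_table2_fixture()
  perm <- sample(nrow(t2$fc))
  shuffled <- fold_change_table(t2$fc[perm, ], t2$contrasts)
  s1 <- summarize_calls(classify_mirnas(t2), contrast("OVA/OVA", "PBS/PBS"))
  s2 <- summarize_calls(classify_mirnas(shuffled),
                        contrast("OVA/OVA", "PBS/PBS"))
  expect_identical(s1, s2)
})
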