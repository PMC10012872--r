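# Differential expression: normalization, dispersion, the exact
# conditional NB test, BH adjustment and direction calls.

test_that("size factors are median-of-ratios against the geometric mean", {
  m <- cbind(A = c(10L, 20L, 30L, 40L), B = c(10L, 20L, 30L, 40L))
  expect_equal(unname(size_factors(m)), c(1, 1))
  # sample B doubled: factors (1/sqrt(2), sqrt(2)), hand-derived
  m2 <- cbind(A = c(10L, 20L, 30L, 40L), B = c(20L, 40L, 60L, 80L))
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
})

test_that("features containing a zero are excluded from the median", {
  # without exclusion the zero feature would drag sample A's median down
  m <- cbind(A = c(10L, 20L, 30L, 0L), B = c(10L, 20L, 30L, 1000L))
  expect_equal(unname(size_factors(m)), c(1, 1))
  expect_error(size_factors(cbind(A = c(0L, 5L), B = c(5L, 0L))),
               "all-positive")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(31)
  m <- matrix(rnbinom(200, mu = 300, size = 10), nrow = 50)
  colnames(m) <- paste0("s", 1:4)
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-10)
})

test_that("moment dispersion is zero at or below Poisson variance", {
  # constant counts
  m <- matrix(100, nrow = 1, ncol = 4)
  expect_equal(unname(estimate_dispersion(m, rep("day7", 4))), 0)
  # one condition of four samples, variance 83.3 < mean 100 -> raw alpha 0
  m2 <- matrix(c(90, 110, 95, 105), nrow = 1)
  expect_equal(unname(estimate_dispersion(m2, rep("day7", 4))), 0)
  expect_error(estimate_dispersion(m2[, 1:2, drop = FALSE],
                                   c("day7", "day42")), ">= 2 samples")
})

test_that("dispersion recovers the generative alpha on average", {
  cfg <- sim_config(n_mrna = 1000, n_lncrna = 1, n_circrna = 1, n_mirna = 1,
                    n_triples_planted = 0, dispersion = 0.05, seed = 14)
  cm <- simulate_counts(simulate_sequences(cfg)$truth, cfg)
  sf <- size_factors(cm$mrna)
  norm <- sweep(cm$mrna, 2, sf, "/")
  cond <- cm$design$condition[match(colnames(norm), cm$design$sample)]
  al <- estimate_dispersion(norm, cond)
  expect_lt(abs(mean(al) - 0.05), 0.02)
})

test_that("exact test matches the hand-enumerated conditional binomial", {
  # A=1, B=3, alpha=0: outcomes of Binomial(4, 1/2) with prob <= 4/16
  # are {0, 1, 3, 4}, total 10/16
  expect_equal(nb_exact_test(1, 3, 0), 0.625, tolerance = 1e-12)
  expect_equal(nb_exact_test(3, 1, 0), 0.625, tolerance = 1e-12)  # symmetry
  # equal sums, equal group sizes -> p = 1
  expect_equal(nb_exact_test(c(5, 5), c(5, 5), 0.1), 1)
  expect_warning(p0 <- nb_exact_test(0, 0, 0), "zero")
  expect_equal(p0, 1)
  expect_error(nb_exact_test(numeric(0), 3), "non-empty")
})

test_that("exact test is symmetric and valid for overdispersed counts", {
  set.seed(4)
  for (i in 1:20) {
    a <- rnbinom(2, mu = 50, size = 5); b <- rnbinom(2, mu = 50, size = 5)
    al <- runif(1, 0, 0.5)
    p1 <- nb_exact_test(a, b, al)
    expect_equal(p1, nb_exact_test(b, a, al), tolerance = 1e-12)
    expect_gte(p1, 0); expect_lte(p1, 1)
  }
})

test_that("BH adjustment follows the step-up rule and dominates raw p", {
  expect_equal(bh_adjust(c(0.002, 0.01, 0.03, 0.04)),
               c(0.008, 0.02, 0.04, 0.04), tolerance = 1e-12)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(2)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("direction calls honour the per-assay screening profiles", {
  rec <- data.frame(feature = c("a", "b", "c", "d"),
                    log2fc = c(4.5034, -4.0543, 0.30, 1.0),
                    p_raw = c(0.007635, 0.021183, 0.01, 0.2),
                    p_adj = c(0.03, 0.08, 0.04, 0.6))
  circ <- de_profile("circrna")
  out <- call_de(rec, circ$fc_cutoff, circ$p_cutoff)
  expect_equal(out$direction, c("up", "down", "up", "ns"))
  mir <- de_profile("mirna")
  out2 <- call_de(rec, mir$fc_cutoff, mir$p_cutoff)
  # 0.30 < log2(1.5) ~ 0.585 -> ns under the miRNA screen
  expect_equal(out2$direction, c("up", "down", "ns", "ns"))
  expect_error(call_de(rec, fc_cutoff = 0.5), ">= 1")
})

test_that("planted fold changes are recovered by the full DE analysis", {
  cfg <- sim_config(seed = 6)
  sim <- simulate_sequences(cfg)
  cm <- simulate_counts(sim$truth, cfg)
  de <- de_analysis(cm$mrna, cm$design, "mrna")
  truth <- sim$truth$true_log2fc[de$feature]
  planted <- which(truth != 0)
  expect_gt(length(planted), 0)
  # >= 90% of planted mRNAs called DE in the right direction
  hit <- de$direction[planted] == ifelse(truth[planted] > 0, "up", "down")
  expect_gte(mean(hit), 0.9)
  # fold-change estimates near the planted effect
  expect_lt(median(abs(de$log2fc[planted] - truth[planted])), 0.5)
  expect_true(all(de$p_adj >= de$p_raw))
})
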