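test_that("correlation suite: hand values, rank invariance, input guards", {
  ct <- correlation_suite(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(ct$pearson, 0.8)
  expect_equal(ct$spearman, 0.8)
  expect_equal(ct$n, 4L)

  same <- correlation_suite(c(1, 5, 9), c(1, 5, 9))
  expect_equal(c(same$pearson, same$pearson_log2, same$spearman), rep(1, 3))

  # monotone nonlinear map: Spearman 1, and unchanged by the log transform
  x <- c(1, 2, 3, 4, 5)
  y <- 2^x
  m <- correlation_suite(x, y)
  expect_equal(m$spearman, 1)
  expect_lt(m$pearson, 1)
  expect_equal(m$pearson_log2, cor(log2(x), x))

  expect_error(correlation_suite(c(1, 2), c(1, 2)), "at least 3")
  expect_error(correlation_suite(c(1, 2, 3), c(1, 2)), "length")
  expect_error(correlation_suite(c(1, -2, 0, 3), c(1, 2, 3, 4)),
               "2 non-positive")
  expect_error(correlation_suite(c(2, 2, 2), c(1, 2, 3)), "zero variance")
})

test_that("Spearman is invariant under strictly increasing transforms", {
  set.seed(8)
  for (i in 1:10) {
    x <- exp(rnorm(50)); y <- exp(rnorm(50))
    base <- correlation_suite(x, y)$spearman
    expect_equal(correlation_suite(x^3, y)$spearman, base)
    expect_equal(correlation_suite(x, 7 * y)$spearman, base)
    expect_equal(correlation_suite(2^x, exp(y))$spearman, base)
  }
})

test_that("Fisher z comparison of two correlations", {
  eq <- compare_correlations_fisher_z(0.5, 30, 0.5, 50)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_value, 1)

  ex <- compare_correlations_fisher_z(0.56, 76, 0.48, 76)
  expect_equal(ex$z, (atanh(0.56) - atanh(0.48)) / sqrt(2 / 73))
  expect_equal(ex$z, 0.6637, tolerance = 1e-3)
  expect_gt(ex$p_value, 0.05)   # not significant

  expect_error(compare_correlations_fisher_z(1, 10, 0.5, 10), "< 1")
  expect_error(compare_correlations_fisher_z(0.5, 3, 0.5, 10), "n > 3")
})

test_that("top-k lists sort by fold change with lexicographic tie-breaks", {
  tb <- fold_change_table(c("a", "b", "c"), c(5, 2, 9))
  expect_equal(top_k_list(tb, 2, "highest"), c("c", "a"))
  expect_equal(top_k_list(tb, 2, "lowest"), c("b", "a"))
  expect_error(top_k_list(tb, 4), "exceeds")

  # tie at the same fc: "p10" < "p2" lexicographically, so p10 first
  tie <- fold_change_table(c("p2", "p10", "p3"), c(5, 5, 1))
  expect_equal(top_k_list(tie, 2, "highest"), c("p10", "p2"))
})

test_that("overlap permutation test matches its exact hypergeometric oracle", {
  # p = 1 whenever the observed overlap is 0, for any configuration
  for (cfg in list(c(20, 5), c(100, 10), c(500, 50))) {
    res <- overlap_permutation_test(sprintf("a%d", 1:cfg[2]),
                                    sprintf("b%d", 1:cfg[2]),
                                    universe_size = cfg[1],
                                    n_trials = 500, seed = cfg[1])
    expect_equal(res$n_observed, 0L)
    expect_equal(res$p_value, 1)
  }

  # empirical tail within Monte-Carlo error of the closed form
  res <- overlap_permutation_test(as.character(1:5), as.character(6:10),
                                  universe_size = 20, n_trials = 1e4,
                                  seed = 99)
  for (n in 0:5) {
    p_exact <- overlap_exact_pvalue(5, n, 20)
    p_emp <- mean(res$trial_overlaps >= n)
    se <- sqrt(p_exact * (1 - p_exact) / res$n_trials)
    expect_lt(abs(p_emp - p_exact), 3 * se + 1e-9)
  }

  # identical lists, k << N: essentially no trial reaches full overlap
  full <- overlap_permutation_test(as.character(1:5), as.character(1:5),
                                   universe_size = 200, n_trials = 2000,
                                   seed = 1)
  expect_equal(full$n_observed, 5L)
  expect_equal(full$p_value, 0)
  expect_lt(overlap_exact_pvalue(5, 5, 200), 1e-9)

  # determinism and guards
  rep1 <- overlap_permutation_test(as.character(1:5), as.character(3:7), 50,
                                   n_trials = 200, seed = 7)
  rep2 <- overlap_permutation_test(as.character(1:5), as.character(3:7), 50,
                                   n_trials = 200, seed = 7)
  expect_identical(rep1$trial_overlaps, rep2$trial_overlaps)
  expect_error(overlap_permutation_test(c("a", "a"), c("b", "c"), 10),
               "duplicate")
  expect_error(overlap_permutation_test(as.character(1:5),
                                        as.character(1:5), 4), "universe")
})

test_that("exact overlap p-value: closed form, limits and monotonicity", {
  expect_equal(overlap_exact_pvalue(5, 0, 20), 1)
  expect_equal(overlap_exact_pvalue(5, 2, 20), 0.366099, tolerance = 1e-6)
  expect_equal(overlap_exact_pvalue(7, 3, 7), 1)   # k = N forces full overlap

  # cross-check against the hypergeometric tail over a grid
  for (N in c(30, 100)) {
    for (k in c(4, 9)) {
      for (n in 0:k) {
        expect_equal(overlap_exact_pvalue(k, n, N),
                     phyper(n - 1, k, N - k, k, lower.tail = FALSE),
                     tolerance = 1e-12)
      }
      p <- vapply(0:k, overlap_exact_pvalue, numeric(1), k = k,
                  universe_size = N)
      expect_true(all(diff(p) <= 1e-15))   # non-increasing in n
    }
  }
  expect_error(overlap_exact_pvalue(5, 6, 20), "n_observed")
  expect_error(overlap_exact_pvalue(21, 0, 20), "universe_size")
})

test_that("threshold concordance counts and percentages", {
  fa <- fold_change_table(c("p1", "p2", "p3", "p4"), c(6, 10, 2, 0.5))
  fb <- fold_change_table(c("p1", "p2", "p3", "p4"), c(7, 1, 9, 0.1))
  tc <- threshold_concordance(fa, fb, 5)
  expect_equal(tc$n_a_above, 2L)
  expect_equal(tc$n_both_above, 1L)
  expect_equal(tc$percent, 50.0)

  idt <- threshold_concordance(fa, fa, 5)
  expect_equal(idt$percent, 100.0)

  none <- threshold_concordance(fa, fb, 100)
  expect_equal(none$n_a_above, 0L)
  expect_true(is.na(none$percent))

  other <- fold_change_table("q9", 3)
  expect_error(threshold_concordance(fa, other, 5), "in common")
  expect_equal(percent_concordant(31, 225), 13.8)
})

test_that("reproducibility report enumerates unordered pairs symmetrically", {
  set.seed(5)
  ids <- sprintf("p%02d", 1:40)
  tabs <- setNames(lapply(1:4, function(i)
    fold_change_table(ids, 2^rnorm(40))), paste0("QP", 1:4))
  rep4 <- reproducibility_report(tabs)
  expect_equal(nrow(rep4), 6L)          # choose(4, 2)
  expect_equal(nrow(reproducibility_report(tabs[1:2])), 1L)

  # (A,B) equals (B,A)
  ba <- reproducibility_report(tabs[c(2, 1)])
  expect_equal(ba[, c("pearson", "pearson_log2", "spearman")],
               rep4[1, c("pearson", "pearson_log2", "spearman")],
               ignore_attr = TRUE)

  # intensity mode: two rows (PRO and QUI) per pair
  cfg <- small_config(seed = 19)
  sim <- simulate_genome(cfg)
  truth <- simulate_expression(cfg)
  scans <- setNames(lapply(1:3, function(i)
    simulate_microarray(truth, sim$array_probes, "qui-cy5", cfg,
                        array_id = paste0("QP", i), seed = 100 + i)),
    paste0("QP", 1:3))
  ri <- reproducibility_report(scans)
  expect_equal(nrow(ri), 2L * choose(3, 2))
  expect_setequal(unique(ri$measure), c("intensity_pro", "intensity_qui"))

  expect_error(reproducibility_report(tabs[1]), "at least 2")
  expect_error(reproducibility_report(unname(tabs)), "named")
})
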