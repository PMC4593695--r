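make_scan <- function(cy3, cy5, excluded = FALSE, orientation = "qui-cy5") {
  array_scan("QPx", orientation,
             data.frame(probe_id = sprintf("p%03d", seq_along(cy3)),
                        cy3 = cy3, cy5 = cy5, excluded = excluded))
}

test_that("cross-channel correction inverts the mixing model", {
  sc <- make_scan(cy3 = 105, cy5 = 60)
  out <- cross_channel_correct(sc, 0.1)
  expect_equal(out$intensities$cy3, 100)
  expect_equal(out$intensities$cy5, 50)

  # alpha = 0 is the identity
  id <- cross_channel_correct(make_scan(c(10, 20), c(5, 8)), 0)
  expect_equal(id$intensities$cy3, c(10, 20))
  expect_equal(id$intensities$cy5, c(5, 8))

  # invertibility for any alpha in [0, 0.5): mix then unmix round-trips
  for (alpha in c(0.05, 0.2, 0.49)) {
    cy3 <- runif(20, 1, 1000); cy5 <- runif(20, 1, 1000)
    mixed <- make_scan(cy3 + alpha * cy5, cy5 + alpha * cy3)
    un <- cross_channel_correct(mixed, alpha)
    expect_equal(un$intensities$cy3, cy3, tolerance = 1e-9)
    expect_equal(un$intensities$cy5, cy5, tolerance = 1e-9)
  }

  # simulator round-trip: simulate with crosstalk, correct with the same alpha
  cfg0 <- noise_free_config(seed = 2)
  cfgx <- noise_free_config(seed = 2, crosstalk_alpha = 0.1)
  sim <- simulate_genome(cfg0)
  truth <- simulate_expression(cfg0)
  clean <- simulate_microarray(truth, sim$array_probes, "qui-cy5", cfg0)
  mixed <- simulate_microarray(truth, sim$array_probes, "qui-cy5", cfgx)
  un <- cross_channel_correct(mixed, 0.1)
  expect_equal(un$intensities$cy3, clean$intensities$cy3, tolerance = 1e-9)
  expect_equal(un$intensities$cy5, clean$intensities$cy5, tolerance = 1e-9)

  expect_error(cross_channel_correct(sc, 0.5), "0.5")
  expect_error(cross_channel_correct(sc, -0.01), "0.5")
  # negative unmixed values are floored and flagged
  neg <- cross_channel_correct(make_scan(c(10, 1), c(100, 300)), 0.2)
  expect_true(neg$intensities$floored[2])
  expect_gt(min(neg$intensities$cy3), 0)
})

test_that("MA-LOWESS removes dye trend, preserves A, and contracts on reapplication", {
  # constant log-ratio offset is removed completely
  n <- 200
  A <- runif(n, 4, 12)
  c_off <- 0.8
  sc <- make_scan(2^(A - c_off / 2), 2^(A + c_off / 2))
  norm <- lowess_normalize(sc)
  M <- log2(norm$intensities$cy5 / norm$intensities$cy3)
  expect_equal(M, rep(0, n), tolerance = 1e-9)

  # multiplicative dye bias in a noisy simulation: median M ~ 0 afterwards
  set.seed(42)
  n <- 5000
  A <- runif(n, 4, 14)
  M0 <- rnorm(n, 0, 0.4) + log2(1.7)   # bias g = 1.7 on the cy5 channel
  sc2 <- make_scan(2^(A - M0 / 2), 2^(A + M0 / 2))
  norm2 <- lowess_normalize(sc2)
  M2 <- log2(norm2$intensities$cy5 / norm2$intensities$cy3)
  expect_lt(abs(median(M2)), 0.01)

  # A is an invariant of the reconstruction
  A2 <- 0.5 * (log2(norm2$intensities$cy5) + log2(norm2$intensities$cy3))
  expect_lt(max(abs(A2 - A)), 1e-9)

  # second application changes far less than the first removed
  norm3 <- lowess_normalize(norm2)
  M3 <- log2(norm3$intensities$cy5 / norm3$intensities$cy3)
  first_pass <- max(abs(M0 - M2))
  expect_lt(max(abs(M3 - M2)), 0.1 * first_pass)

  expect_error(lowess_normalize(make_scan(1:5, 1:5)), "fewer than 10")
  bad <- make_scan(c(rep(1, 11)), c(rep(1, 10), 0))
  expect_error(lowess_normalize(bad), "positive")
})

test_that("fold changes respect orientation, exclusion and dye swaps", {
  sc <- make_scan(cy3 = c(50, 100, 10), cy5 = c(200, 100, 30),
                  excluded = c(FALSE, TRUE, FALSE))
  fc <- array_fold_changes(sc)
  expect_equal(fc$fc[fc$probe_id == "p001"], 4)
  expect_equal(fc$log2_fc[fc$probe_id == "p001"], 2)
  expect_false("p002" %in% fc$probe_id)   # excluded probe absent

  # swapping the orientation reciprocates every fold change
  fc_sw <- array_fold_changes(swap_orientation(sc))
  expect_equal(fc_sw$fc, 1 / fc$fc)
  expect_equal(cor(fc$log2_fc, fc_sw$log2_fc), -1)

  # double swap restores the original table
  expect_equal(array_fold_changes(swap_orientation(swap_orientation(sc))), fc)

  # zero PRO-channel intensity drops the probe with a message
  z <- make_scan(cy3 = c(0, 10), cy5 = c(5, 20))
  expect_message(fcz <- array_fold_changes(z), "zero PRO-channel")
  expect_equal(fcz$probe_id, "p002")
})

test_that("geometric-mean combination and its reciprocal commutation", {
  tabs <- lapply(c(2, 8, 4, 1), function(f) fold_change_table("p1", f))
  expect_equal(combine_arrays_geometric_mean(tabs)$fc, 64^(1 / 4))
  expect_equal(combine_arrays_geometric_mean(tabs[1:2])$fc, 4)
  ones <- lapply(rep(1, 4), function(f) fold_change_table("p1", f))
  expect_equal(combine_arrays_geometric_mean(ones)$fc, 1)

  # combine(1/fc) == 1 / combine(fc), probe-wise, for random tables
  set.seed(1)
  ids <- sprintf("p%02d", 1:30)
  tables <- lapply(1:4, function(i)
    fold_change_table(ids, 2^rnorm(30, 0, 2), source = paste0("QP", i)))
  recip <- lapply(tables, function(tb)
    fold_change_table(tb$probe_id, 1 / tb$fc, source = attr(tb, "source")))
  expect_equal(combine_arrays_geometric_mean(recip)$fc,
               1 / combine_arrays_geometric_mean(tables)$fc,
               tolerance = 1e-12)

  expect_error(fold_change_table("p1", 0), "> 0")
  expect_error(combine_arrays_geometric_mean(list()), "at least one")
})
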