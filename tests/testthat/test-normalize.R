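test_that("batch-mean scaling factors follow SF_i = C_i./C.. and average to 1", {
  pa <- primer_panel("V1", c("J1", "J2"))
  x <- st_counts(matrix(c(10, 10, 30, 30), nrow = 2, byrow = TRUE), pa)
  sf <- batch_scaling_factors(x)
  expect_equal(sf$factor, c(0.5, 1.5))

  flat <- st_counts(matrix(5, nrow = 2, ncol = 3), pa)
  expect_equal(batch_scaling_factors(flat)$factor, c(1, 1))

  set.seed(51)
  for (i in 1:5) {
    r <- counts_fixture(matrix(rpois(24, 60), nrow = 6))
    expect_equal(mean(batch_scaling_factors(r)$factor), 1)
  }
  expect_error(batch_scaling_factors(st_counts(matrix(0, 2, 2), pa)),
               "all-zero")
})

test_that("NB-mean factors equal batch-mean factors on a single batch", {
  pa <- primer_panel("V1", c("J1", "J2"))
  x <- st_counts(matrix(c(10, 10, 30, 30), nrow = 2, byrow = TRUE), pa)
  expect_equal(nb_scaling_factors(fit_panel(x))$factor, c(0.5, 1.5))

  model <- sample_bias_model(tiny_panel(), base_mean = 400, seed = 61)
  y <- simulate_st_counts(model, n_samples = 8, seed = 62)
  expect_equal(nb_scaling_factors(fit_panel(y))$factor,
               batch_scaling_factors(y)$factor)
  # and via pooled combined means of that single batch
  expect_equal(nb_scaling_factors(pool_batches(list(y)))$factor,
               batch_scaling_factors(y)$factor)

  flat <- bias_model(tiny_panel(), rep(100, 6))
  z <- simulate_st_counts(flat, n_samples = 1, seed = 63)
  expect_equal(batch_scaling_factors(z)$factor,
               as.numeric(count_matrix(z) / mean(count_matrix(z))))
})

test_that("normalized primer totals divide by the factor and conserve ST totals", {
  pa <- primer_panel("V1", c("J1", "J2"))
  x <- st_counts(matrix(c(10, 10, 30, 30), nrow = 2, byrow = TRUE), pa)
  sf <- batch_scaling_factors(x)
  out <- normalize_primer_totals(c(10, 30), sf)
  expect_equal(out$norm_total, c(20, 20))
  expect_equal(sum(out$norm_total), 40)

  # identity under unit factors; zeros stay zero
  flat <- batch_scaling_factors(st_counts(matrix(5, 2, 2), pa))
  expect_equal(normalize_primer_totals(c(3, 0), flat)$norm_total, c(3, 0))

  # exact grand-total conservation on the factor-generating matrix
  model <- sample_bias_model(tiny_panel(), base_mean = 300, seed = 71)
  y <- simulate_st_counts(model, n_samples = 6, seed = 72)
  sfy <- batch_scaling_factors(y)
  tot_norm <- rowSums(vapply(sample_ids(y), function(s) {
    normalize_primer_totals(y[[s]], sfy)$norm_total
  }, numeric(6)))
  expect_equal(sum(tot_norm), sum(count_matrix(y)))

  # a nonzero total on a pair without a factor errors by pair name
  m <- matrix(c(0, 0, 10, 10, 20, 20, 5, 5, 8, 8, 2, 2), nrow = 6,
              byrow = TRUE)
  suppressWarnings(sfz <- batch_scaling_factors(counts_fixture(m)))
  expect_error(normalize_primer_totals(rep(1, 6), sfz), "V1\\|J1")
})

test_that("clonotype normalization preserves within-pair proportions exactly", {
  pa <- primer_panel("V1", c("J1", "J2"))
  x <- st_counts(matrix(c(40, 40, 10, 10), nrow = 2, byrow = TRUE), pa)
  sf <- batch_scaling_factors(x)  # factors (1.6, 0.4)
  tb <- clonotype_table(c("AAA", "CCC", "GGG"), c("V1", "V1", "V1"),
                        c("J1", "J1", "J2"), c(30, 70, 10))
  norm <- normalize_clonotypes(tb, sf)
  # SF = 1.6 for J1: proportional redistribution = raw / SF
  expect_equal(norm$normalized_count[1:2], c(30, 70) / 1.6)
  expect_equal(norm$normalized_count[1] / sum(norm$normalized_count[1:2]),
               0.3)

  # SF_i = 2 hand case: clones (30, 70) -> (15, 35)
  one <- primer_panel("V1", c("J1", "J2", "J3"))
  xs <- st_counts(matrix(c(20, 20, 5, 5, 5, 5), nrow = 3, byrow = TRUE), one)
  sf2 <- batch_scaling_factors(xs)
  expect_equal(sf2$factor[1], 2)
  tb2 <- clonotype_table(c("A", "C"), c("V1", "V1"), c("J1", "J1"), c(30, 70))
  n2 <- normalize_clonotypes(tb2, sf2)
  expect_equal(n2$normalized_count, c(15, 35))

  # unit factors: normalized equals raw
  flat <- batch_scaling_factors(st_counts(matrix(6, 2, 2), pa))
  expect_equal(normalize_clonotypes(tb, flat)$normalized_count,
               tb$raw_count)

  # clonotypes on a pair with no factor are a hard error
  m <- matrix(c(0, 0, 10, 10), nrow = 2, byrow = TRUE)
  suppressWarnings(sfz <- batch_scaling_factors(st_counts(m, pa)))
  bad <- clonotype_table("AAA", "V1", "J1", 5)
  expect_error(normalize_clonotypes(bad, sfz), "V1\\|J1")
})

test_that("normalizing with factors recomputed from normalized data is idempotent", {
  model <- sample_bias_model(tiny_panel(), base_mean = 500, seed = 81)
  x <- simulate_st_counts(model, n_samples = 10, seed = 82)
  sf <- batch_scaling_factors(x)
  norm <- count_matrix(x) / sf$factor
  sf2 <- batch_scaling_factors(st_counts(norm, tiny_panel()))
  expect_equal(sf2$factor, rep(1, 6), tolerance = 1e-12)
})

test_that("normalization with true factors removes simulated bias in expectation", {
  p <- tiny_panel()
  means <- c(300, 100, 150, 80, 120, 60)
  model <- bias_model(p, means, dispersion = 0.05)
  # exact true factors from a noiseless ST matrix at the model means
  sf <- batch_scaling_factors(st_counts(cbind(means, means), p))
  expect_equal(sf$factor, means / mean(means))
  res <- vapply(1:30, function(s) {
    tb <- simulate_repertoire(c(0.5, 0.5), c(1L, 2L), model, depth = 5000,
                              seed = 200 + s)
    nt <- normalize_clonotypes(tb, sf)
    p1_norm <- nt$normalized_count[nt$pair == 1] / sum(nt$normalized_count)
    c(p1 = p1_norm,
      dev_raw = abs(dominant_clone_proportion(nt) - 0.5),
      dev_norm = abs(dominant_clone_proportion(nt, use_normalized = TRUE)
                     - 0.5))
  }, numeric(3))
  # the first clone's normalized frequency is unbiased at 1/2
  # (Monte-Carlo margin: 4 standard errors of the replicate mean)
  p1 <- res["p1", ]
  expect_lt(abs(mean(p1) - 0.5), 4 * sd(p1) / sqrt(length(p1)))
  # and the dominant clone deviates less from 1/2 than before normalization
  expect_lt(mean(res["dev_norm", ]), mean(res["dev_raw", ]))
  expect_gt(mean(res["dev_raw", ]), 0.2)  # raw data sit near 3/4
})

test_that("spread report shows normalization compressing within-sample spread", {
  model <- sample_bias_model(default_panel(), base_mean = 800,
                             log_spread = 4, dispersion = 0.125, seed = 91)
  x <- simulate_st_counts(model, n_samples = 6, seed = 92)
  sf <- nb_scaling_factors(fit_panel(x))
  rep_ <- spread_report(x, sf)
  expect_true(all(rep_$per_sample$cv_norm < rep_$per_sample$cv_raw))
  expect_true(all(rep_$per_sample$q3q1_norm < rep_$per_sample$q3q1_raw))
  expect_gt(rep_$iqr_contrast$fold, 1)

  # unbiased data with unit factors: before ~ after
  flat <- bias_model(default_panel(), rep(800, 260), dispersion = 0.125)
  y <- simulate_st_counts(flat, n_samples = 6, seed = 93)
  sf1 <- batch_scaling_factors(
    st_counts(matrix(800, 260, 2), default_panel()))
  rep0 <- spread_report(y, sf1)
  expect_equal(rep0$per_sample$q3q1_norm, rep0$per_sample$q3q1_raw)
})
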