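test_that("NB mean estimate is the arithmetic mean; dispersion clips at Poisson", {
  f <- fit_nb_single(c(7, 7, 7, 7))
  expect_equal(f$m_hat, 7)
  expect_equal(f$d_hat, 0)

  expect_equal(fit_nb_single(c(10, 30))$m_hat, 20)

  set.seed(17)
  for (i in 1:10) {
    x <- rpois(15, sample(5:500, 1))
    expect_equal(fit_nb_single(x)$m_hat, mean(x))
  }
  expect_error(fit_nb_single(c(0, 0, 0)), "all counts are zero")
  expect_error(fit_nb_single(5), "at least 2")
})

test_that("dispersion MLE is consistent for NB data", {
  p <- primer_panel("V1", "J1")
  x <- simulate_st_counts(bias_model(p, 200, dispersion = 0.125),
                          n_samples = 5000, seed = 23)
  f <- fit_nb_single(as.numeric(count_matrix(x)))
  expect_equal(f$d_hat, 0.125, tolerance = 0.08)
  # at the fitted (m, d) the likelihood is higher than at Poisson
  expect_gt(f$loglik, sum(dpois(count_matrix(x), f$m_hat, log = TRUE)))
})

test_that("panel fits give row means, a median common dispersion, and are permutation-stable", {
  m <- matrix(c(4, 4, 4, 9, 9, 9, 25, 25, 25, 1, 1, 1, 7, 7, 7, 3, 3, 3),
              nrow = 6, byrow = TRUE)
  x <- counts_fixture(m)
  fit <- fit_panel(x)
  expect_equal(fit$per_st$d_hat, rep(0, 6))  # identical columns
  expect_equal(fit$common_dispersion, 0)
  expect_equal(fit$per_st$m_hat, rowMeans(m))
  expect_equal(fit$m_bar, mean(rowMeans(m)))

  model <- sample_bias_model(tiny_panel(), base_mean = 300, seed = 2)
  y <- simulate_st_counts(model, n_samples = 12, seed = 3)
  fit_y <- fit_panel(y)
  perm <- y[, c("v_name", "j_name", sample(sample_ids(y)))]
  fit_p <- fit_panel(st_counts(perm, tiny_panel()))
  expect_equal(fit_p$per_st$d_hat, fit_y$per_st$d_hat)
  expect_equal(fit_p$per_st$m_hat, fit_y$per_st$m_hat)

  expect_error(fit_panel(counts_fixture(matrix(1:6, ncol = 1))),
               "at least 2 samples")
})

test_that("all-zero templates are excluded from the pooled estimates with a warning", {
  m <- matrix(c(10, 12, 8, 0, 0, 0, 30, 28, 32, 5, 6, 7, 9, 9, 9, 2, 3, 4),
              nrow = 6, byrow = TRUE)
  expect_warning(fit <- fit_panel(counts_fixture(m)), "all-zero")
  expect_true(is.na(fit$per_st$d_hat[2]))
  expect_equal(fit$m_bar, mean(rowMeans(m)[-2]))
  expect_warning(sf <- nb_scaling_factors(fit), "no scaling")
  expect_equal(nrow(sf), 5)
})

test_that("mean-variance table evaluates the model line and recovers slope 2", {
  m <- matrix(c(100, 100, 20, 60), nrow = 2, byrow = TRUE)
  mv <- mean_variance_table(counts_fixture(m), dispersion = 0.125)
  expect_equal(mv$v_model[mv$m_hat == 100], 100 + 0.125 * 100^2)  # 1350
  mv0 <- mean_variance_table(counts_fixture(m), dispersion = 0)
  expect_equal(mv0$v_model, mv0$m_hat)  # Poisson line

  # log-log slope ~2 at large means for common-dispersion NB counts
  set.seed(29)
  means <- 10^seq(3, 5, length.out = 8)
  emp <- t(vapply(means, function(mu) {
    x <- rnbinom(400, mu = mu, size = 1 / 0.125)
    c(mean(x), var(x))
  }, numeric(2)))
  slope <- coef(lm(log(emp[, 2]) ~ log(emp[, 1])))[2]
  expect_equal(unname(slope), 2, tolerance = 0.1)
})

test_that("pooled combined estimates are concentration-invariant weighted means", {
  # single batch: proportional to row means
  m1 <- matrix(c(10, 10, 30, 30, 20, 20, 40, 40, 50, 50, 30, 30),
               nrow = 6, byrow = TRUE)
  x1 <- counts_fixture(m1, "b1")
  single <- pool_batches(list(x1))
  expect_equal(single$m_rel, rowMeans(m1) / mean(rowMeans(m1)))
  expect_equal(mean(single$m_rel), 1)

  # a pure concentration shift changes nothing
  x2 <- counts_fixture(2 * m1, "b2", concentration = 2)
  expect_equal(pool_batches(list(x1, x2))$m_rel, single$m_rel)

  # hand arithmetic: batch means (10, 30) and (20, 60), equal n
  pa <- primer_panel("V1", c("J1", "J2"))
  ba <- st_counts(matrix(c(10, 10, 30, 30), nrow = 2, byrow = TRUE), pa)
  bb <- st_counts(matrix(c(20, 20, 60, 60), nrow = 2, byrow = TRUE), pa)
  expect_equal(pool_batches(list(ba, bb))$m_rel, c(0.5, 1.5))

  # unequal sample counts weight the batches
  bc_ <- st_counts(matrix(c(20, 20, 20, 20, 20, 20), nrow = 2,
                          byrow = TRUE), pa)
  comb <- pool_batches(list(ba, bc_))
  expect_equal(comb$m_rel,
               (2 * c(0.5, 1.5) + 3 * c(1, 1)) / 5 /
                 mean((2 * c(0.5, 1.5) + 3 * c(1, 1)) / 5))

  pb <- primer_panel("V1", c("J1", "J3"))
  bx <- st_counts(matrix(c(1, 1, 2, 2), nrow = 2), pb)
  expect_error(pool_batches(list(ba, bx)), "same primer panel")
})

test_that("independence spread floor is seeded and matches the Poisson closed form", {
  b1 <- independence_spread_bound(m = 400, d = 0, n_st = 100,
                                  n_samples = 8, n_rep = 20, seed = 44)
  b2 <- independence_spread_bound(m = 400, d = 0, n_st = 100,
                                  n_samples = 8, n_rep = 20, seed = 44)
  expect_identical(b1, b2)
  # Poisson CV ~ 1/sqrt(m) after normalization
  cv <- b1$mean[b1$statistic == "cv"]
  expect_equal(cv, 1 / sqrt(400), tolerance = 0.15)
  # larger mean, smaller floor
  b3 <- independence_spread_bound(m = 4000, d = 0, n_st = 100,
                                  n_samples = 8, n_rep = 20, seed = 44)
  expect_lt(b3$mean[b3$statistic == "cv"], cv)
  expect_error(independence_spread_bound(-1, 0, 10, 5, 5, seed = 1),
               "positive")
})

test_that("scaling-factor stability correlation is scale-invariant", {
  model <- sample_bias_model(tiny_panel(), base_mean = 500, seed = 13)
  x <- simulate_st_counts(model, n_samples = 10, seed = 14)
  fit <- fit_panel(x)
  expect_equal(scaling_factor_stability(fit, fit), 1)

  doubled <- st_counts(2 * count_matrix(x), tiny_panel(), batch_id = "b2")
  expect_equal(scaling_factor_stability(fit, fit_panel(doubled)), 1)

  y <- simulate_st_counts(model, n_samples = 10, seed = 15)
  r <- scaling_factor_stability(fit, fit_panel(y))
  expect_gt(r, 0.8)  # same bias model, independent noise
  expect_lte(r, 1)
})
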