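test_that("vj_table reshapes pair-ordered vectors onto the V x J grid", {
  p <- tiny_panel()
  ones <- vj_table(rep(1, 6), p)
  expect_equal(dim(ones), c(2, 3))
  expect_true(all(ones == 1))

  v <- rep(0, 6)
  v[pair_index(p, "Vb", "Jc")] <- 7
  m <- vj_table(v, p)
  expect_equal(m["Vb", "Jc"], 7)
  expect_equal(sum(m), 7)

  # flatten(vj_table(x)) round trip in pair order (J fastest)
  x <- rnorm(6)
  expect_equal(as.vector(t(vj_table(x, p))), x)
  expect_error(vj_table(rep(1, 5), p), "one entry per")
})

test_that("Pearson residuals match hand computation and the contingency oracle", {
  O <- matrix(c(10, 20, 30, 40), nrow = 2, byrow = TRUE)
  res <- pearson_residuals(O)
  expect_equal(res$expected, matrix(c(12, 18, 28, 42), nrow = 2,
                                    byrow = TRUE))
  expect_equal(res$values, (O - res$expected) / sqrt(res$expected))
  expect_equal(res$values[1, 1], -2 / sqrt(12))
  # classic 2x2 identity n(ad - bc)^2 / (r1 r2 c1 c2)
  expect_equal(res$chi_square,
               100 * (10 * 40 - 20 * 30)^2 / (30 * 70 * 40 * 60))

  # rank-one table: exact independence, all residuals zero
  rank1 <- outer(c(1, 2, 5), c(3, 4)) * 10
  expect_equal(max(abs(pearson_residuals(rank1)$values)), 0,
               tolerance = 1e-12)

  # chi-square equals stats::chisq.test on random small tables
  set.seed(77)
  for (i in 1:10) {
    tab <- matrix(rpois(12, 30) + 1, nrow = 3)
    expect_equal(pearson_residuals(tab)$chi_square,
                 unname(suppressWarnings(
                   chisq.test(tab, correct = FALSE)$statistic)))
  }
  expect_error(pearson_residuals(matrix(0, 2, 2)), "zero grand total")
  expect_warning(pearson_residuals(rbind(c(0, 0), c(3, 4))), "all-zero")
})

test_that("residual margins vanish: sum of residual * sqrt(E) is 0 per row and column", {
  set.seed(78)
  tab <- matrix(rpois(20, 50), nrow = 4)
  res <- pearson_residuals(tab)
  contrib <- res$values * sqrt(res$expected)
  expect_equal(max(abs(rowSums(contrib))), 0, tolerance = 1e-9)
  expect_equal(max(abs(colSums(contrib))), 0, tolerance = 1e-9)
})

test_that("chi-square is calibrated under separable models and inflated by interaction", {
  p <- default_panel()
  sep <- sample_bias_model(p, base_mean = 2000, log_spread = 2,
                           dispersion = 0, seed = 101)
  df <- (20 - 1) * (13 - 1)
  # per-sample Poisson tables from a separable model: E(chi-square) ~ df
  chis <- vapply(1:40, function(s) {
    x <- simulate_st_counts(sep, n_samples = 1, seed = 300 + s)
    pearson_residuals(vj_table(as.numeric(count_matrix(x)), p))$chi_square
  }, numeric(1))
  se <- sd(chis) / sqrt(length(chis))
  expect_lt(abs(mean(chis) - df), 3 * se)

  # block interaction inflates chi-square in every replicate
  inter <- matrix(1, 20, 13)
  inter[1:10, 1:6] <- 1.35
  inter[11:20, 7:13] <- 1.35
  inter <- inter / mean(inter)
  with_int <- bias_model(p, sep$st_means, dispersion = 0,
                         interaction = inter)
  chis_int <- vapply(1:10, function(s) {
    x <- simulate_st_counts(with_int, n_samples = 1, seed = 400 + s)
    pearson_residuals(vj_table(as.numeric(count_matrix(x)), p))$chi_square
  }, numeric(1))
  expect_true(all(chis_int > max(chis)))
})

test_that("clustering orders group similar dependence patterns adjacently", {
  # two identical rows end up adjacent
  tab <- rbind(c(30, 5, 5), c(30, 5, 5), c(5, 30, 5), c(5, 5, 30))
  res <- cluster_order(pearson_residuals(tab))
  ord <- res$row_order
  expect_equal(abs(which(ord == 1) - which(ord == 2)), 1)

  # block-structured interaction: rows of one block stay together
  p <- primer_panel(sprintf("V%d", 1:6), sprintf("J%d", 1:4))
  inter <- matrix(1, 6, 4)
  inter[1:3, 1:2] <- 2
  inter[4:6, 3:4] <- 2
  m <- bias_model(p, rep(500, 24), dispersion = 0, interaction = inter)
  x <- simulate_st_counts(m, n_samples = 1, seed = 55)
  res2 <- cluster_order(pearson_residuals(
    vj_table(as.numeric(count_matrix(x)), p)))
  pos <- match(1:6, res2$row_order)
  block1 <- sort(match(1:3, res2$row_order))
  expect_equal(block1, seq(block1[1], block1[1] + 2))

  # permuting rows preserves the partition (flat clusters at k = 2)
  perm <- c(4, 1, 6, 2, 5, 3)
  res3 <- cluster_order(pearson_residuals(
    vj_table(as.numeric(count_matrix(x)), p)[perm, ]))
  cut_orig <- cutree(hclust(dist(res2$values), "average"), k = 2)
  cut_perm <- cutree(hclust(dist(res3$values), "average"), k = 2)[order(perm)]
  agree <- outer(cut_orig, cut_orig, "==") == outer(cut_perm, cut_perm, "==")
  expect_true(all(agree))

  expect_error(cluster_order(pearson_residuals(matrix(c(1, 2), 1, 2))),
               "at least 2")
})

test_that("tidy and autoplot expose the residual matrix faithfully", {
  tab <- matrix(rpois(12, 40) + 1, nrow = 3,
                dimnames = list(c("Va", "Vb", "Vc"), sprintf("J%d", 1:4)))
  res <- cluster_order(pearson_residuals(tab))
  td <- tidy(res)
  expect_equal(nrow(td), 12)
  expect_equal(td$residual[td$v_name == "Vb" & td$j_name == "J3"],
               res$values["Vb", "J3"])
  pl <- autoplot(res)
  expect_s3_class(pl, "ggplot")
})
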