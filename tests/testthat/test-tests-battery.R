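test_that("pooled t-test matches the hand-worked example and t.test", {
  fm <- feature_matrix(matrix(c(1, 2, 3, 4, 3, 4, 5, 6), nrow = 1),
                       scale = "normal")
  labels <- factor(rep(c("A", "B"), each = 4))
  res <- row_t_equal_var(fm, labels)
  # pooled SS = 10, df = 6, se = sqrt((10/6) * (1/4 + 1/4)) = 0.9129
  expect_equal(res$statistic, -2.1909, tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(res$p_value, 0.070988, tolerance = 1e-4, ignore_attr = TRUE)
  expect_identical(res$df, 6L)

  # per-feature agreement with stats::t.test on random data
  set.seed(1)
  fm2 <- feature_matrix(matrix(rnorm(20 * 30), nrow = 20), scale = "normal")
  lab2 <- random_group_labels(30, seed = 2)
  res2 <- row_t_equal_var(fm2, lab2)
  for (j in c(1, 7, 20)) {
    ref <- t.test(fm2[j, lab2 == "A"], fm2[j, lab2 == "B"], var.equal = TRUE)
    expect_equal(unname(res2$statistic[j]), unname(ref$statistic),
                 tolerance = 1e-10)
    expect_equal(unname(res2$p_value[j]), ref$p.value, tolerance = 1e-10)
  }
})

test_that("identical groups give t = 0, p = 1; degenerate features do not abort", {
  vals <- rbind(c(1, 2, 3, 1, 2, 3),     # same values both groups
                c(1, 1, 1, 1, 1, 1),     # constant everywhere
                c(0, 0, 0, 1, 1, 1))     # constant per group, unequal means
  fm <- feature_matrix(vals, scale = "normal")
  labels <- factor(rep(c("A", "B"), each = 3))
  res <- suppressWarnings(row_t_equal_var(fm, labels))
  expect_equal(res$statistic[1], 0, ignore_attr = TRUE)
  expect_equal(res$p_value[1], 1, ignore_attr = TRUE)
  expect_equal(res$p_value[2], 1, ignore_attr = TRUE)
  expect_equal(res$p_value[3], 0, ignore_attr = TRUE)
  expect_warning(row_t_equal_var(fm, labels), "degenerate")

  small <- feature_matrix(matrix(rnorm(8), nrow = 2), scale = "normal")
  expect_error(row_t_equal_var(small, factor(c("A", "A", "A", "B"))),
               class = "depfdr_size_error")
})

test_that("two-group tests are invariant to swapping group labels", {
  set.seed(3)
  fm <- feature_matrix(matrix(rnorm(50 * 24), nrow = 50), scale = "normal")
  lab <- random_group_labels(24, seed = 4)
  swapped <- factor(ifelse(lab == "A", "B", "A"), levels = c("A", "B"))
  for (test in c("t_equal_var", "moderated_t", "wilcoxon")) {
    p1 <- run_feature_test(fm, lab, test)$p_value
    p2 <- run_feature_test(fm, swapped, test)$p_value
    expect_equal(p1, p2, tolerance = 1e-12)
  }
})

test_that("moderated t collapses to the ordinary t in its limits", {
  set.seed(5)
  # identical variance for every feature: shifted copies of one template
  base <- rnorm(16)
  vals <- t(vapply(1:30, function(j) base + j, numeric(16)))
  fm <- feature_matrix(vals + rnorm(16)[col(vals)] * 0, scale = "normal")
  lab <- factor(rep(c("A", "B"), 8))
  mod <- row_moderated_t(fm, lab)
  ord <- row_t_equal_var(fm, lab)
  # all sample variances equal -> complete shrinkage to a common variance:
  # statistics proportional to the ordinary t with a factor near 1 (the
  # log-scale bias correction in the prior-variance estimate)
  ratio <- mod$statistic / ord$statistic
  expect_lt(diff(range(ratio)), 1e-8)
  expect_equal(mean(ratio), 1, tolerance = 0.1)
  expect_identical(mod$d0, Inf)

  # d0 = 0: no prior, exact ordinary t
  set.seed(6)
  fm2 <- feature_matrix(matrix(rnorm(40 * 20), nrow = 40), scale = "normal")
  lab2 <- random_group_labels(20, seed = 7)
  mod0 <- row_moderated_t(fm2, lab2, d0 = 0)
  ord2 <- row_t_equal_var(fm2, lab2)
  expect_equal(mod0$statistic, ord2$statistic, tolerance = 1e-12)
  expect_equal(mod0$p_value, ord2$p_value, tolerance = 1e-12)

  expect_error(row_moderated_t(feature_matrix(matrix(rnorm(12), 3),
                                              scale = "normal"),
                               factor(c("A", "A", "B", "B"))),
               class = "depfdr_ensemble_error")
})

test_that("moderated t agrees with limma's empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  set.seed(8)
  fm <- feature_matrix(matrix(rnorm(500 * 16, sd = rep(exp(rnorm(500, 0, 0.6)), 16)),
                              nrow = 500), scale = "normal")
  lab <- factor(rep(c("A", "B"), each = 8))
  ours <- row_moderated_t(fm, lab)

  design <- cbind(1, lab == "A")
  fit <- limma::eBayes(limma::lmFit(unclass(fm), design))
  expect_equal(ours$d0, fit$df.prior, tolerance = 0.05)
  expect_equal(ours$s0_sq, fit$s2.prior, tolerance = 0.05)
  expect_equal(abs(ours$statistic), abs(fit$t[, 2]), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(ours$p_value, fit$p.value[, 2], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("Wilcoxon rank-sum matches enumeration, wilcox.test and rank invariances", {
  fm <- feature_matrix(matrix(c(1, 2, 3, 4), nrow = 1), scale = "normal")
  lab <- factor(c("A", "A", "B", "B"))
  res <- row_wilcoxon(fm, lab)
  expect_equal(res$p_value, 2 / 6, tolerance = 1e-12, ignore_attr = TRUE)

  set.seed(9)
  n <- 16
  fm2 <- feature_matrix(matrix(rnorm(10 * n), nrow = 10), scale = "normal")
  lab2 <- factor(rep(c("A", "B"), each = n / 2))
  res2 <- row_wilcoxon(fm2, lab2)
  for (j in 1:10) {
    ref <- wilcox.test(fm2[j, lab2 == "A"], fm2[j, lab2 == "B"], exact = TRUE)
    expect_equal(res2$p_value[j], ref$p.value, tolerance = 1e-12)
  }
  # large-sample normal approximation against wilcox.test's
  fm3 <- feature_matrix(matrix(rnorm(5 * 60), nrow = 5), scale = "normal")
  lab3 <- factor(rep(c("A", "B"), each = 30))
  res3 <- row_wilcoxon(fm3, lab3)
  for (j in 1:5) {
    ref <- wilcox.test(fm3[j, lab3 == "A"], fm3[j, lab3 == "B"],
                       exact = FALSE, correct = TRUE)
    expect_equal(res3$p_value[j], ref$p.value, tolerance = 1e-10)
  }

  # invariance to observation order and to monotone transforms
  perm <- sample(n)
  res_perm <- row_wilcoxon(feature_matrix(unclass(fm2)[, perm], scale = "normal"),
                           lab2[perm])
  expect_equal(res_perm$p_value, res2$p_value, tolerance = 1e-12)
  mono <- feature_matrix(exp(unclass(fm2)), scale = "normal")
  expect_equal(row_wilcoxon(mono, lab2)$p_value, res2$p_value, tolerance = 1e-12)
})

test_that("KS normality test detects non-normal features and fits perfect ones", {
  n <- 100
  perfect <- feature_matrix(matrix(qnorm((1:n - 0.5) / n), nrow = 1),
                            scale = "normal")
  res <- row_ks_normal(perfect)
  expect_lte(res$statistic[1], 0.5 / n + 1e-12)
  expect_gt(res$p_value[1], 0.999)

  set.seed(10)
  unif <- feature_matrix(matrix(runif(n), nrow = 1), scale = "normal")
  expect_lt(row_ks_normal(unif)$p_value[1], 0.001)

  # fraction of null N(0,1) features below 0.05 stays near nominal
  fm <- feature_matrix(matrix(rnorm(2000 * 50), nrow = 2000), scale = "normal")
  frac <- mean(row_ks_normal(fm)$p_value < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 2000) + 0.01)
})

test_that("t-test p-values are uniform under the independent null", {
  set.seed(11)
  fm <- feature_matrix(matrix(rnorm(10000 * 20), nrow = 10000),
                       scale = "normal")
  p <- row_t_equal_var(fm, random_group_labels(20, 12))$p_value
  frac <- mean(p < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 10000))
  expect_true(all(p >= 0 & p <= 1))
})
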