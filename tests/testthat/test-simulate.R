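test_that("method-of-moments recovers beta shapes from large samples", {
  params <- data.frame(feature_id = c("f1", "f2"), a = c(2, 0.8), b = c(5, 3))
  fm <- simulate_independent_beta(1e5, params, seed = 42)
  est <- estimate_beta_params(fm)
  expect_equal(est$a, params$a, tolerance = 0.05)
  expect_equal(est$b, params$b, tolerance = 0.05)
})

test_that("mirror-symmetric features give a = b and degenerate features error", {
  sym <- feature_matrix(matrix(c(0.2, 0.8, 0.3, 0.7), nrow = 1), scale = "beta")
  est <- estimate_beta_params(sym)
  expect_equal(est$a, est$b)

  const <- feature_matrix(matrix(0.5, nrow = 1, ncol = 5), scale = "beta")
  expect_error(estimate_beta_params(const),
               class = "depfdr_degenerate_feature_error")
  expect_match(tryCatch(estimate_beta_params(const), error = conditionMessage),
               "f1")

  out_of_range <- matrix(c(0.2, 1.2, 0.4, 0.5), nrow = 1)
  expect_error(feature_matrix(out_of_range, scale = "beta"),
               class = "depfdr_invalid_scale_error")
})

test_that("block construction yields the prescribed correlations", {
  # fixed r: empirical corr with the representative should match analytically
  cfg <- dependence_config(bin_size = 10, corr_range = c(0.8, 0.8),
                           prop_correlated = 1)
  fm <- simulate_correlated_gaussian(10000, 20, cfg, seed = 7)
  blocks <- attr(fm, "block")
  for (b in unique(blocks)) {
    idx <- which(blocks == b)
    cc <- cor(fm[idx[1], ], t(fm[idx[-1], , drop = FALSE]))
    expect_true(all(abs(cc - 0.8) < 0.02))
  }

  # r = 0: everything mutually independent
  cfg0 <- dependence_config(corr_range = c(0, 0), prop_correlated = 1)
  fm0 <- simulate_correlated_gaussian(5000, 30, cfg0, seed = 8)
  cc0 <- cor(t(unclass(fm0)))
  expect_lt(mean(abs(cc0[upper.tri(cc0)])), 3 / sqrt(5000))

  # r -> 1: members coincide with the representative
  cfg1 <- dependence_config(bin_size = 5, corr_range = c(1 - 1e-9, 1 - 1e-9),
                            prop_correlated = 1)
  fm1 <- simulate_correlated_gaussian(50, 5, cfg1, seed = 9)
  expect_equal(unclass(fm1)[2, ], unclass(fm1)[1, ], tolerance = 1e-3)
})

test_that("within-block correlations respect corr_range; cross-block near zero", {
  cfg <- dependence_config(bin_size = 25, corr_range = c(0.6, 0.9),
                           prop_correlated = 1)
  n_obs <- 4000
  fm <- simulate_correlated_gaussian(n_obs, 100, cfg, seed = 11)
  blocks <- attr(fm, "block")
  tol <- 3 / sqrt(n_obs)
  within <- c()
  for (b in unique(blocks)) {
    idx <- which(blocks == b)
    rep_row <- idx[1]
    within <- c(within, cor(fm[rep_row, ], t(fm[idx[-1], , drop = FALSE])))
  }
  expect_true(all(within > 0.6 - tol & within < 0.9 + tol))
  cross <- cor(t(unclass(fm)))[blocks == 1, blocks == 2]
  # members of different blocks are independent
  expect_lt(mean(abs(cross)), 3 / sqrt(n_obs))
})

test_that("copula transform preserves target beta marginals and ranks", {
  # uniform shapes: output is the probability integral transform of the input
  g <- simulate_mvn(200, 3, seed = 13)
  unif <- gaussian_to_beta(g, data.frame(a = rep(1, 3), b = rep(1, 3)))
  expect_equal(unclass(unif), pnorm(unclass(g)), tolerance = 1e-12,
               ignore_attr = TRUE)

  # marginal preservation under dependence: one-sample KS against Beta(a,b)
  # below the 1% critical value for >= 20 randomly chosen features
  n_obs <- 10000
  cfg <- dependence_config()
  params <- sample_methylation_params(60, seed = 14)
  g2 <- simulate_correlated_gaussian(n_obs, 60, cfg, seed = 15)
  bmat <- gaussian_to_beta(g2, params, maps = beta_quantile_maps(params))
  ks_crit_01 <- 1.6276 / sqrt(n_obs)
  set.seed(16)
  for (j in sample(60, 25)) {
    d <- suppressWarnings(
      ks.test(bmat[j, ], function(x) pbeta(x, params$a[j], params$b[j])))
    expect_lt(unname(d$statistic), ks_crit_01)
  }
  # monotone maps preserve within-feature rank order
  expect_identical(rank(bmat[1, ]), rank(g2[1, ]))
})

test_that("independent beta generator has the right moments and is seed-pure", {
  params <- data.frame(a = 2, b = 2)
  fm <- simulate_independent_beta(1e5, params, seed = 3)
  expect_equal(mean(fm), 0.5, tolerance = 0.005)
  expect_identical(unclass(simulate_independent_beta(50, params, seed = 5)),
                   unclass(simulate_independent_beta(50, params, seed = 5)))
  expect_error(simulate_independent_beta(10, data.frame(a = -1, b = 2), seed = 1),
               class = "depfdr_config_error")
})

test_that("M-value transform is the base-2 logit with exact round-trip", {
  b <- feature_matrix(matrix(c(0.5, 0.8, 0.2, 0.9), nrow = 2), scale = "beta")
  m <- beta_to_m(b)
  expect_equal(m[1, 1], 0)
  expect_equal(m[2, 1], 2)  # log2(0.8/0.2)
  expect_equal(unclass(m_to_beta(m)), unclass(b), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(beta_to_m(m), class = "depfdr_invalid_scale_error")
})

test_that("effect injection shifts exactly one group by the stated constant", {
  dat <- make_null_m_dataset(40, 1000, seed = 21)
  labels <- random_group_labels(40, seed = 22)
  inj <- inject_effect(dat, labels, fraction = 0.015, seed = 23)
  expect_identical(sum(inj$truth$is_non_null), 15L)  # ceiling(0.015 * 1000)

  gA <- labels == levels(labels)[1]
  diff_before <- rowMeans(dat[, gA]) - rowMeans(dat[, !gA])
  diff_after <- rowMeans(inj$matrix[, gA]) - rowMeans(inj$matrix[, !gA])
  delta <- diff_after - diff_before
  sign <- if (inj$truth$shifted_group == levels(labels)[1]) 1 else -1
  expect_equal(delta[inj$truth$is_non_null],
               rep(sign * 1, 15), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(delta[!inj$truth$is_non_null], rep(0, 985), ignore_attr = TRUE)

  # zero shift: values untouched, mask still set
  inj0 <- inject_effect(dat, labels, fraction = 0.015, shift = 0, seed = 23)
  expect_equal(unclass(inj0$matrix), unclass(dat), ignore_attr = TRUE)
  expect_identical(sum(inj0$truth$is_non_null), 15L)

  # demanding more eligible features than exist reports the shortage
  expect_error(
    inject_effect(dat, labels, fraction = 0.9, seed = 23),
    class = "depfdr_eligibility_error")
})

test_that("label shuffling is a seed-pure permutation preserving group sizes", {
  labels <- factor(rep(c("A", "B"), c(6, 4)))
  for (s in 1:5) {
    sh <- shuffle_labels(labels, seed = s)
    expect_identical(c(table(sh)), c(table(labels)))
  }
  expect_identical(shuffle_labels(labels, 9), shuffle_labels(labels, 9))

  # two observations: identity and swap both occur across seeds
  two <- factor(c("A", "B"))
  outcomes <- vapply(1:200, function(s) shuffle_labels(two, s)[1] == "A", TRUE)
  expect_gt(mean(outcomes), 0.35)
  expect_lt(mean(outcomes), 0.65)
})

test_that("generators are pure functions of their seed", {
  cfg <- dependence_config()
  a <- simulate_correlated_gaussian(30, 120, cfg, seed = 77)
  b <- simulate_correlated_gaussian(30, 120, cfg, seed = 77)
  expect_identical(unclass(a), unclass(b))
  expect_false(identical(
    unclass(simulate_correlated_gaussian(30, 120, cfg, seed = 78)),
    unclass(a)))
  expect_identical(derive_seed(5, 0:10), derive_seed(5, 0:10))
  expect_identical(anyDuplicated(derive_seed(1, 0:10000)), 0L)
})
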