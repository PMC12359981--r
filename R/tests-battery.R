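#' Feature-wise statistical tests
#'
#' One p-value per feature (row) of a [feature_matrix]. Four tests are
#' available:
#'
#' * `t_equal_var` — two-sided pooled-variance Student t-test comparing the
#'   two groups, df = n - 2.
#' * `moderated_t` — empirical-Bayes moderated t: per-feature residual
#'   variances are shrunk toward an ensemble prior before forming the
#'   t-statistic (see [row_moderated_t()]).
#' * `wilcoxon` — two-sided Wilcoxon rank-sum test; exact null distribution
#'   when both groups have fewer than 20 observations and the feature has no
#'   ties, otherwise a normal approximation with tie and continuity
#'   correction.
#' * `ks_normal` — one-sample Kolmogorov-Smirnov test of each feature
#'   against the fixed standard normal CDF (no parameter estimation: the
#'   simulated normal marginals are standard by construction).
#'
#' Degenerate features (zero pooled variance with equal group means) yield
#' statistic 0 and p = 1 rather than an error, so whole-matrix runs never
#' abort; their count is recorded in the result.
#'
#' @param matrix A [feature_matrix].
#' @param labels Two-group vector of length `ncol(matrix)`; ignored by
#'   `ks_normal`.
#' @param test One of `"t_equal_var"`, `"moderated_t"`, `"wilcoxon"`,
#'   `"ks_normal"`.
#' @return A `test_result`: list with `statistic`, `p_value`, `df` (where
#'   defined), `test_name`, `feature_ids`, `degenerate` (logical vector).
#' @export
#' @examples
#' fm <- simulate_mvn(20, 50, seed = 1)
#' res <- run_feature_test(fm, random_group_labels(20, 2), "t_equal_var")
#' head(res$p_value)
run_feature_test <- function(matrix, labels = NULL,
                             test = c("t_equal_var", "moderated_t",
                                      "wilcoxon", "ks_normal")) {
  test <- match.arg(test)
  switch(test,
    t_equal_var = row_t_equal_var(matrix, labels),
    moderated_t = row_moderated_t(matrix, labels),
    wilcoxon    = row_wilcoxon(matrix, labels),
    ks_normal   = row_ks_normal(matrix))
}

new_test_result <- function(statistic, p_value, test_name, matrix,
                            df = NULL, degenerate = NULL, extra = list()) {
  stopifnot(length(statistic) == nrow(matrix),
            length(p_value) == nrow(matrix))
  out <- c(list(statistic = statistic,
                p_value = pmin(pmax(p_value, 0), 1),
                df = df,
                test_name = test_name,
                feature_ids = rownames(matrix),
                degenerate = degenerate %||% logical(nrow(matrix))),
           extra)
  class(out) <- "test_result"
  out
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s, %d features (%d degenerate)\n",
              x$test_name, length(x$p_value), sum(x$degenerate)))
  invisible(x)
}

group_split_stats <- function(matrix, labels) {
  labels <- check_two_groups(labels, ncol(matrix))
  g1 <- labels == levels(labels)[1L]
  x1 <- unclass(matrix)[, g1, drop = FALSE]
  x2 <- unclass(matrix)[, !g1, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2)
  ss2 <- rowSums((x2 - m2)^2)
  list(labels = labels, n1 = n1, n2 = n2, diff = m1 - m2,
       pooled_var = (ss1 + ss2) / (n1 + n2 - 2),
       s2 = (ss1 + ss2) / (n1 + n2 - 2))
}

#' @rdname run_feature_test
#' @export
row_t_equal_var <- function(matrix, labels) {
  st <- group_split_stats(matrix, labels)
  df <- st$n1 + st$n2 - 2L
  se <- sqrt(st$pooled_var * (1 / st$n1 + 1 / st$n2))
  tstat <- st$diff / se
  degen <- se == 0
  # zero pooled variance: equal means -> t = 0, p = 1; unequal -> p = 0
  tstat[degen & st$diff == 0] <- 0
  p <- 2 * stats::pt(-abs(tstat), df = df)
  p[degen & st$diff == 0] <- 1
  p[degen & st$diff != 0] <- 0
  if (any(degen)) {
    warning(sprintf("%d degenerate (zero-variance) feature(s)", sum(degen)))
  }
  new_test_result(tstat, p, "t_equal_var", matrix, df = df, degenerate = degen)
}

#' Empirical-Bayes moderated t-test
#'
#' Residual variances \eqn{s_j^2} (pooled, df \eqn{d = n - 2}) are modelled
#' as scaled-F draws around a prior variance \eqn{s_0^2} with prior df
#' \eqn{d_0}; the posterior variance
#' \eqn{\tilde s_j^2 = (d_0 s_0^2 + d s_j^2) / (d_0 + d)} replaces
#' \eqn{s_j^2} in the t-statistic, which is referred to a t distribution
#' with \eqn{d + d_0} df. The hyperparameters are estimated by matching the
#' first two moments of \eqn{\log s_j^2} to the scaled log-F law:
#' \eqn{\mathrm{var}(\log s_j^2) - \psi'(d/2) = \psi'(d_0/2)} is solved for
#' \eqn{d_0} by Newton iteration on the inverse trigamma, with
#' \eqn{d_0 = \infty} (complete shrinkage to \eqn{s_0^2}) when the observed
#' spread of log-variances is no larger than expected under a common
#' variance.
#'
#' @inheritParams run_feature_test
#' @param d0,s0_sq Optional hyperparameter overrides; when supplied the
#'   estimation step is skipped (useful for studying limits: `d0 = 0`
#'   recovers the ordinary t-test, `d0 = Inf` a common-variance z-like
#'   test).
#' @return A `test_result` with extra fields `d0` and `s0_sq`.
#' @export
row_moderated_t <- function(matrix, labels, d0 = NULL, s0_sq = NULL) {
  if (nrow(matrix) < 10L && is.null(d0)) {
    stop_depfdr("moderated t needs >= 10 features to estimate its prior",
                "depfdr_ensemble_error")
  }
  st <- group_split_stats(matrix, labels)
  d <- st$n1 + st$n2 - 2
  s2 <- st$s2
  degen <- s2 == 0
  if (is.null(d0)) {
    z <- log(s2[!degen])
    evar <- stats::var(z) - trigamma(d / 2)
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s0_sq <- exp(mean(z) - digamma(d / 2) + log(d / 2) +
                   digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s0_sq <- exp(mean(z) - digamma(d / 2) + log(d / 2))
    }
  } else if (is.null(s0_sq)) {
    s0_sq <- exp(mean(log(s2[!degen])) - digamma(d / 2) + log(d / 2))
  }
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else {
    (d0 * s0_sq + d * s2) / (d0 + d)
  }
  df_total <- d + d0
  se <- sqrt(s2_post * (1 / st$n1 + 1 / st$n2))
  tstat <- st$diff / se
  tstat[degen & st$diff == 0 & se == 0] <- 0
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  p[se == 0 & st$diff == 0] <- 1
  p[se == 0 & st$diff != 0] <- 0
  new_test_result(tstat, p, "moderated_t", matrix, df = df_total,
                  degenerate = degen,
                  extra = list(d0 = d0, s0_sq = s0_sq))
}

# Newton solve of trigamma(x) = y (limma-style inverse trigamma)
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) < 1e-10 * x) break
  }
  x
}

#' @rdname run_feature_test
#' @param exact_max Largest per-group size for which the exact rank-sum null
#'   distribution is used (default 19; above it, normal approximation with
#'   tie and continuity correction).
#' @export
row_wilcoxon <- function(matrix, labels, exact_max = 19L) {
  labels <- check_two_groups(labels, ncol(matrix))
  g1 <- labels == levels(labels)[1L]
  n1 <- sum(g1); n2 <- sum(!g1); n <- n1 + n2
  x <- unclass(matrix)
  m <- nrow(x)
  u <- numeric(m); p <- numeric(m); has_ties <- logical(m)
  use_exact <- max(n1, n2) <= exact_max
  mu <- n1 * n2 / 2
  for (j in seq_len(m)) {
    r <- rank(x[j, ])
    tie_tab <- table(r)
    ties <- any(tie_tab > 1L)
    has_ties[j] <- ties
    uj <- sum(r[g1]) - n1 * (n1 + 1) / 2
    u[j] <- uj
    if (use_exact && !ties) {
      pj <- if (uj > mu) {
        2 * (1 - stats::pwilcox(uj - 1, n1, n2))
      } else {
        2 * stats::pwilcox(uj, n1, n2)
      }
      p[j] <- min(1, pj)
    } else {
      tie_term <- sum(tie_tab^3 - tie_tab) / ((n) * (n - 1))
      sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
      if (sigma == 0) { p[j] <- 1; u[j] <- mu; next }
      z <- (abs(uj - mu) - 0.5) / sigma
      p[j] <- min(1, 2 * stats::pnorm(-z))
    }
  }
  new_test_result(u, p, "wilcoxon", matrix, degenerate = has_ties & use_exact)
}

#' @rdname run_feature_test
#' @export
row_ks_normal <- function(matrix) {
  assert_scale(matrix, "normal")
  if (ncol(matrix) < 5L) {
    stop_depfdr("KS normality test needs >= 5 observations",
                "depfdr_shape_error")
  }
  x <- unclass(matrix)
  res <- apply(x, 1L, function(row) {
    k <- suppressWarnings(stats::ks.test(row, "pnorm"))
    c(k$statistic, k$p.value)
  })
  new_test_result(res[1L, ], res[2L, ], "ks_normal", matrix)
}
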