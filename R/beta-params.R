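#' Estimate per-feature beta-distribution parameters
#'
#' Method-of-moments estimates of the two shape parameters of a beta
#' distribution, one pair per feature (row). With per-feature sample mean
#' \eqn{\bar m} and variance \eqn{v}, the estimates are
#' \deqn{\hat a = \bar m\,(\bar m(1-\bar m)/v - 1), \qquad
#'       \hat b = (1-\bar m)\,(\bar m(1-\bar m)/v - 1).}
#' Closed-form and robust, which is all a plasmode-style marginal mimicry
#' needs; no likelihood iteration is involved.
#'
#' @param matrix A beta-scale [feature_matrix] (all entries strictly in
#'   (0,1)) with at least 3 observations per feature.
#' @return A data.frame with columns `feature_id`, `a`, `b`.
#' @export
#' @examples
#' fm <- simulate_independent_beta(500, data.frame(a = 2, b = 5), seed = 1)
#' estimate_beta_params(fm)
estimate_beta_params <- function(matrix) {
  assert_scale(matrix, "beta")
  if (ncol(matrix) < 3L) {
    stop_depfdr("need at least 3 observations per feature",
                "depfdr_shape_error")
  }
  m <- rowMeans(matrix)
  v <- apply(matrix, 1L, stats::var)
  if (any(v == 0)) {
    bad <- rownames(matrix)[which(v == 0)[1L]]
    stop_depfdr(sprintf("feature %s has zero variance; beta parameters are undefined", bad),
                "depfdr_degenerate_feature_error")
  }
  # moment estimates can go non-positive when v >= m(1-m) (overdispersed
  # relative to any beta); flag rather than silently clip
  k <- m * (1 - m) / v - 1
  if (any(k <= 0)) {
    bad <- rownames(matrix)[which(k <= 0)[1L]]
    stop_depfdr(sprintf("feature %s has variance too large for a beta law", bad),
                "depfdr_degenerate_feature_error")
  }
  data.frame(feature_id = rownames(matrix), a = m * k, b = (1 - m) * k,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Synthetic methylation-like beta parameters
#'
#' Draws per-feature beta shape parameters from a mixture that mimics the
#' marginal landscape of methylation arrays: a hypomethylated mode (mean
#' beta value near 0.1), a hypermethylated mode (near 0.85) and a smaller
#' intermediate fraction, with precision \eqn{a+b} log-normally distributed
#' around 30 so that per-site standard deviations fall in the few-percent
#' range typical of array data. This is a synthetic stand-in for parameters
#' estimated from a real reference array and can be replaced by the output
#' of [estimate_beta_params()] on any beta-scale matrix.
#'
#' @param n_features Number of features.
#' @param seed Integer seed.
#' @param prop Length-3 mixture proportions (hypo, hyper, intermediate).
#' @return A data.frame with columns `feature_id`, `a`, `b`.
#' @export
sample_methylation_params <- function(n_features, seed,
                                      prop = c(0.60, 0.30, 0.10)) {
  stopifnot(n_features >= 1, length(prop) == 3, all(prop >= 0))
  prop <- prop / sum(prop)
  with_seed(seed, {
    comp <- sample.int(3L, n_features, replace = TRUE, prob = prop)
    mu <- numeric(n_features)
    mu[comp == 1L] <- stats::rbeta(sum(comp == 1L), 4, 36)     # mean 0.10
    mu[comp == 2L] <- stats::rbeta(sum(comp == 2L), 34, 6)     # mean 0.85
    mu[comp == 3L] <- stats::runif(sum(comp == 3L), 0.3, 0.7)
    mu <- pmin(pmax(mu, 0.02), 0.98)
    nu <- stats::rlnorm(n_features, meanlog = log(30), sdlog = 0.5)
    data.frame(feature_id = paste0("f", seq_len(n_features)),
               a = mu * nu, b = (1 - mu) * nu,
               row.names = NULL, stringsAsFactors = FALSE)
  })
}

check_beta_params <- function(params, n_features = NULL) {
  if (!is.data.frame(params) || !all(c("a", "b") %in% names(params))) {
    stop_depfdr("beta parameters must be a data.frame with columns a and b",
                "depfdr_config_error")
  }
  if (any(!is.finite(params$a)) || any(!is.finite(params$b)) ||
      any(params$a <= 0) || any(params$b <= 0)) {
    stop_depfdr("beta shape parameters must be finite and positive",
                "depfdr_config_error")
  }
  if (!is.null(n_features) && nrow(params) != n_features) {
    stop_depfdr(sprintf("expected %d beta parameter pairs, got %d",
                        n_features, nrow(params)),
                "depfdr_shape_error")
  }
  invisible(params)
}

#' Simulate independent beta-marginal features
#'
#' Each feature is an i.i.d. draw from its own Beta(a, b); there is no
#' dependence between features. This is the no-dependence comparator for the
#' copula-based correlated generator.
#'
#' @param n_obs Number of observations (columns).
#' @param params data.frame of beta shapes as from [estimate_beta_params()]
#'   or [sample_methylation_params()].
#' @param seed Integer seed; the draw is a pure function of its arguments.
#' @return A beta-scale [feature_matrix], `nrow(params)` x `n_obs`.
#' @export
simulate_independent_beta <- function(n_obs, params, seed) {
  check_beta_params(params)
  stopifnot(n_obs >= 1)
  m <- nrow(params)
  vals <- with_seed(seed, {
    matrix(stats::rbeta(m * n_obs, shape1 = rep(params$a, n_obs),
                        shape2 = rep(params$b, n_obs)),
           nrow = m, ncol = n_obs)
  })
  # guard against numerically exact 0/1 from extreme shapes
  eps <- 1e-12
  vals[vals <= 0] <- eps
  vals[vals >= 1] <- 1 - eps
  ids <- params$feature_id %||% paste0("f", seq_len(m))
  feature_matrix(vals, scale = "beta", feature_ids = ids)
}
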