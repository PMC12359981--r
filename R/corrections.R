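#' Multiple-testing adjustment
#'
#' Adjusted p-values and rejection sets for the nine closed-form FWER/FDR
#' procedures compared in this package (the tenth, permutation-resampling
#' FDR, lives in [resampling_fdr()]):
#'
#' * `bonferroni` — \eqn{\min(1, m p)}.
#' * `sidak` — \eqn{1 - (1 - p)^m}.
#' * `holm` — step-down, \eqn{\min(1, (m - i + 1) p_{(i)})} with running
#'   maximum in sort order.
#' * `holm_sidak` — step-down with the Sidak factor
#'   \eqn{1 - (1 - p_{(i)})^{m-i+1}}.
#' * `simes_hochberg` — Hochberg's step-up, \eqn{(m - i + 1) p_{(i)}} with
#'   running minimum from the largest p downward.
#' * `bh` — Benjamini-Hochberg step-up, \eqn{\min_{k \ge i} m p_{(k)} / k}.
#' * `by` — Benjamini-Yekutieli: BH multiplied by
#'   \eqn{c(m) = \sum_{i=1}^m 1/i}, capped at 1.
#' * `ts_bh` — two-stage adaptive BH: a first BH pass at level q estimates
#'   \eqn{\hat m_0 = m - R_1}; adjusted values are BH times
#'   \eqn{\hat m_0 / m}.
#' * `ts_bky` — Benjamini-Krieger-Yekutieli two-stage: stage 1 is BH at
#'   \eqn{q' = q/(1+q)} giving \eqn{\hat m_0 = m - R_1} (if \eqn{R_1 = 0}
#'   nothing is rejected; if \eqn{\hat m_0 = 0} everything is); stage 2 is
#'   BH at level \eqn{q' m / \hat m_0}. Adjusted values are BH times
#'   \eqn{\hat m_0 (1 + q) / m}, so `rejected == (adjusted <= q)` holds for
#'   every method.
#'
#' Bonferroni, Holm, Simes-Hochberg, BH and BY delegate to
#' [stats::p.adjust()]; the remainder are implemented here.
#'
#' @param raw Numeric vector of p-values in `[0, 1]`.
#' @param method One of the method names above (or `"resampling"`, which
#'   signals to use [resampling_fdr()]).
#' @param q Nominal level in (0, 1); default 0.05. Enters the adjusted
#'   values only for the adaptive (`ts_*`) methods.
#' @return An `adjusted_pvalues` object: list with `raw`, `adjusted`,
#'   `rejected`, `method`, `q`.
#' @export
#' @examples
#' adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh", q = 0.05)$adjusted
adjust_pvalues <- function(raw, method, q = 0.05) {
  method <- match.arg(method, fdr_methods())
  if (method == "resampling") {
    stop_depfdr("use resampling_fdr() for the permutation-resampling method",
                "depfdr_config_error")
  }
  check_pvalues(raw)
  if (length(q) != 1L || !is.finite(q) || q <= 0 || q >= 1) {
    stop_depfdr("q must lie in (0, 1)", "depfdr_config_error")
  }
  m <- length(raw)
  adjusted <- switch(method,
    bonferroni = stats::p.adjust(raw, "bonferroni"),
    sidak = 1 - (1 - raw)^m,
    holm = stats::p.adjust(raw, "holm"),
    holm_sidak = holm_sidak_adjust(raw),
    simes_hochberg = stats::p.adjust(raw, "hochberg"),
    bh = stats::p.adjust(raw, "BH"),
    by = stats::p.adjust(raw, "BY"),
    ts_bh = ts_bh_adjust(raw, q),
    ts_bky = ts_bky_adjust(raw, q))
  new_adjusted_pvalues(raw, adjusted, adjusted <= q, method, q)
}

#' @rdname adjust_pvalues
#' @export
fdr_methods <- function() {
  c("bonferroni", "sidak", "holm", "holm_sidak", "simes_hochberg",
    "bh", "by", "ts_bh", "ts_bky", "resampling")
}

new_adjusted_pvalues <- function(raw, adjusted, rejected, method, q) {
  structure(list(raw = raw, adjusted = pmin(pmax(adjusted, 0), 1),
                 rejected = rejected, method = method, q = q),
            class = "adjusted_pvalues")
}

#' @export
print.adjusted_pvalues <- function(x, ...) {
  cat(sprintf("<adjusted_pvalues> %s at q = %g: %d of %d rejected\n",
              x$method, x$q, sum(x$rejected), length(x$raw)))
  invisible(x)
}

check_pvalues <- function(p) {
  if (length(p) < 1L || any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop_depfdr("p-values must be finite and in [0, 1]", "depfdr_domain_error")
  }
  invisible(p)
}

holm_sidak_adjust <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

ts_bh_adjust <- function(p, q) {
  m <- length(p)
  bh <- stats::p.adjust(p, "BH")
  m0 <- m - sum(bh <= q)
  if (m0 == 0L) return(numeric(m))   # all rejected
  pmin(1, bh * m0 / m)
}

ts_bky_adjust <- function(p, q) {
  m <- length(p)
  bh <- stats::p.adjust(p, "BH")
  r1 <- sum(bh <= q / (1 + q))
  m0 <- m - r1
  if (m0 == 0L) return(numeric(m))   # stage 1 rejected everything
  pmin(1, bh * m0 * (1 + q) / m)
}

#' Permutation null ensemble of p-values
#'
#' Re-runs a feature-wise test under `B` label permutations, giving a
#' `B x m` matrix of null p-values used by the resampling FDR estimator and
#' the negative-control diagnostic. Permutation b uses the label shuffle
#' seeded by `derive_seed(seed, b)`, so the ensemble is reproducible and
#' individual rows can be regenerated.
#'
#' @param matrix A [feature_matrix].
#' @param labels Two-group vector.
#' @param test Test name as in [run_feature_test()].
#' @param B Number of permutations (>= 1).
#' @param seed Integer master seed for the shuffles.
#' @return A `B x m` numeric matrix of class `null_pvalue_ensemble`.
#' @export
build_null_ensemble <- function(matrix, labels, test = "t_equal_var",
                                B = 1000L, seed = 1L) {
  B <- as.integer(B)
  if (is.na(B) || B < 1L) {
    stop_depfdr("B must be a positive integer", "depfdr_config_error")
  }
  labels <- check_two_groups(labels, ncol(matrix))
  ens <- matrix(NA_real_, nrow = B, ncol = nrow(matrix))
  for (b in seq_len(B)) {
    perm <- shuffle_labels(labels, derive_seed(seed, b))
    ens[b, ] <- run_feature_test(matrix, perm, test)$p_value
  }
  class(ens) <- c("null_pvalue_ensemble", class(ens))
  ens
}

#' Permutation-resampling FDR estimator
#'
#' For each candidate threshold t among the sorted observed p-values, the
#' number of discoveries is \eqn{R(t) = \#\{p_i \le t\}} and the expected
#' number of null discoveries is estimated from the permutation ensemble as
#' \eqn{\hat V(t) = B^{-1} \sum_b \#\{p^{(b)}_j \le t\}}. The estimated FDR
#' curve \eqn{\hat{FDR}(t) = \hat V(t) / \max(R(t), 1)} is regularised to be
#' non-decreasing in t by a cumulative minimum taken from the largest
#' threshold downward (so \eqn{g(t) = \min_{t' \ge t} \hat{FDR}(t')}), the
#' rejection threshold is the largest t with \eqn{g(t) \le q}, and each
#' feature's adjusted value is \eqn{g(p_i)}. This is the plug-in point
#' estimate in the spirit of resampling-based FDR control, not the full
#' conservative upper-bound construction.
#'
#' @param raw Observed p-values (length m).
#' @param ensemble A `B x m` matrix from [build_null_ensemble()] (any
#'   `B x m` numeric matrix of null p-values is accepted).
#' @param q Nominal FDR level.
#' @return An `adjusted_pvalues` object with `method = "resampling"`.
#' @export
resampling_fdr <- function(raw, ensemble, q = 0.05) {
  check_pvalues(raw)
  if (is.null(dim(ensemble)) || nrow(ensemble) < 1L) {
    stop_depfdr("ensemble must be a B x m matrix with B >= 1",
                "depfdr_config_error")
  }
  if (ncol(ensemble) != length(raw)) {
    stop_depfdr("ensemble column count must match length(raw)",
                "depfdr_shape_error")
  }
  B <- nrow(ensemble)
  thresholds <- sort(unique(raw))
  r_at <- findInterval(thresholds, sort(raw))
  ens_sorted <- sort(as.numeric(ensemble))
  v_at <- findInterval(thresholds, ens_sorted) / B
  fdr_hat <- v_at / pmax(r_at, 1)
  g <- rev(cummin(rev(fdr_hat)))          # monotone non-decreasing in t
  g <- pmin(g, 1)
  adjusted <- g[match(raw, thresholds)]
  new_adjusted_pvalues(raw, adjusted, adjusted <= q, "resampling", q)
}
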