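#' Score one dataset's rejections against the truth
#'
#' Counts rejections R, false rejections V, and derives the per-dataset
#' error rates: the false positive ratio FPR = V / #true nulls, the true
#' positive ratio TPR = true rejections / #non-nulls (NA when no non-nulls
#' exist), and the false discovery proportion FDP = V / max(R, 1) — the
#' max(R, 1) convention makes FDP 0, not undefined, when nothing is
#' rejected. In all-null settings every rejection is false, so any dataset
#' with R > 0 has FDP exactly 1.
#'
#' @param adj An `adjusted_pvalues` object (or a logical rejection vector).
#' @param truth Logical vector `is_non_null` per feature, or a truth list as
#'   returned by [inject_effect()]; `NULL` means all nulls.
#' @return A one-row data.frame: `n_rejected`, `n_false`, `fpr`, `tpr`,
#'   `fdp`.
#' @export
#' @examples
#' adj <- adjust_pvalues(runif(100), "bh")
#' score_run(adj, truth = NULL)
score_run <- function(adj, truth = NULL) {
  rejected <- if (inherits(adj, "adjusted_pvalues")) adj$rejected else adj
  if (!is.logical(rejected)) {
    stop_depfdr("adj must be adjusted_pvalues or a logical vector",
                "depfdr_shape_error")
  }
  m <- length(rejected)
  is_non_null <- truth_mask(truth, m)
  R <- sum(rejected)
  V <- sum(rejected & !is_non_null)
  n_null <- sum(!is_non_null)
  n_alt <- m - n_null
  data.frame(
    n_rejected = R,
    n_false = V,
    fpr = if (n_null > 0) V / n_null else NA_real_,
    tpr = if (n_alt > 0) sum(rejected & is_non_null) / n_alt else NA_real_,
    fdp = V / max(R, 1)
  )
}

truth_mask <- function(truth, m) {
  if (is.null(truth)) return(logical(m))
  if (is.list(truth) && !is.null(truth$is_non_null)) truth <- truth$is_non_null
  if (!is.logical(truth) || length(truth) != m) {
    stop_depfdr("truth mask length must match the number of features",
                "depfdr_shape_error")
  }
  truth
}

#' Aggregate per-dataset metrics across replicates
#'
#' The empirical FDR is the mean FDP across replicates; the zero-discovery
#' proportion is the fraction of replicates with no rejections; the
#' rejection variance is the sample variance of the rejection count. TPR is
#' averaged only over replicates that contain at least one non-null (the
#' others carry `tpr = NA`).
#'
#' @param runs A data.frame of per-replicate rows as from [score_run()]
#'   (row-bound), or a list of such rows.
#' @return A one-row data.frame: `n_runs`, `fdr`, `zero_discovery_prop`,
#'   `rejection_variance`, `mean_fpr`, `mean_tpr`, `mean_rejected`.
#' @export
aggregate_runs <- function(runs) {
  if (is.list(runs) && !is.data.frame(runs)) runs <- do.call(rbind, runs)
  if (!is.data.frame(runs) || nrow(runs) == 0L) {
    stop_depfdr("runs must be a non-empty metrics table", "depfdr_empty_error")
  }
  data.frame(
    n_runs = nrow(runs),
    fdr = mean(runs$fdp),
    zero_discovery_prop = mean(runs$n_rejected == 0),
    rejection_variance = if (nrow(runs) > 1L) stats::var(runs$n_rejected) else 0,
    mean_fpr = mean(runs$fpr, na.rm = TRUE),
    mean_tpr = if (all(is.na(runs$tpr))) NA_real_ else mean(runs$tpr, na.rm = TRUE),
    mean_rejected = mean(runs$n_rejected)
  )
}

#' Correlation-ECDF diagnostic for a hit set
#'
#' Compares the distribution of pairwise Pearson correlations among the
#' significant ("hit") features with that of randomly drawn feature sets of
#' the same size from the same matrix. If hits are mutually far more
#' correlated than random sets, a mass discovery is consistent with a
#' dependence-driven false-positive event rather than distributed signal.
#' No hypothesis test is attached; the output is a long-format ECDF table
#' meant for plotting or tabular comparison.
#'
#' @param matrix A [feature_matrix].
#' @param hit_ids Feature ids (or integer indices) of the hits; at least 2.
#' @param n_random_sets Number of random comparison sets (default 5).
#' @param seed Integer seed for the random sets.
#' @return A data.frame with columns `set` (`"hits"` or `"random<k>"`),
#'   `correlation` (sorted upper-triangle values) and `cum_fraction`, or
#'   `NULL` (with a warning) when fewer than 2 hits make the diagnostic
#'   undefined.
#' @export
correlation_ecdf <- function(matrix, hit_ids, n_random_sets = 5L, seed = 1L) {
  idx <- if (is.character(hit_ids)) match(hit_ids, rownames(matrix)) else as.integer(hit_ids)
  if (any(is.na(idx)) || any(idx < 1L) || any(idx > nrow(matrix))) {
    stop_depfdr("hit_ids do not match the matrix features", "depfdr_shape_error")
  }
  idx <- unique(idx)
  if (length(idx) < 2L) {
    warning("fewer than 2 hit features; correlation diagnostic undefined")
    return(NULL)
  }
  one_set <- function(rows, label) {
    cc <- stats::cor(t(unclass(matrix)[rows, , drop = FALSE]))
    vals <- sort(cc[upper.tri(cc)])
    data.frame(set = label, correlation = vals,
               cum_fraction = seq_along(vals) / length(vals))
  }
  out <- one_set(idx, "hits")
  rand <- with_seed(seed, {
    lapply(seq_len(n_random_sets), function(k) {
      one_set(sample.int(nrow(matrix), length(idx)), paste0("random", k))
    })
  })
  rbind(out, do.call(rbind, rand))
}

#' Negative-control distribution of significant-hit counts
#'
#' Repeatedly permutes the group labels (enforcing the global null), reruns
#' the test-plus-correction pipeline, and records the number of rejections
#' per shuffle. The resulting distribution shows how many "significant"
#' findings arise with no true signal given this dataset's dependence
#' structure; the quantile of an observed hit count within it is the
#' negative-control calibration check.
#'
#' @param matrix A [feature_matrix].
#' @param labels Two-group vector.
#' @param test Test name as in [run_feature_test()].
#' @param method Correction method name as in [adjust_pvalues()].
#' @param q Nominal level.
#' @param n_shuffles Number of label permutations.
#' @param seed Integer seed.
#' @param observed_R Optional observed rejection count to place within the
#'   null distribution.
#' @return A list with `counts` (integer vector of length `n_shuffles`) and
#'   `observed_quantile` (fraction of shuffles with counts strictly below
#'   `observed_R`; `NA` if not supplied).
#' @export
negative_control_null <- function(matrix, labels, test = "t_equal_var",
                                  method = "bh", q = 0.05,
                                  n_shuffles = 100L, seed = 1L,
                                  observed_R = NULL) {
  labels <- check_two_groups(labels, ncol(matrix))
  counts <- integer(n_shuffles)
  for (s in seq_len(n_shuffles)) {
    perm <- shuffle_labels(labels, derive_seed(seed, s))
    p <- run_feature_test(matrix, perm, test)$p_value
    counts[s] <- sum(adjust_pvalues(p, method, q)$rejected)
  }
  list(counts = counts,
       observed_quantile = if (is.null(observed_R)) NA_real_ else
         mean(counts < observed_R))
}
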