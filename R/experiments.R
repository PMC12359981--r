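#' Experiment specification
#'
#' Bundles everything one simulation arm needs: replication, dataset shape,
#' marginal family, dependence structure, the feature-wise test, the
#' correction methods and nominal levels, and an optional injected effect.
#' Per-replicate seeds are derived from `master_seed` with the counter-based
#' scheme of [derive_seed()], so any replicate can be regenerated in
#' isolation and replicates may run in any order or in parallel.
#'
#' @param n_replicates Number of simulated datasets (>= 1).
#' @param n_obs Observations per dataset.
#' @param n_features Features per dataset.
#' @param marginal `"beta"` (methylation-like, tested on the M scale) or
#'   `"normal"`.
#' @param dependence A [dependence_config()] or `NULL` for independent
#'   features.
#' @param test Test name as in [run_feature_test()].
#' @param methods Character vector of correction methods
#'   (see [fdr_methods()]; `"resampling"` is not valid here — it needs a
#'   permutation ensemble and lives in [reproduce_panel()]).
#' @param q_levels Nominal levels; default `c(0.01, 0.05, 0.10)`.
#' @param effect `NULL`, or a list with elements `fraction`,
#'   `eligible_mean_range`, `shift` passed to [inject_effect()].
#' @param beta_params Optional beta shapes (data.frame with `a`, `b`); by
#'   default methylation-like shapes are drawn once per experiment from the
#'   master seed and shared by all replicates, like a fixed reference panel.
#' @param master_seed Integer master seed (required).
#' @return A list of class `experiment_spec`.
#' @export
experiment_spec <- function(n_replicates, n_obs, n_features,
                            marginal = c("beta", "normal"),
                            dependence = NULL,
                            test = "t_equal_var",
                            methods = "bh",
                            q_levels = c(0.01, 0.05, 0.10),
                            effect = NULL,
                            beta_params = NULL,
                            master_seed) {
  marginal <- match.arg(marginal)
  if (missing(master_seed)) {
    stop_depfdr("experiments require an explicit master_seed",
                "depfdr_config_error")
  }
  stopifnot(n_replicates >= 1, n_obs >= 4, n_features >= 1)
  methods <- vapply(methods, function(m) match.arg(m, fdr_methods()), "")
  if ("resampling" %in% methods) {
    stop_depfdr("resampling FDR needs a permutation ensemble; use reproduce_panel()",
                "depfdr_config_error")
  }
  if (!is.null(dependence) && !inherits(dependence, "dependence_config")) {
    stop_depfdr("dependence must be a dependence_config or NULL",
                "depfdr_config_error")
  }
  structure(list(n_replicates = as.integer(n_replicates),
                 n_obs = as.integer(n_obs),
                 n_features = as.integer(n_features),
                 marginal = marginal, dependence = dependence, test = test,
                 methods = unname(methods), q_levels = q_levels,
                 effect = effect, beta_params = beta_params,
                 master_seed = as.integer(master_seed)),
            class = "experiment_spec")
}

# Fill in the per-experiment beta parameters (drawn once, deterministically
# from the master seed, in the plasmode spirit of a fixed reference panel)
# and precompute the copula quantile maps shared by all replicates.
resolve_spec <- function(spec) {
  if (spec$marginal != "beta" || isTRUE(attr(spec, "resolved"))) return(spec)
  if (is.null(spec$beta_params)) {
    spec$beta_params <- sample_methylation_params(
      spec$n_features, seed = derive_seed(spec$master_seed, 0L))
  }
  check_beta_params(spec$beta_params, spec$n_features)
  if (!is.null(spec$dependence)) {
    attr(spec, "maps") <- beta_quantile_maps(spec$beta_params)
  }
  attr(spec, "resolved") <- TRUE
  spec
}

#' Regenerate a single replicate's dataset
#'
#' Returns exactly the dataset (matrix on its testing scale, group labels,
#' truth mask) that [run_experiment()] used for the given replicate index —
#' the counter-based seed derivation makes every replicate reconstructible
#' in isolation, e.g. to run diagnostics on one interesting dataset.
#'
#' @param spec An [experiment_spec()].
#' @param replicate Replicate index (1-based).
#' @return A list with `matrix`, `labels`, `truth` (`NULL` when all nulls)
#'   and the replicate `seed`.
#' @export
simulate_replicate <- function(spec, replicate) {
  spec <- resolve_spec(spec)
  seed <- derive_seed(spec$master_seed, replicate)
  labels <- random_group_labels(spec$n_obs, derive_seed(seed, 1L))
  if (spec$marginal == "normal") {
    fm <- simulate_mvn(spec$n_obs, spec$n_features, spec$dependence,
                       seed = derive_seed(seed, 2L))
  } else {
    params <- spec$beta_params
    if (is.null(spec$dependence)) {
      fm <- simulate_independent_beta(spec$n_obs, params,
                                      seed = derive_seed(seed, 2L))
    } else {
      g <- simulate_correlated_gaussian(spec$n_obs, spec$n_features,
                                        spec$dependence,
                                        seed = derive_seed(seed, 2L))
      fm <- gaussian_to_beta(g, params, maps = attr(spec, "maps"))
    }
    fm <- beta_to_m(fm)
  }
  truth <- NULL
  if (!is.null(spec$effect)) {
    inj <- inject_effect(fm, labels,
                         fraction = spec$effect$fraction %||% 0.015,
                         eligible_mean_range = spec$effect$eligible_mean_range %||% c(2, 2.5),
                         shift = spec$effect$shift %||% 1,
                         seed = derive_seed(seed, 4L))
    fm <- inj$matrix
    truth <- inj$truth
  }
  list(matrix = fm, labels = labels, truth = truth, seed = seed)
}

#' Run a simulation experiment
#'
#' Executes `spec$n_replicates` independent simulate - test - adjust - score
#' pipelines and returns a long-format metrics table with one row per
#' (replicate, method, q). A replicate whose pipeline errors is logged and
#' counted; if more than 1% of replicates fail the experiment aborts.
#'
#' @param spec An [experiment_spec()].
#' @param raw_alpha Optional numeric vector of raw (unadjusted) thresholds
#'   to score alongside the correction methods, reported as method
#'   `"raw"`.
#' @param verbose Print a progress line every 200 replicates.
#' @return A data.frame with columns `replicate`, `seed`, `method`, `q`,
#'   `n_rejected`, `n_false`, `fpr`, `tpr`, `fdp`.
#' @export
#' @examples
#' spec <- experiment_spec(5, 20, 100, marginal = "normal",
#'                         methods = "bh", q_levels = 0.05, master_seed = 7)
#' run_experiment(spec)
run_experiment <- function(spec, raw_alpha = NULL, verbose = FALSE) {
  stopifnot(inherits(spec, "experiment_spec"))
  spec <- resolve_spec(spec)
  rows <- vector("list", spec$n_replicates)
  n_failed <- 0L
  for (i in seq_len(spec$n_replicates)) {
    res <- tryCatch(run_one_replicate(spec, i, raw_alpha),
                    error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
      warning(sprintf("replicate %d failed: %s", i, conditionMessage(res)))
      if (n_failed > max(1L, ceiling(0.01 * spec$n_replicates))) {
        stop_depfdr("more than 1% of replicates failed; aborting experiment",
                    "depfdr_experiment_error")
      }
      next
    }
    rows[[i]] <- res
    if (verbose && i %% 200L == 0L) {
      message(sprintf("  replicate %d / %d", i, spec$n_replicates))
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

run_one_replicate <- function(spec, i, raw_alpha = NULL) {
  dat <- simulate_replicate(spec, i)
  tr <- run_feature_test(dat$matrix, dat$labels, spec$test)
  grid <- expand.grid(method = spec$methods, q = spec$q_levels,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    adj <- adjust_pvalues(tr$p_value, grid$method[k], grid$q[k])
    cbind(data.frame(replicate = i, seed = dat$seed,
                     method = grid$method[k], q = grid$q[k]),
          score_run(adj, dat$truth))
  })
  if (!is.null(raw_alpha)) {
    raw_rows <- lapply(raw_alpha, function(a) {
      cbind(data.frame(replicate = i, seed = dat$seed, method = "raw", q = a),
            score_run(tr$p_value <= a, dat$truth))
    })
    rows <- c(rows, raw_rows)
  }
  do.call(rbind, rows)
}

#' Reproduce the study's headline panels at configurable scale
#'
#' * `null_design_grid`: the all-null design grid — for each combination of a
#'   varied axis (dependence on/off by default) the full
#'   simulate/test/adjust/score pipeline is run and aggregated.
#' * `method_comparison`: from an all-null BH run, selects all
#'   replicates with FPR > 0.05 ("elevated") plus a random subset of 100
#'   with controlled FPR, re-simulates those exact datasets, injects
#'   effects, and evaluates all ten procedures (including resampling FDR
#'   with `B` permutations) on each.
#'
#' @param panel `"null_design_grid"` or `"method_comparison"`.
#' @param scale Multiplier in (0, 1] applied to the replication and, for
#'   the method comparison, the permutation count `B` (floor at 50).
#' @param master_seed Integer master seed.
#' @param n_replicates,n_obs,n_features Base design shape before scaling.
#' @param B Base permutation count for the resampling method.
#' @param q Nominal level for the method comparison.
#' @return For `null_design_grid`, an aggregated data.frame (one row per setting x
#'   method x q). For `method_comparison`, a list with the per-dataset
#'   long table (`metrics`), the stratum sizes, and the selection rule's
#'   threshold.
#' @export
reproduce_panel <- function(panel = c("null_design_grid", "method_comparison"),
                            scale = 1, master_seed,
                            n_replicates = 1000L, n_obs = 100L,
                            n_features = 2000L, B = 1000L, q = 0.05) {
  panel <- match.arg(panel)
  stopifnot(scale > 0, scale <= 1)
  n_rep <- max(2L, as.integer(floor(n_replicates * scale)))
  if (panel == "null_design_grid") {
    settings <- list(
      dependent   = dependence_config(),
      independent = NULL
    )
    out <- lapply(names(settings), function(nm) {
      spec <- experiment_spec(n_rep, n_obs, n_features, marginal = "beta",
                              dependence = settings[[nm]],
                              methods = c("bh", "bonferroni"),
                              q_levels = c(0.01, 0.05, 0.10),
                              master_seed = derive_seed(master_seed,
                                                        match(nm, names(settings))))
      tab <- run_experiment(spec)
      parts <- split(tab, paste(tab$method, tab$q, sep = "|"))
      agg <- do.call(rbind, lapply(parts, aggregate_runs))
      key <- do.call(rbind, strsplit(names(parts), "|", fixed = TRUE))
      cbind(data.frame(setting = nm, method = key[, 1],
                       q = as.numeric(key[, 2])), agg)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    return(out)
  }

  # method_comparison
  B_eff <- max(50L, as.integer(floor(B * scale)))
  base_spec <- experiment_spec(n_rep, n_obs, n_features, marginal = "beta",
                               dependence = dependence_config(),
                               methods = "bh", q_levels = q,
                               master_seed = master_seed)
  screen <- run_experiment(base_spec)
  elevated <- screen$replicate[screen$fpr > 0.05]
  controlled_pool <- screen$replicate[screen$fpr <= 0.05]
  n_ctrl <- min(100L, length(controlled_pool))
  controlled <- with_seed(derive_seed(master_seed, 999L),
                          sample(controlled_pool, n_ctrl))
  chosen <- c(elevated, controlled)
  strata <- rep(c("elevated", "controlled"),
                c(length(elevated), length(controlled)))
  eff_spec <- base_spec
  eff_spec$effect <- list(fraction = 0.015,
                          eligible_mean_range = c(2, 2.5), shift = 1)
  eff_spec <- resolve_spec(eff_spec)
  closed_form <- setdiff(fdr_methods(), "resampling")
  rows <- vector("list", length(chosen))
  for (k in seq_along(chosen)) {
    i <- chosen[k]
    dat <- simulate_replicate(eff_spec, i)
    tr <- run_feature_test(dat$matrix, dat$labels, eff_spec$test)
    ens <- build_null_ensemble(dat$matrix, dat$labels, eff_spec$test,
                               B = B_eff, seed = derive_seed(dat$seed, 5L))
    adjs <- c(lapply(closed_form, function(m) adjust_pvalues(tr$p_value, m, q)),
              list(resampling_fdr(tr$p_value, ens, q)))
    rows[[k]] <- do.call(rbind, lapply(adjs, function(a) {
      cbind(data.frame(replicate = i, stratum = strata[k],
                       method = a$method, q = q),
            score_run(a, dat$truth))
    }))
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  list(metrics = metrics,
       n_elevated = length(elevated), n_controlled = length(controlled),
       selection_threshold = 0.05, B = B_eff)
}
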