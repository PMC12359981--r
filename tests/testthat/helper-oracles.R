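# Brute-force sequential definitions of the step procedures, written
# directly from their textbook rejection rules. Deliberately independent of
# the package's adjusted-p-value implementations: these loop over sorted
# p-values and apply each threshold comparison literally.

brute_reject <- function(p, method, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  rej_sorted <- switch(method,
    bonferroni = ps <= q / m,
    sidak = ps <= 1 - (1 - q)^(1 / m),
    holm = {
      r <- logical(m)
      for (i in seq_len(m)) {
        if (ps[i] > q / (m - i + 1)) break
        r[i] <- TRUE
      }
      r
    },
    holm_sidak = {
      r <- logical(m)
      for (i in seq_len(m)) {
        if (ps[i] > 1 - (1 - q)^(1 / (m - i + 1))) break
        r[i] <- TRUE
      }
      r
    },
    simes_hochberg = {
      k <- 0L
      for (i in m:1) if (ps[i] <= q / (m - i + 1)) { k <- i; break }
      seq_len(m) <= k
    },
    bh = brute_bh_sorted(ps, q, m),
    by = brute_bh_sorted(ps, q / sum(1 / seq_len(m)), m),
    ts_bh = {
      r1 <- sum(brute_bh_sorted(ps, q, m))
      m0 <- m - r1
      if (m0 == 0L) rep(TRUE, m) else {
        k <- 0L
        for (i in m:1) if (ps[i] <= q * i / m0) { k <- i; break }
        seq_len(m) <= k
      }
    },
    ts_bky = {
      q1 <- q / (1 + q)
      r1 <- sum(brute_bh_sorted(ps, q1, m))
      m0 <- m - r1
      if (r1 == 0L) rep(FALSE, m)
      else if (m0 == 0L) rep(TRUE, m)
      else brute_bh_sorted(ps, q1 * m / m0, m)
    },
    stop("unknown method"))
  out <- logical(m)
  out[o] <- rej_sorted
  out
}

brute_bh_sorted <- function(ps, level, m) {
  k <- 0L
  for (i in m:1) if (ps[i] <= level * i / m) { k <- i; break }
  seq_len(m) <= k
}

# direct enumeration of the step-up minimisation for BH adjusted values
brute_bh_adjust <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# brute-force resampling-FDR curve: double loop over thresholds
brute_resampling_reject <- function(raw, ensemble, q) {
  thresholds <- sort(unique(raw))
  fdr_hat <- vapply(thresholds, function(t) {
    R <- sum(raw <= t)
    V <- mean(apply(ensemble, 1, function(row) sum(row <= t)))
    V / max(R, 1)
  }, numeric(1))
  g <- vapply(seq_along(thresholds), function(i) min(fdr_hat[i:length(fdr_hat)]),
              numeric(1))
  ok <- which(g <= q)
  if (!length(ok)) return(rep(FALSE, length(raw)))
  raw <= thresholds[max(ok)]
}

# small all-null beta-marginal dataset on the M scale, for test reuse
make_null_m_dataset <- function(n_obs, n_features, dependence = NULL, seed = 1) {
  params <- sample_methylation_params(n_features, seed = seed + 1)
  fm <- if (is.null(dependence)) {
    simulate_independent_beta(n_obs, params, seed = seed)
  } else {
    gaussian_to_beta(
      simulate_correlated_gaussian(n_obs, n_features, dependence, seed = seed),
      params)
  }
  beta_to_m(fm)
}
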