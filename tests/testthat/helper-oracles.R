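# Independent oracles used across tests. These deliberately avoid the code
# paths they check: BH by literal step-up, Fisher by lchoose enumeration,
# the F density written out from the beta-function form.

# Brute-force Benjamini-Hochberg step-up: q(i) = min_{j>=i} p(j)*m/j on the
# sorted list, capped at 1, mapped back to input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Two-tailed Fisher p by full-table enumeration with explicit binomial
# coefficients (minimum-likelihood convention, 1e-7 relative tie guard).
fisher_oracle <- function(k, n, K, N) {
  lo <- max(0, n + K - N); hi <- min(n, K)
  ks <- lo:hi
  logd <- lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)
  d <- exp(logd)
  obs <- d[k - lo + 1]
  min(1, sum(d[d <= obs * (1 + 1e-7)]))
}

# log F density from the beta-function form (independent of stats::df)
log_df_oracle <- function(x, d1, d2) {
  (d1 / 2) * log(d1 / d2) + (d1 / 2 - 1) * log(x) -
    ((d1 + d2) / 2) * log(1 + d1 * x / d2) - lbeta(d1 / 2, d2 / 2)
}

# RVM marginal log-likelihood written out independently
rvm_loglik_oracle <- function(a, b, s2, d) {
  sum(log(a * b) + log_df_oracle(a * b * s2, d, 2 * a))
}

# Direct-formula Pearson r
pearson_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Small cohort defaults used where full array scale is unnecessary
small_config <- function(seed, ...) {
  args <- list(...)
  defaults <- list(n_case = 12, n_control = 6, n_mirna = 300, n_mrna = 1500,
                   n_true_pairs = 20, repression_slope = -1, noise_sd = 0.3,
                   seed = seed)
  do.call(simulation_config, utils::modifyList(defaults, args))
}

pair_keys <- function(df) paste(df$mirna, df$gene, sep = "\r")
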