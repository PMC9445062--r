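# Independent brute-force oracles used to cross-check the package's own
# implementations. Everything here is deliberately written in the most
# literal way possible, with no shared code paths with the package.

# Benjamini-Hochberg step-up by its definition: find the largest k with
# p_(k) <= k * alpha / m and reject the k smallest p-values.
bh_oracle_reject <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0L
  for (i in seq_len(m)) if (ps[i] <= i * alpha / m) k <- i
  reject <- logical(m)
  if (k > 0) reject[o[seq_len(k)]] <- TRUE
  reject
}

# Weighted Harrell concordance by the pair definition: i has an event at
# t_i, j is comparable when t_j > t_i, or t_j == t_i with j censored.
# Pair weight w_i * w_j; predictor ties score 1/2.
harrell_oracle <- function(time, event, score, w = rep(1, length(time))) {
  num <- 0
  den <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    if (event[i] != 1) next
    for (j in seq_len(n)) {
      if (j == i) next
      comparable <- time[j] > time[i] ||
        (time[j] == time[i] && event[j] == 0)
      if (!comparable) next
      ww <- w[i] * w[j]
      den <- den + ww
      if (score[i] > score[j]) num <- num + ww
      else if (score[i] == score[j]) num <- num + ww / 2
    }
  }
  num / den
}

# Full-cohort Breslow log partial likelihood written directly from the
# definition, for use with a 1-d grid/golden-section optimizer.
breslow_loglik_oracle <- function(beta, time, event, x) {
  eta <- x * beta
  ll <- 0
  for (i in which(event == 1)) {
    at_risk <- time >= time[i]
    ll <- ll + eta[i] - log(sum(exp(eta[at_risk])))
  }
  ll
}

# A small random survival dataset for estimator cross-checks.
random_survival_data <- function(n, p, tie_rounding = NULL) {
  X <- matrix(stats::rnorm(n * p), n, p)
  colnames(X) <- paste0("x", seq_len(p))
  tm <- stats::rexp(n, 0.1)
  if (!is.null(tie_rounding)) tm <- round(tm, tie_rounding)
  d <- data.frame(id = seq_len(n), time = tm + 0.5,
                  event = stats::rbinom(n, 1, 0.4))
  cbind(d, as.data.frame(X))
}

# A minimal measured-only panel of m markers for generator-based studies.
toy_panel <- function(m, prefix = "M") {
  build_panel(data.frame(
    name = sprintf("%s%02d", prefix, seq_len(m)),
    class = "amino_acid", is_ratio = FALSE,
    numerator = NA_character_, denominator = NA_character_,
    stringsAsFactors = FALSE))
}
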