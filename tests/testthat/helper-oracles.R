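# Independent oracles and small shared fixtures.

# Brute-force two-group log-rank statistic: O - E and hypergeometric
# variance accumulated over the pooled distinct event times.
brute_force_logrank <- function(time, event, group) {
  g <- as.integer(factor(group)) - 1L   # 0/1
  ts <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (tt in ts) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & g == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Cox partial log-likelihood for a single covariate, untied data.
cox_partial_loglik <- function(beta, time, event, x) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Rank-sum (concordance) AUC between case and control marker values,
# ties counted 1/2.
rank_sum_auc <- function(m_case, m_ctrl) {
  s <- 0
  for (a in m_case) s <- s + sum(a > m_ctrl) + 0.5 * sum(a == m_ctrl)
  s / (length(m_case) * length(m_ctrl))
}

# Small-bag cohort builder used by several files.
small_sim_config <- function(seed = 1, ...) {
  slide_sim_config(n_tiles = 8, tile_size = 32, seed = seed, ...)
}

# Heavy shared fixtures (trained models) built once per test run.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}
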