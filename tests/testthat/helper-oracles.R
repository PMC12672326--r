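# Independent oracles and small fixtures shared across test files.

# Closed-form discounted lifetime payoff for a cohort decaying geometrically
# out of a single alive state: survival a_k = q^k, trapezoidal occupancy
# averaging, per-cycle payoff `pay` discounted at factor v per cycle.
# sum_k pay * (q^(k-1) + q^k)/2 * v^k  =  pay * (1+q)/(2q) * sum_k (qv)^k
annuity_oracle <- function(pay, q, v, n) {
  x <- q * v
  pay * (1 + q) / (2 * q) * x * (1 - x^n) / (1 - x)
}

# One-off payoff on the mass dying each cycle, mid-cycle discounting:
# sum_k pay * (q^(k-1) - q^k) * v^(k-1/2)
event_on_deaths_oracle <- function(pay, q, v, n) {
  k <- seq_len(n)
  sum(pay * (q^(k - 1) - q^k) * v^(k - 0.5))
}

# Exhaustive efficiency-frontier oracle: gift-wrap the upper-left hull of
# (qaly, cost) pairs starting from the cheapest strategy, always taking the
# smallest incremental cost per QALY among strictly more effective points.
# Independent of the dominance-iteration algorithm under test.
hull_frontier_oracle <- function(cost, qaly) {
  stopifnot(length(cost) == length(qaly))
  start <- which(cost == min(cost))
  if (length(start) > 1L) start <- start[which.max(qaly[start])]
  path <- start
  repeat {
    cur <- path[length(path)]
    cand <- which(qaly > qaly[cur])
    if (length(cand) == 0L) break
    slopes <- (cost[cand] - cost[cur]) / (qaly[cand] - qaly[cur])
    nxt <- cand[which.min(slopes)]
    path <- c(path, nxt)
  }
  sort(path)
}

# Wrap bare (cost, qaly) numbers as outcome objects for frontier().
as_outcomes <- function(labels, cost, qaly) {
  mapply(function(l, c, q) {
    structure(list(strategy = l, total_cost = c, total_qaly = q,
                   undiscounted_cost = c, undiscounted_qaly = q,
                   cost_breakdown = c(total = c)),
              class = "cua_outcome")
  }, labels, cost, qaly, SIMPLIFY = FALSE)
}

# Externally reported base-case totals (cost USD, QALY) for the ten
# strategies, used as input data for dominance-classification checks.
reported_base_case <- function() {
  path <- system.file("extdata", "published_base_case.csv",
                      package = "pcsk9cua")
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

# A tiny all-zero-mortality parameter set: nothing moves, nothing dies.
frozen_cohort_parameters <- function(horizon = 1, discount = 0) {
  p <- make_test_parameters(difficulty = "degenerate")
  p$life_table <- life_table(40:100, rep(0, 61), rep(0, 61))
  p$settings$horizon <- horizon
  p$settings$discount_rate_costs <- discount
  p$settings$discount_rate_outcomes <- discount
  validate_parameters(p)
}
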