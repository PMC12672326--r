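#' Discount factor for a cycle
#'
#' `(1 + rate)^(-cycle * cycle_length)`, the factor applied to flows accruing
#' in cycle `cycle` under annual discount rate `rate`.
#'
#' @param cycle Cycle index (0 = no discounting).
#' @param rate Annual discount rate (>= 0).
#' @param cycle_length Cycle length in years.
#' @return Discount factor in `(0, 1]`.
#' @export
discount_factor <- function(cycle, rate, cycle_length = 1) {
  if (any(rate < 0)) stop("discount rate must be non-negative")
  (1 + rate)^(-cycle * cycle_length)
}

# Per-state annual cost and utility payoff vectors (canonical state order).
.state_costs <- function(costs) {
  c(0, costs$mi_year1, costs$mi_subsequent_annual,
    costs$mi_year1, costs$mi_subsequent_annual,
    costs$is_year1, costs$is_subsequent_annual,
    costs$is_year1, costs$is_subsequent_annual, 0, 0)
}

.state_utilities <- function(u) {
  c(u$baseline, u$mi_year1, u$mi_post, u$mi2_year1, u$mi2_post,
    u$is_year1, u$is_post, u$is2_year1, u$is2_post, 0, 0)
}

#' Discounted lifetime costs and QALYs for one strategy
#'
#' Accrues, cycle by cycle: state costs (first-year and long-term annual
#' post-event costs for MI and stroke), background statin cost on all alive
#' occupancy in every arm, PCSK9 drug cost (pens x per-pen price x
#' administrations, with the first model year using the loading schedule),
#' the one-off terminal-hospitalization cost on mass newly entering CV
#' death, and revascularization procedure costs on the expected event
#' overlay; and state utilities with the annual injection disutility on
#' alive occupancy in active arms plus the one-cycle revascularization
#' disutility. Continuous state flows use the trapezoidal half-cycle
#' correction (payoffs on the average of start- and end-of-cycle occupancy)
#' and are discounted at `(1 + d)^-k`; one-off event flows are discounted
#' mid-cycle at `(1 + d)^-(k - 1/2)` and receive no further correction.
#'
#' @param trace A `cua_trace` from [run_cohort()].
#' @param params The `cua_parameters` the trace was run under.
#' @param regimen The `cua_regimen` (or its name) the trace belongs to.
#' @return An object of class `cua_outcome`: `strategy`, `total_cost`,
#'   `total_qaly` (discounted), `undiscounted_cost`, `undiscounted_qaly`,
#'   and `cost_breakdown` (components summing to `total_cost`).
#' @export
accumulate_outcomes <- function(trace, params, regimen) {
  if (is.character(regimen)) regimen <- params$regimens[[regimen]]
  s <- params$settings
  n <- as.integer(round(s$horizon / s$cycle_length))
  if (trace$n_cycles != n)
    stop("horizon mismatch: trace has ", trace$n_cycles,
         " cycles, settings imply ", n)
  t_len <- s$cycle_length
  occ <- trace$occupancy
  cvec <- .state_costs(params$costs)
  uvec <- .state_utilities(params$utilities)
  u_inj <- if (regimen$is_injectable) params$utilities$disutility_injection else 0
  u_rv <- params$utilities$disutility_revasc
  drug_annual <- function(k) {
    if (!regimen$is_injectable) return(0)
    adm <- if (k == 1L) regimen$administrations_year1 else regimen$administrations_subsequent
    regimen$pens_per_administration * regimen$price_per_pen * adm
  }

  comp <- c(statin = 0, pcsk9_drug = 0, mi = 0, is = 0,
            revascularization = 0, cv_death = 0)
  qaly <- 0
  u_cost <- 0  # undiscounted accumulators
  u_qaly <- 0
  mi_idx <- c(2L, 3L, 4L, 5L)
  is_idx <- c(6L, 7L, 8L, 9L)

  for (k in seq_len(n)) {
    avg <- if (s$half_cycle_correction) (occ[k, ] + occ[k + 1L, ]) / 2 else occ[k, ]
    alive <- sum(avg[1:9])
    vc <- discount_factor(k, s$discount_rate_costs, t_len)
    ve <- discount_factor(k, s$discount_rate_outcomes, t_len)
    vch <- discount_factor(k - 0.5, s$discount_rate_costs, t_len)
    veh <- discount_factor(k - 0.5, s$discount_rate_outcomes, t_len)

    mi_cost <- sum(avg[mi_idx] * cvec[mi_idx]) * t_len
    is_cost <- sum(avg[is_idx] * cvec[is_idx]) * t_len
    statin <- alive * params$costs$statin_annual * t_len
    drug <- alive * drug_annual(k) * t_len
    new_cvd <- unname(occ[k + 1L, 10L] - occ[k, 10L])
    cvd_cost <- new_cvd * params$costs$cv_death
    rv_cost <- trace$revasc_events[k] * params$costs$revascularization

    comp["mi"] <- comp["mi"] + mi_cost * vc
    comp["is"] <- comp["is"] + is_cost * vc
    comp["statin"] <- comp["statin"] + statin * vc
    comp["pcsk9_drug"] <- comp["pcsk9_drug"] + drug * vc
    comp["cv_death"] <- comp["cv_death"] + cvd_cost * vch
    comp["revascularization"] <- comp["revascularization"] + rv_cost * vch
    u_cost <- u_cost + mi_cost + is_cost + statin + drug + cvd_cost + rv_cost

    q_state <- (sum(avg * uvec) + alive * u_inj) * t_len
    q_rv <- trace$revasc_events[k] * u_rv
    qaly <- qaly + q_state * ve + q_rv * veh
    u_qaly <- u_qaly + q_state + q_rv
  }

  out <- list(strategy = regimen$name,
              total_cost = sum(comp), total_qaly = qaly,
              undiscounted_cost = u_cost, undiscounted_qaly = u_qaly,
              cost_breakdown = comp)
  class(out) <- "cua_outcome"
  out
}

#' Run the full deterministic pipeline for one or all strategies
#'
#' `run_strategy()` runs the cohort trace and accumulates outcomes for one
#' regimen; `run_strategies()` does so for a set of regimens (default: all
#' in the parameter set) and returns the list of `cua_outcome`s.
#'
#' @param params A validated `cua_parameters`.
#' @param regimen A regimen name or `cua_regimen`.
#' @return A `cua_outcome`, or a named list of them.
#' @export
run_strategy <- function(params, regimen) {
  if (is.character(regimen)) regimen <- params$regimens[[regimen]]
  trace <- run_cohort(params, regimen)
  accumulate_outcomes(trace, params, regimen)
}

#' @rdname run_strategy
#' @param strategies Character vector of regimen names.
#' @export
run_strategies <- function(params, strategies = names(params$regimens)) {
  out <- lapply(strategies, function(nm) run_strategy(params, nm))
  names(out) <- strategies
  out
}

#' Incremental cost-utility ratio between two strategies
#'
#' `(cost_b - cost_a) / (qaly_b - qaly_a)` on full-precision outcomes.
#' Strategies with identical QALYs are incomparable by ICUR and raise an
#' error rather than returning an infinity.
#'
#' @param a,b `cua_outcome` objects (b is compared against a).
#' @return ICUR in USD per QALY.
#' @export
icur <- function(a, b) {
  dq <- b$total_qaly - a$total_qaly
  if (dq == 0) stop("strategies '", a$strategy, "' and '", b$strategy,
                    "' have identical QALYs; ICUR undefined")
  (b$total_cost - a$total_cost) / dq
}

#' Dominance classification and cost-effectiveness frontier
#'
#' Orders strategies by cost, marks strict dominance (more costly and no
#' more effective than some alternative), then iteratively removes extended
#' dominance (a strategy whose incremental ICUR exceeds that of the next
#' more effective frontier candidate) until the frontier ICURs are
#' non-decreasing. Also reports every strategy's pairwise ICUR against the
#' reference strategy.
#'
#' @param outcomes List of `cua_outcome` objects (>= 2, unique labels).
#' @param reference Label of the reference strategy (e.g. statins alone).
#' @return An object of class `cua_frontier`: `table` (a `data.frame`
#'   ordered by cost with costs, QALYs, increments vs reference, pairwise
#'   ICUR vs reference, frontier ICUR, and status), `status` (named vector:
#'   `frontier`, `dominated`, or `extended_dominated`), `icur_vs_reference`,
#'   `icur_frontier`, and `reference`.
#' @export
frontier <- function(outcomes, reference) {
  labs <- vapply(outcomes, function(o) o$strategy, character(1))
  if (anyDuplicated(labs)) stop("duplicate strategy labels")
  if (length(outcomes) < 2L) stop("need at least two strategies")
  if (!reference %in% labs) stop("reference strategy '", reference, "' not present")
  cost <- vapply(outcomes, function(o) o$total_cost, numeric(1))
  qaly <- vapply(outcomes, function(o) o$total_qaly, numeric(1))
  ord <- order(cost, qaly)
  labs <- labs[ord]; cost <- cost[ord]; qaly <- qaly[ord]
  outcomes <- outcomes[ord]
  m <- length(labs)

  status <- rep("frontier", m)
  names(status) <- labs
  # strict dominance: some alternative is no more costly, no less effective,
  # and strictly better on at least one axis
  for (i in seq_len(m)) {
    dominated <- any(cost <= cost[i] & qaly >= qaly[i] &
                       (cost < cost[i] | qaly > qaly[i]))
    if (dominated) status[i] <- "dominated"
  }
  # extended dominance among the remaining candidates
  repeat {
    cand <- which(status == "frontier")
    if (length(cand) < 3L) break
    ic <- diff(cost[cand]) / diff(qaly[cand])
    bad <- which(diff(ic) < 0)  # ICUR to candidate j+1 exceeds that to j+2
    if (length(bad) == 0L) break
    status[cand[bad[1L] + 1L]] <- "extended_dominated"
  }

  ref_i <- which(labs == reference)
  icur_ref <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    if (i == ref_i || qaly[i] == qaly[ref_i]) next
    icur_ref[i] <- (cost[i] - cost[ref_i]) / (qaly[i] - qaly[ref_i])
  }
  icur_front <- rep(NA_real_, m)
  cand <- which(status == "frontier")
  if (length(cand) > 1L)
    icur_front[cand[-1L]] <- diff(cost[cand]) / diff(qaly[cand])

  tab <- data.frame(strategy = labs, total_cost = cost, total_qaly = qaly,
                    delta_cost = cost - cost[ref_i],
                    delta_qaly = qaly - qaly[ref_i],
                    icur_vs_reference = icur_ref,
                    icur_frontier = icur_front,
                    status = unname(status),
                    stringsAsFactors = FALSE)
  res <- list(table = tab, status = status,
              icur_vs_reference = stats::setNames(icur_ref, labs),
              icur_frontier = stats::setNames(icur_front, labs),
              reference = reference, outcomes = outcomes)
  class(res) <- "cua_frontier"
  res
}

#' @export
print.cua_frontier <- function(x, ...) {
  cat("Cost-utility frontier (reference: ", x$reference, ")\n\n", sep = "")
  tab <- x$table
  tab$total_cost <- round(tab$total_cost, 2)
  tab$total_qaly <- round(tab$total_qaly, 4)
  tab$icur_vs_reference <- round(tab$icur_vs_reference, 2)
  tab$icur_frontier <- round(tab$icur_frontier, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Export frontier results as CSV
#'
#' One row per strategy, ordered by total cost: costs, QALYs, increments
#' versus the reference, pairwise and frontier ICURs, and dominance status.
#'
#' @param x A `cua_frontier`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  utils::write.csv(x$table, path, row.names = FALSE)
  invisible(path)
}
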