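#' One-way (tornado) sensitivity analysis
#'
#' Re-runs the full deterministic pipeline with each parameter set in turn
#' to its lower and upper bound (everything else at base case) and records
#' the pairwise ICUR of the target strategy versus the reference.
#' Parameters with a registered 95\% interval use it; the discount rate
#' (named `"discount_rate"`, applied jointly to costs and outcomes) varies
#' over 0--8\%; any other named parameter without an interval is varied by
#' +/-20\% of its base value. If a bound makes the target no more effective
#' than the reference the ICUR at that bound is flagged as `NA` rather than
#' reported as a negative ratio.
#'
#' @param params A validated `cua_parameters`.
#' @param target,reference Regimen labels compared by the ICUR.
#' @param parameter_list Character vector of parameter names; defaults to
#'   every non-fixed registered distribution plus the discount rate and the
#'   annual statin cost.
#' @return A `data.frame` of class `cua_tornado`, one row per parameter
#'   sorted by descending ICUR spread, with attribute `base_icur`.
#' @export
one_way_sa <- function(params, target, reference, parameter_list = NULL) {
  if (is.null(parameter_list)) {
    dn <- names(params$distributions)
    dn <- dn[vapply(params$distributions, function(d) d$family != "fixed", logical(1))]
    parameter_list <- c(dn, "discount_rate", "costs.statin_annual")
  }
  pair_icur <- function(p) {
    out <- run_strategies(p, c(reference, target))
    dq <- out[[target]]$total_qaly - out[[reference]]$total_qaly
    if (dq <= 0) return(NA_real_)
    icur(out[[reference]], out[[target]])
  }
  base_icur <- pair_icur(params)

  bounds_of <- function(nm) {
    if (nm == "discount_rate") return(c(0, 0.08))
    d <- params$distributions[[nm]]
    if (!is.null(d) && d$family != "fixed") return(c(d$low, d$high))
    v <- get_parameter(params, nm)
    sort(c(0.8, 1.2) * v)
  }
  apply_value <- function(nm, v) {
    if (nm == "discount_rate") {
      params$settings$discount_rate_costs <- v
      params$settings$discount_rate_outcomes <- v
      params
    } else {
      set_parameter(params, nm, v)
    }
  }

  rows <- lapply(parameter_list, function(nm) {
    b <- bounds_of(nm)
    lo <- pair_icur(apply_value(nm, b[1]))
    hi <- pair_icur(apply_value(nm, b[2]))
    data.frame(parameter = nm, low_input = b[1], high_input = b[2],
               icur_at_low = lo, icur_at_high = hi,
               spread = if (is.na(lo) || is.na(hi)) NA_real_ else abs(hi - lo),
               dominance_flag = is.na(lo) || is.na(hi),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-ifelse(is.na(tab$spread), Inf, tab$spread)), ]
  rownames(tab) <- NULL
  attr(tab, "base_icur") <- base_icur
  attr(tab, "target") <- target
  attr(tab, "reference") <- reference
  class(tab) <- c("cua_tornado", "data.frame")
  tab
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n` independent probabilistic parameter sets (see
#' [sample_parameters()]) and runs the full pipeline for every strategy in
#' each draw. The whole analysis is deterministic under a fixed seed.
#'
#' @param params A validated `cua_parameters`.
#' @param n Number of Monte Carlo draws (>= 1).
#' @param seed Integer seed.
#' @param strategies Regimen labels to evaluate (default: all).
#' @return An object of class `cua_psa`: `draws` (long `data.frame` with
#'   columns `draw`, `strategy`, `cost`, `qaly`), `n`, `seed`,
#'   `strategies`, and the willingness-to-pay thresholds of the settings.
#' @export
run_psa <- function(params, n, seed, strategies = names(params$regimens)) {
  stopifnot(n >= 1)
  validate_parameters(params)
  set.seed(as.integer(seed %% .Machine$integer.max))
  draw_seeds <- sample.int(.Machine$integer.max - 1L, n, replace = TRUE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      p_i <- sample_parameters(params, draw_seeds[i])
      out <- run_strategies(p_i, strategies)
      data.frame(draw = i, strategy = strategies,
                 cost = vapply(out, function(o) o$total_cost, numeric(1)),
                 qaly = vapply(out, function(o) o$total_qaly, numeric(1)),
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      stop("PSA draw ", i, " failed: ", conditionMessage(e))
    })
    rows[[i]] <- res
  }
  psa <- list(draws = do.call(rbind, rows), n = n, seed = seed,
              strategies = strategies,
              wtp_low = params$settings$wtp_low,
              wtp_high = params$settings$wtp_high)
  class(psa) <- "cua_psa"
  psa
}

# draws in wide matrix form: draws x strategies
.psa_wide <- function(psa, what) {
  d <- psa$draws
  m <- matrix(NA_real_, psa$n, length(psa$strategies),
              dimnames = list(NULL, psa$strategies))
  m[cbind(d$draw, match(d$strategy, psa$strategies))] <- d[[what]]
  m
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value and each PSA draw, the cost-effective
#' strategy is the one maximizing net monetary benefit
#' `NMB = wtp * QALY - cost`; the curve reports each strategy's frequency of
#' being that maximizer, so at every grid point the probabilities across
#' strategies sum to 1. Ties (measure-zero under continuous sampling) are
#' broken toward the lower-cost strategy, then lexically.
#'
#' @param psa A `cua_psa` object.
#' @param wtp_grid Willingness-to-pay grid (USD/QALY); defaults to 0 up to
#'   the settings' upper threshold in 100 steps, with both named thresholds
#'   included exactly.
#' @return An object of class `cua_ceac`: `wtp_grid`, `prob` (matrix grid x
#'   strategies), and a long `data.frame` `curve`.
#' @export
ceac <- function(psa, wtp_grid = NULL) {
  if (psa$n < 1L) stop("empty PSA")
  if (is.null(wtp_grid)) {
    wtp_grid <- sort(unique(c(seq(0, psa$wtp_high, length.out = 101L),
                              psa$wtp_low, psa$wtp_high)))
  }
  cost <- .psa_wide(psa, "cost")
  qaly <- .psa_wide(psa, "qaly")
  strat <- psa$strategies
  # tie-break ordering: evaluate candidates lowest-cost-first (then lexical)
  prob <- matrix(0, length(wtp_grid), length(strat),
                 dimnames = list(NULL, strat))
  for (g in seq_along(wtp_grid)) {
    nmb <- wtp_grid[g] * qaly - cost
    best <- integer(psa$n)
    for (i in seq_len(psa$n)) {
      x <- nmb[i, ]
      w <- which(x == max(x))
      if (length(w) > 1L) w <- w[order(cost[i, w], strat[w])][1L]
      best[i] <- w
    }
    prob[g, ] <- tabulate(best, nbins = length(strat)) / psa$n
  }
  curve <- data.frame(wtp = rep(wtp_grid, times = length(strat)),
                      strategy = rep(strat, each = length(wtp_grid)),
                      probability = as.vector(prob),
                      stringsAsFactors = FALSE)
  res <- list(wtp_grid = wtp_grid, prob = prob, curve = curve)
  class(res) <- "cua_ceac"
  res
}

#' Pairwise probability of cost-effectiveness
#'
#' Fraction of PSA draws in which the target strategy has higher net
#' monetary benefit than the reference at the given willingness-to-pay —
#' equivalently, in which the target's incremental cost per QALY against
#' the reference falls below the threshold (or the target dominates).
#'
#' @param psa A `cua_psa` containing both strategies.
#' @param target,reference Strategy labels.
#' @param wtp Willingness-to-pay threshold (USD/QALY).
#' @return A fraction in `[0, 1]`.
#' @export
prob_cost_effective <- function(psa, target, reference, wtp) {
  cost <- .psa_wide(psa, "cost")
  qaly <- .psa_wide(psa, "qaly")
  nmb_t <- wtp * qaly[, target] - cost[, target]
  nmb_r <- wtp * qaly[, reference] - cost[, reference]
  mean(nmb_t > nmb_r)
}

#' Time-horizon scenario analysis
#'
#' Re-runs the deterministic pipeline with the analytic horizon truncated
#' at each requested value, everything else unchanged, and reports costs,
#' QALYs, increments, and pairwise ICURs against the reference.
#'
#' @param params A validated `cua_parameters`.
#' @param horizons Numeric vector of horizons in years.
#' @param strategies Regimen labels (default: all).
#' @param reference Reference strategy label (default: first strategy).
#' @return A `data.frame` with one row per horizon x strategy: `horizon`,
#'   `strategy`, `cost`, `qaly`, `delta_cost`, `delta_qaly`,
#'   `icur_vs_reference`.
#' @export
scenario_horizons <- function(params, horizons,
                              strategies = names(params$regimens),
                              reference = strategies[1L]) {
  max_age <- params$life_table$age[nrow(params$life_table)]
  rows <- lapply(horizons, function(h) {
    if (params$settings$start_age + h > max_age + 1)
      stop("horizon ", h, " years exceeds life-table coverage")
    p <- params
    p$settings$horizon <- h
    out <- run_strategies(p, strategies)
    ref <- out[[reference]]
    data.frame(
      horizon = h, strategy = strategies,
      cost = vapply(out, function(o) o$total_cost, numeric(1)),
      qaly = vapply(out, function(o) o$total_qaly, numeric(1)),
      delta_cost = vapply(out, function(o) o$total_cost - ref$total_cost, numeric(1)),
      delta_qaly = vapply(out, function(o) o$total_qaly - ref$total_qaly, numeric(1)),
      icur_vs_reference = vapply(out, function(o) {
        dq <- o$total_qaly - ref$total_qaly
        if (dq == 0) NA_real_ else (o$total_cost - ref$total_cost) / dq
      }, numeric(1)),
      stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Value-based price-threshold analysis
#'
#' Finds the per-pen price at which the target strategy's pairwise ICUR
#' against the reference equals the willingness-to-pay threshold. Lifetime
#' cost is affine in the per-pen price (QALYs are price-invariant), so the
#' threshold has the closed form
#' `p* = p0 + (wtp * dQALY - dCost(p0)) / w`, where `w` is the discounted
#' per-dollar price weight obtained from a two-point probe; the result is
#' verified against a bisection solve of the same equation.
#'
#' @param params A validated `cua_parameters`.
#' @param target Label of an active regimen.
#' @param reference Label of the comparator (e.g. statins alone).
#' @param wtp Willingness-to-pay threshold (USD/QALY).
#' @return An object of class `cua_price_threshold`: `price` (closed form),
#'   `price_bisection`, `current_price`, `icur_at_current_price`,
#'   `required_change_pct` (negative = price cut needed), and
#'   `no_reduction_needed`.
#' @export
price_threshold <- function(params, target, reference, wtp) {
  out0 <- run_strategies(params, c(reference, target))
  dq <- out0[[target]]$total_qaly - out0[[reference]]$total_qaly
  if (dq <= 0)
    stop("target '", target, "' does not gain QALYs over '", reference,
         "'; price threshold undefined")
  p0 <- params$regimens[[target]]$price_per_pen
  cost_at <- function(p) {
    pp <- params
    pp$regimens[[target]]$price_per_pen <- p
    run_strategy(pp, target)$total_cost
  }
  c_ref <- out0[[reference]]$total_cost
  c0 <- out0[[target]]$total_cost
  w <- cost_at(p0 + 1) - c0  # discounted administrations x pens weight
  p_star <- p0 + (wtp * dq - (c0 - c_ref)) / w

  f <- function(p) (cost_at(p) - c_ref) / dq - wtp
  hi <- max(2 * abs(p_star), 2 * p0, 1)
  lo <- min(0, 2 * p_star)
  p_bis <- stats::uniroot(f, c(lo, hi), tol = 1e-8 * max(1, abs(p_star)))$root

  res <- list(price = p_star, price_bisection = p_bis,
              current_price = p0,
              icur_at_current_price = (c0 - c_ref) / dq,
              required_change_pct = if (p0 > 0) 100 * (p_star - p0) / p0 else NA_real_,
              no_reduction_needed = p_star >= p0,
              wtp = wtp, target = target, reference = reference)
  class(res) <- "cua_price_threshold"
  res
}
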