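#' Convert an annual event rate to a transition probability
#'
#' Uses the standard exponential (constant-hazard) conversion
#' `P = 1 - exp(-r t)` for a rate `r` per person-year over a cycle of
#' `t` years, and its inverse `r = -log(1 - P) / t`.
#'
#' @param rate Event rate per person-year (>= 0).
#' @param t Cycle length in years (> 0).
#' @return A probability in `[0, 1)`.
#' @export
rate_to_prob <- function(rate, t = 1) {
  if (any(rate < 0)) stop("rate must be non-negative")
  if (any(t <= 0)) stop("cycle length t must be positive")
  1 - exp(-rate * t)
}

#' @rdname rate_to_prob
#' @param prob A probability in `[0, 1)`.
#' @export
prob_to_rate <- function(prob, t = 1) {
  if (any(prob < 0 | prob >= 1)) stop("prob must lie in [0, 1)")
  -log(1 - prob) / t
}

#' Adjust a reference-cohort event rate to the target population
#'
#' Rescales a baseline event rate measured in a reference cohort to the
#' modelled population via `r_a = r0 * hr_age^delta_age * rr^delta_ldl`,
#' where `hr_age` is the hazard ratio per year of age, `delta_age` the age
#' difference between target and reference, `rr` the rate ratio per 1 mmol/L
#' LDL-C reduction for any major vascular event, and `delta_ldl` the amount
#' by which the target population's LDL-C is below the reference cohort's.
#' The adjustment is the identity when both deltas are zero, as in the base
#' case where the cohort is the reference population itself.
#'
#' @param r0 Baseline event rate per person-year (>= 0).
#' @param hr_age Hazard ratio per year of age (> 0).
#' @param delta_age Age difference in years (target minus reference).
#' @param rr Rate ratio per 1 mmol/L LDL-C reduction (> 0).
#' @param delta_ldl LDL-C difference in mmol/L (reference minus target).
#' @return Adjusted rate per person-year.
#' @export
adjust_baseline_rate <- function(r0, hr_age, delta_age, rr, delta_ldl) {
  if (any(r0 < 0)) stop("r0 must be non-negative")
  if (any(hr_age <= 0)) stop("hr_age must be positive")
  if (any(rr <= 0)) stop("rr must be positive")
  r0 * hr_age^delta_age * rr^delta_ldl
}

#' Treatment-effect translation: LDL-C reduction to event-rate reduction
#'
#' Applies the per-mmol/L rate ratio to a regimen's absolute LDL-C
#' reduction: `r_tx = r0 * rr^delta_ldl`. With `delta_ldl = 0` (the
#' statins-alone comparator) the rate is unchanged.
#'
#' @param r0 Untreated event rate per person-year (>= 0).
#' @param rr Rate ratio per 1 mmol/L LDL-C reduction, in `(0, 1]`.
#' @param delta_ldl Absolute LDL-C reduction under treatment (mmol/L, >= 0).
#' @return Treated event rate per person-year.
#' @export
treated_rate <- function(r0, rr, delta_ldl) {
  if (any(r0 < 0)) stop("r0 must be non-negative")
  if (any(rr <= 0 | rr > 1)) stop("rr must lie in (0, 1]")
  if (any(delta_ldl < 0)) stop("delta_ldl must be non-negative")
  r0 * rr^delta_ldl
}

#' Background mortality split into CV and non-CV components
#'
#' Looks up all-cause and cardiovascular mortality at the given age
#' (floored; ages past the last table row reuse that row), applies the
#' treatment effect on vascular death (`rr_vascular_death^delta_ldl`) and,
#' for patients whose MI or stroke occurred in the previous year, the
#' post-event relative risk of CV death. Non-CV mortality is the all-cause
#' minus CV remainder and is unaffected by treatment.
#'
#' @param life_table A `cua_life_table`.
#' @param age Current cohort age (years).
#' @param delta_ldl Absolute LDL-C reduction under treatment (mmol/L).
#' @param effects Effects list (uses `rr_vascular_death`).
#' @param post_event_year1 Is the cohort in a first-year post-event state?
#' @param multipliers Risk-multiplier list (uses `cv_death_post_event`).
#' @return List with components `cv_rate` and `non_cv_rate` (per person-year).
#' @export
mortality_rates <- function(life_table, age, delta_ldl, effects,
                            post_event_year1 = FALSE, multipliers = NULL) {
  if (age < life_table$age[1L]) stop("age ", age, " below life-table range")
  m <- .life_table_lookup(life_table, age)
  cv <- m$cv * effects$rr_vascular_death^delta_ldl
  if (isTRUE(post_event_year1)) {
    rrd <- if (is.null(multipliers)) 1 else multipliers$cv_death_post_event
    cv <- cv * rrd
  }
  list(cv_rate = cv, non_cv_rate = m$all_cause - m$cv)
}

# Static per-state structure of the 11-state model (alive states 1..9 in the
# canonical order of health_states()): which state an MI or IS sends the
# cohort to, where residual mass goes (stay put, or the tunnel exit), and
# whether the state is a first-post-event-year tunnel.
.state_structure <- list(
  mi_dest  = c(2L, 4L, 4L, 4L, 4L, 2L, 2L, 2L, 2L),
  is_dest  = c(6L, 6L, 6L, 6L, 6L, 8L, 8L, 8L, 8L),
  residual = c(1L, 3L, 3L, 5L, 5L, 7L, 7L, 9L, 9L),
  tunnel   = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))

# Event-rate multipliers by alive state: history multiplier per event type,
# stacked with the any-CV-event-in-past-year multiplier in tunnel states.
.state_multipliers <- function(multipliers) {
  m <- multipliers
  rec <- m$any_cv_event_past_year
  list(
    mi = c(1, m$recurrent_mi * rec, m$recurrent_mi, m$mi_2plus * rec,
           m$mi_2plus, rec, 1, rec, 1),
    is = c(1, rec, 1, rec, 1, m$recurrent_stroke * rec, m$recurrent_stroke,
           m$stroke_2plus * rec, m$stroke_2plus))
}

# Precompute everything about one strategy that does not change over cycles.
.engine_context <- function(params, regimen) {
  s <- params$settings
  br <- params$baseline_rates
  eff <- params$effects
  aa <- params$age_adj
  delta_age <- s$start_age - aa$reference_age
  delta_ldl_pop <- (aa$reference_ldl %||% s$baseline_ldl) - s$baseline_ldl
  adj <- function(r0) adjust_baseline_rate(r0, aa$hr_age_per_year, delta_age,
                                           eff$rr_any_major_vascular,
                                           delta_ldl_pop)
  dldl <- regimen$ldl_reduction_mean
  list(
    r_mi = treated_rate(adj(br$nonfatal_mi), eff$rr_mi, dldl),
    r_is = treated_rate(adj(br$nonfatal_stroke), eff$rr_stroke, dldl),
    r_rv = treated_rate(adj(br$revascularization), eff$rr_revasc, dldl),
    cv_effect = eff$rr_vascular_death^dldl,
    sm = .state_multipliers(params$multipliers),
    delta_ldl = dldl)
}

#' Build the transition matrix for one cycle
#'
#' For every alive state the competing annual rates (MI, IS, CV death,
#' non-CV death) are assembled from the treated event rates, the post-event
#' history multipliers, and the life table at the cohort's current age
#' (`start_age + cycle`). Competing risks are resolved jointly: the total
#' exit probability is `1 - exp(-sum(rates) * t)`, apportioned across causes
#' proportionally to their rates, which guarantees row-stochastic rows
#' without truncation and reduces to the single-cause exponential formula
#' when only one rate is non-zero. Residual probability keeps the cohort in
#' place, except in the first-year tunnel states, whose residual moves to
#' the corresponding post-event state. Only one CV event can occur per
#' cycle; death states are absorbing.
#'
#' @param params A validated `cua_parameters`.
#' @param regimen A `cua_regimen` (one entry of `params$regimens`).
#' @param cycle Zero-based cycle index (age at the cycle start is
#'   `start_age + cycle * cycle_length`).
#' @return An 11 x 11 row-stochastic matrix with state-labelled dimnames.
#' @export
build_transition_matrix <- function(params, regimen, cycle) {
  ctx <- .engine_context(params, regimen)
  .transition_matrix(params, ctx, cycle)
}

.transition_matrix <- function(params, ctx, cycle) {
  s <- params$settings
  t_len <- s$cycle_length
  age <- s$start_age + cycle * t_len
  lt <- .life_table_lookup(params$life_table, age)
  cv_base <- lt$cv * ctx$cv_effect
  ncv <- lt$all_cause - lt$cv
  rr_post <- params$multipliers$cv_death_post_event
  st <- .state_structure

  M <- matrix(0, 11L, 11L, dimnames = list(health_states(), health_states()))
  for (i in 1:9) {
    r_mi <- ctx$r_mi * ctx$sm$mi[i]
    r_is <- ctx$r_is * ctx$sm$is[i]
    r_cvd <- cv_base * (if (st$tunnel[i]) rr_post else 1)
    total <- r_mi + r_is + r_cvd + ncv
    if (total > 0) {
      p_exit <- 1 - exp(-total * t_len)
      w <- p_exit / total
      M[i, st$mi_dest[i]] <- M[i, st$mi_dest[i]] + r_mi * w
      M[i, st$is_dest[i]] <- M[i, st$is_dest[i]] + r_is * w
      M[i, 10L] <- r_cvd * w
      M[i, 11L] <- ncv * w
      M[i, st$residual[i]] <- M[i, st$residual[i]] + (1 - p_exit)
    } else {
      M[i, st$residual[i]] <- 1
    }
  }
  M[10L, 10L] <- 1
  M[11L, 11L] <- 1
  M
}

#' Run the cohort trace for one strategy
#'
#' Starts the whole cohort event-free and iterates the per-cycle transition
#' matrices over the horizon. Expected revascularizations — a costed
#' procedure overlay, not a health state — are recorded per cycle as the
#' start-of-cycle alive occupancy times the per-cycle probability of the
#' treated revascularization rate.
#'
#' @param params A validated `cua_parameters`.
#' @param regimen A `cua_regimen`, or the name of one in `params$regimens`.
#' @return An object of class `cua_trace`: list with `occupancy`
#'   (`(n_cycles + 1) x 11` matrix of state fractions, row 1 the initial
#'   distribution), `revasc_events` (expected events per person per cycle),
#'   `ages`, `regimen`, and `n_cycles`.
#' @export
run_cohort <- function(params, regimen) {
  if (is.character(regimen)) {
    if (!regimen %in% names(params$regimens))
      stop("unknown regimen: ", regimen)
    regimen <- params$regimens[[regimen]]
  }
  s <- params$settings
  n <- as.integer(round(s$horizon / s$cycle_length))
  ctx <- .engine_context(params, regimen)
  p_rv <- rate_to_prob(ctx$r_rv, s$cycle_length)

  occ <- matrix(0, n + 1L, 11L, dimnames = list(NULL, health_states()))
  occ[1L, 1L] <- 1
  rv <- numeric(n)
  for (k in seq_len(n)) {
    M <- .transition_matrix(params, ctx, k - 1L)
    rv[k] <- sum(occ[k, 1:9]) * p_rv
    occ[k + 1L, ] <- occ[k, ] %*% M
  }
  trace <- list(occupancy = occ, revasc_events = rv,
                ages = s$start_age + (0:n) * s$cycle_length,
                regimen = regimen$name, n_cycles = n,
                cycle_length = s$cycle_length)
  class(trace) <- "cua_trace"
  trace
}

#' Export a cohort trace as CSV
#'
#' One row per cycle boundary: cycle index, cohort age, the 11 state
#' occupancies, and the expected revascularization events accrued during
#' the cycle ending at that boundary (0 for the initial row).
#'
#' @param trace A `cua_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(cycle = 0:trace$n_cycles, age = trace$ages,
                   trace$occupancy,
                   revasc_events = c(0, trace$revasc_events),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
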