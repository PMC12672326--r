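#' Cohort and analysis settings
#'
#' @param start_age Mean age of the cohort at entry (years).
#' @param baseline_ldl Mean baseline LDL-C of the cohort (mmol/L).
#' @param cycle_length Markov cycle length (years).
#' @param horizon Analytic time horizon (years).
#' @param discount_rate_costs Annual discount rate applied to costs.
#' @param discount_rate_outcomes Annual discount rate applied to QALYs.
#' @param half_cycle_correction Apply the trapezoidal half-cycle correction?
#' @param wtp_low,wtp_high Willingness-to-pay thresholds (USD/QALY); the
#'   defaults are 1x and 3x China's 2024 per-capita GDP.
#' @return A list of class `cua_settings`.
#' @export
cohort_settings <- function(start_age = 60.6,
                            baseline_ldl = 3.13,
                            cycle_length = 1,
                            horizon = 30,
                            discount_rate_costs = 0.05,
                            discount_rate_outcomes = 0.05,
                            half_cycle_correction = TRUE,
                            wtp_low = 13291.7,
                            wtp_high = 39875.0) {
  s <- list(start_age = start_age, baseline_ldl = baseline_ldl,
            cycle_length = cycle_length, horizon = horizon,
            discount_rate_costs = discount_rate_costs,
            discount_rate_outcomes = discount_rate_outcomes,
            half_cycle_correction = isTRUE(half_cycle_correction),
            wtp_low = wtp_low, wtp_high = wtp_high)
  class(s) <- "cua_settings"
  if (s$start_age <= 0) stop("settings.start_age must be positive")
  if (s$cycle_length <= 0 || s$cycle_length > s$horizon)
    stop("settings.cycle_length must satisfy 0 < cycle_length <= horizon")
  for (f in c("discount_rate_costs", "discount_rate_outcomes"))
    if (s[[f]] < 0 || s[[f]] > 1) stop("settings.", f, " must lie in [0, 1]")
  if (s$wtp_low > s$wtp_high) stop("settings.wtp_low must not exceed settings.wtp_high")
  s
}

#' Specification of one treatment strategy
#'
#' Each strategy is a dosing regimen of a PCSK9 inhibitor added to background
#' statin therapy, characterised by its mean absolute LDL-C reduction versus
#' statins alone and by its dosing schedule and per-pen price. Statins alone
#' is itself a regimen with zero LDL-C reduction and zero PCSK9 drug cost, so
#' a single code path serves all arms.
#'
#' @param name Strategy label (unique within a parameter set).
#' @param ldl_reduction_mean Mean absolute LDL-C reduction (mmol/L).
#' @param ldl_reduction_ci Length-2 numeric, 95\% CI of the reduction.
#' @param price_per_pen Price per pen (USD); higher doses are priced as pen
#'   multiples of the listed pen strength.
#' @param pens_per_administration Pens consumed at each administration.
#' @param administrations_year1 Administrations in the first model year.
#' @param administrations_subsequent Administrations per year thereafter.
#' @param is_injectable Is this an active injectable PCSK9 arm? (`FALSE`
#'   only for the statins-alone comparator.)
#' @return A list of class `cua_regimen`.
#' @export
regimen_spec <- function(name, ldl_reduction_mean, ldl_reduction_ci = c(NA, NA),
                         price_per_pen = 0, pens_per_administration = 0,
                         administrations_year1 = 0,
                         administrations_subsequent = 0,
                         is_injectable = TRUE) {
  r <- list(name = name,
            ldl_reduction_mean = ldl_reduction_mean,
            ldl_reduction_ci = as.numeric(ldl_reduction_ci),
            price_per_pen = price_per_pen,
            pens_per_administration = pens_per_administration,
            administrations_year1 = administrations_year1,
            administrations_subsequent = administrations_subsequent,
            is_injectable = isTRUE(is_injectable))
  class(r) <- "cua_regimen"
  if (r$ldl_reduction_mean < 0)
    stop("regimen '", name, "': ldl_reduction_mean must be >= 0")
  if (r$price_per_pen < 0) stop("regimen '", name, "': price_per_pen must be >= 0")
  if (r$is_injectable &&
      (r$administrations_year1 <= 0 || r$administrations_subsequent <= 0))
    stop("regimen '", name, "': administration counts must be positive for active regimens")
  r
}

#' Uncertainty distribution of one model parameter
#'
#' Families follow standard practice for probabilistic sensitivity analysis:
#' gamma for costs (and for the magnitude of disutilities), lognormal for
#' hazard/rate ratios, normal for mean LDL-C reductions, beta for utilities
#' and probabilities. Parameters marked `fixed` are never varied.
#'
#' @param family One of `"gamma"`, `"lognormal"`, `"normal"`, `"beta"`,
#'   `"fixed"`.
#' @param base Base-case value (the distribution is centred here).
#' @param low,high The printed 95\% interval.
#' @param paths List of character vectors; each is a path into the parameter
#'   set (e.g. `c("costs", "mi_year1")`) that this distribution drives. A
#'   single distribution may drive several fields (e.g. one per-pen price
#'   shared by all dose regimens of an agent).
#' @return A list of class `cua_distribution`.
#' @export
parameter_distribution <- function(family, base, low = NA, high = NA,
                                   paths = list()) {
  fam <- match.arg(family, c("gamma", "lognormal", "normal", "beta", "fixed"))
  d <- list(family = fam, base = as.numeric(base), low = as.numeric(low),
            high = as.numeric(high), paths = paths)
  class(d) <- "cua_distribution"
  if (fam != "fixed") {
    if (is.na(low) || is.na(high)) stop("non-fixed distribution needs a (low, high) range")
    if (!(low <= base && base <= high))
      stop("distribution range must bracket the base value (base = ", base, ")")
  }
  d
}

#' Assemble a complete, validated parameter set
#'
#' @param settings A `cua_settings` object.
#' @param baseline_rates Named list: `nonfatal_mi`, `nonfatal_stroke`,
#'   `revascularization`, events per person-year.
#' @param age_adj Named list: `hr_age_per_year`, `reference_age`,
#'   `reference_ldl` — the hazard ratio per year of age and the reference
#'   cohort the baseline rates were measured in.
#' @param multipliers Named list of risk multipliers after prior events.
#' @param effects Named list of rate ratios per 1 mmol/L LDL-C reduction.
#' @param regimens Named list of `cua_regimen` objects.
#' @param costs Named list of cost inputs (USD).
#' @param utilities Named list of state utilities and disutilities.
#' @param distributions Named list of `cua_distribution` objects.
#' @param life_table A `cua_life_table`.
#' @return A list of class `cua_parameters`.
#' @export
parameter_set <- function(settings, baseline_rates, age_adj, multipliers,
                          effects, regimens, costs, utilities,
                          distributions, life_table) {
  p <- list(settings = settings, baseline_rates = baseline_rates,
            age_adj = age_adj, multipliers = multipliers, effects = effects,
            regimens = regimens, costs = costs, utilities = utilities,
            distributions = distributions, life_table = life_table)
  class(p) <- "cua_parameters"
  validate_parameters(p)
}

#' Validate a parameter set against all model invariants
#'
#' Checks ranges, signs, uniqueness of regimen names, the life table, and
#' that every distribution path resolves to an existing numeric field.
#' Errors name the offending field.
#'
#' @param params A `cua_parameters` object.
#' @return The validated object, invisibly unchanged.
#' @export
validate_parameters <- function(params) {
  if (!inherits(params, "cua_parameters")) stop("not a cua_parameters object")
  # settings re-validated via its constructor invariants
  s <- params$settings
  do.call(cohort_settings, unclass(s))

  for (f in c("nonfatal_mi", "nonfatal_stroke", "revascularization")) {
    v <- params$baseline_rates[[f]]
    if (is.null(v) || v < 0) stop("baseline_rates.", f, " must be a rate >= 0")
  }
  if (params$age_adj$hr_age_per_year <= 0)
    stop("age_adj.hr_age_per_year must be positive")
  for (f in names(params$multipliers)) {
    if (params$multipliers[[f]] <= 0) stop("multipliers.", f, " must be positive")
  }
  for (f in names(params$effects)) {
    v <- params$effects[[f]]
    if (v <= 0 || v > 1) stop("effects.", f, " must lie in (0, 1]")
  }
  rn <- vapply(params$regimens, function(r) r$name, character(1))
  if (anyDuplicated(rn)) stop("regimen names must be unique")
  if (!identical(unname(rn), names(params$regimens)))
    stop("regimens list names must match regimen$name labels")
  for (r in params$regimens) do.call(regimen_spec, unclass(r))

  for (f in setdiff(names(params$costs), character(0))) {
    if (params$costs[[f]] < 0) stop("costs.", f, " must be >= 0")
  }
  for (f in names(params$utilities)) {
    v <- params$utilities[[f]]
    if (startsWith(f, "disutility")) {
      if (v > 0) stop("utilities.", f, " is a disutility and must be <= 0")
    } else if (v < 0 || v > 1) {
      stop("utilities.", f, " must lie in [0, 1]")
    }
  }
  for (nm in names(params$distributions)) {
    d <- params$distributions[[nm]]
    if (d$family == "fixed") next
    for (path in d$paths) {
      v <- tryCatch(params[[path]], error = function(e) NULL)
      if (is.null(v) || !is.numeric(v))
        stop("distribution '", nm, "' path does not resolve: ",
             paste(path, collapse = "."))
    }
  }
  validate_life_table(params$life_table)
  if (s$start_age < params$life_table$age[1L])
    stop("life table does not cover the cohort start age")
  invisible(params)
}

#' Read and write a single model parameter by name
#'
#' Parameters are addressed by the names of the distribution registry (for
#' `set_parameter()` all paths driven by that distribution are updated
#' together, e.g. a per-pen price shared across dose regimens), or by a
#' dotted field path such as `"costs.mi_year1"`.
#'
#' @param params A `cua_parameters` object.
#' @param name Distribution name or dotted path.
#' @param value Replacement value (for `set_parameter`).
#' @return `get_parameter()` the current value; `set_parameter()` the
#'   modified parameter set.
#' @export
get_parameter <- function(params, name) {
  if (name %in% names(params$distributions)) {
    path <- params$distributions[[name]]$paths[[1L]]
    return(params[[path]])
  }
  path <- strsplit(name, ".", fixed = TRUE)[[1L]]
  v <- tryCatch(params[[path]], error = function(e) NULL)
  if (is.null(v)) stop("unknown parameter: ", name)
  v
}

#' @rdname get_parameter
#' @export
set_parameter <- function(params, name, value) {
  if (name %in% names(params$distributions)) {
    for (path in params$distributions[[name]]$paths) params[[path]] <- value
    return(params)
  }
  path <- strsplit(name, ".", fixed = TRUE)[[1L]]
  old <- tryCatch(params[[path]], error = function(e) NULL)
  if (is.null(old)) stop("unknown parameter: ", name)
  params[[path]] <- value
  params
}

# -- built-in base case -------------------------------------------------------

# Distribution registry for the base case. Rates from the statin reference
# arm carry no interval and stay fixed; everything else follows the family
# conventions documented in parameter_distribution().
.base_case_distributions <- function(regimens) {
  d <- list()
  ln <- function(base, low, high, ...) parameter_distribution(
    "lognormal", base, low, high, paths = list(...))
  gm <- function(base, low, high, ...) parameter_distribution(
    "gamma", base, low, high, paths = list(...))
  be <- function(base, low, high, ...) parameter_distribution(
    "beta", base, low, high, paths = list(...))

  d[["hr_recurrent_mi"]] <- ln(1.13, 1.04, 1.22, c("multipliers", "recurrent_mi"))
  d[["hr_recurrent_stroke"]] <- ln(1.13, 0.99, 1.30, c("multipliers", "recurrent_stroke"))
  d[["hr_any_cv_event_past_year"]] <- ln(1.50, 1.39, 1.62, c("multipliers", "any_cv_event_past_year"))
  d[["hr_mi_2plus"]] <- ln(1.19, 1.05, 1.34, c("multipliers", "mi_2plus"))
  d[["hr_stroke_2plus"]] <- ln(1.36, 1.03, 1.80, c("multipliers", "stroke_2plus"))
  d[["rr_cv_death_post_event"]] <- ln(1.31, 1.15, 1.49, c("multipliers", "cv_death_post_event"))

  d[["rr_mi"]] <- ln(0.74, 0.69, 0.78, c("effects", "rr_mi"))
  d[["rr_stroke"]] <- ln(0.80, 0.73, 0.88, c("effects", "rr_stroke"))
  d[["rr_revasc"]] <- ln(0.76, 0.73, 0.80, c("effects", "rr_revasc"))
  d[["rr_vascular_death"]] <- ln(0.86, 0.82, 0.90, c("effects", "rr_vascular_death"))
  d[["rr_any_death"]] <- ln(0.90, 0.87, 0.93, c("effects", "rr_any_death"))
  d[["rr_any_major_vascular"]] <- ln(0.78, 0.76, 0.80, c("effects", "rr_any_major_vascular"))

  for (r in regimens) {
    if (!r$is_injectable) next
    d[[paste0("ldl_reduction.", r$name)]] <- parameter_distribution(
      "normal", r$ldl_reduction_mean, r$ldl_reduction_ci[1], r$ldl_reduction_ci[2],
      paths = list(c("regimens", r$name, "ldl_reduction_mean")))
  }
  # one per-pen price per agent, shared across its dose regimens
  agent_of <- function(nm) tolower(strsplit(nm, " ")[[1L]][1L])
  agents <- list(
    alirocumab  = c(40.4, 32.3, 48.5),
    evolocumab  = c(39.4, 31.5, 47.3),
    tafolecimab = c(39.7, 31.8, 47.7),
    inclisiran  = c(1387.2, 1109.8, 1664.7))
  for (ag in names(agents)) {
    members <- Filter(function(r) r$is_injectable && agent_of(r$name) == ag, regimens)
    if (length(members) == 0L) next
    paths <- lapply(members, function(r) c("regimens", r$name, "price_per_pen"))
    v <- agents[[ag]]
    d[[paste0("price_per_pen.", ag)]] <- parameter_distribution(
      "gamma", v[1], v[2], v[3], paths = paths)
  }

  d[["cost.mi_year1"]] <- gm(3275.0, 2620.0, 3930.0, c("costs", "mi_year1"))
  d[["cost.mi_subsequent_annual"]] <- gm(1893.9, 1420.3, 2367.3, c("costs", "mi_subsequent_annual"))
  d[["cost.is_year1"]] <- gm(1390.4, 1112.3, 1668.5, c("costs", "is_year1"))
  d[["cost.is_subsequent_annual"]] <- gm(1141.1, 1099.3, 1206.0, c("costs", "is_subsequent_annual"))
  d[["cost.revascularization"]] <- gm(16543.2, 13234.6, 19851.9, c("costs", "revascularization"))
  d[["cost.cv_death"]] <- gm(2332.7, 1866.2, 2799.3, c("costs", "cv_death"))

  d[["utility.baseline"]] <- be(0.964, 0.959, 0.969, c("utilities", "baseline"))
  d[["utility.mi_year1"]] <- be(0.866, 0.847, 0.886, c("utilities", "mi_year1"))
  d[["utility.mi_post"]] <- be(0.950, 0.942, 0.958, c("utilities", "mi_post"))
  d[["utility.mi2_year1"]] <- be(0.819, 0.793, 0.846, c("utilities", "mi2_year1"))
  d[["utility.mi2_post"]] <- be(0.940, 0.905, 0.975, c("utilities", "mi2_post"))
  d[["utility.is_year1"]] <- be(0.510, 0.470, 0.540, c("utilities", "is_year1"))
  d[["utility.is_post"]] <- be(0.750, 0.710, 0.800, c("utilities", "is_post"))
  d[["utility.is2_year1"]] <- be(0.340, 0.320, 0.360, c("utilities", "is2_year1"))
  d[["utility.is2_post"]] <- be(0.420, 0.390, 0.451, c("utilities", "is2_post"))
  # disutilities: gamma on the magnitude, sign restored at draw time
  d[["disutility.injection"]] <- parameter_distribution(
    "gamma", -0.0003, -0.002, 0, paths = list(c("utilities", "disutility_injection")))
  d[["disutility.revascularization"]] <- parameter_distribution(
    "gamma", -0.007, -0.014, -0.001, paths = list(c("utilities", "disutility_revasc")))

  # event rates reported without intervals: registered as fixed
  d[["rate.nonfatal_mi"]] <- parameter_distribution(
    "fixed", 0.009, paths = list(c("baseline_rates", "nonfatal_mi")))
  d[["rate.nonfatal_stroke"]] <- parameter_distribution(
    "fixed", 0.004, paths = list(c("baseline_rates", "nonfatal_stroke")))
  d[["rate.revascularization"]] <- parameter_distribution(
    "fixed", 0.012, paths = list(c("baseline_rates", "revascularization")))
  d
}

#' The built-in base-case parameter set
#'
#' Returns the full base-case input set for the cost-utility comparison of
#' nine PCSK9-inhibitor dosing regimens added to statins versus statins
#' alone: a 60.6-year-old hypercholesterolemia cohort with baseline LDL-C
#' 3.13 mmol/L, 1-year cycles over a 30-year horizon, 5\% annual discounting
#' of costs and outcomes, and willingness-to-pay thresholds of $13,291.7 and
#' $39,875.0 per QALY. Event rates are per person-year (the per-100
#' patient-year source values divided by 100 at construction). Dosing
#' schedules use calendar arithmetic (Q2W = 26/yr, Q4W = 13/yr,
#' Q6W = 365.25/42 per yr) and inclisiran's loading year of three
#' administrations followed by two per year.
#'
#' @param life_table Optional `cua_life_table`; defaults to the synthetic
#'   Gompertz-Makeham life table from [make_life_table()].
#' @return A validated `cua_parameters` object.
#' @seealso [make_life_table()], [load_parameters()]
#' @export
base_case_parameters <- function(life_table = NULL) {
  if (is.null(life_table)) life_table <- make_life_table()

  q2w <- 26
  q4w <- 13
  q6w <- 365.25 / 42
  regimen_list <- list(
    regimen_spec("Statins alone", 0, c(NA, NA), 0, 0, 0, 0, is_injectable = FALSE),
    regimen_spec("Evolocumab 140 mg Q2W", 1.79, c(1.65, 1.93), 39.4, 1, q2w, q2w),
    regimen_spec("Evolocumab 420 mg Q4W", 1.59, c(1.48, 1.71), 39.4, 3, q4w, q4w),
    regimen_spec("Alirocumab 75 mg Q2W", 1.36, c(1.25, 1.46), 40.4, 1, q2w, q2w),
    regimen_spec("Alirocumab 150 mg Q2W", 1.47, c(1.24, 1.69), 40.4, 2, q2w, q2w),
    regimen_spec("Alirocumab 300 mg Q4W", 1.53, c(1.26, 1.79), 40.4, 4, q4w, q4w),
    regimen_spec("Tafolecimab 150 mg Q2W", 1.48, c(1.04, 1.93), 39.7, 1, q2w, q2w),
    regimen_spec("Tafolecimab 450 mg Q4W", 1.65, c(1.46, 1.85), 39.7, 3, q4w, q4w),
    regimen_spec("Tafolecimab 600 mg Q6W", 1.41, c(1.10, 1.73), 39.7, 4, q6w, q6w),
    regimen_spec("Inclisiran 300 mg Q6M", 1.27, c(1.11, 1.43), 1387.2, 1, 3, 2))
  names(regimen_list) <- vapply(regimen_list, function(r) r$name, character(1))

  parameter_set(
    settings = cohort_settings(),
    baseline_rates = list(nonfatal_mi = 0.9 / 100,
                          nonfatal_stroke = 0.4 / 100,
                          revascularization = 1.2 / 100),
    age_adj = list(hr_age_per_year = 1.0, reference_age = 60.6,
                   reference_ldl = 3.13),
    multipliers = list(recurrent_mi = 1.13, recurrent_stroke = 1.13,
                       any_cv_event_past_year = 1.50, mi_2plus = 1.19,
                       stroke_2plus = 1.36, cv_death_post_event = 1.31),
    effects = list(rr_mi = 0.74, rr_stroke = 0.80, rr_revasc = 0.76,
                   rr_vascular_death = 0.86, rr_any_death = 0.90,
                   rr_any_major_vascular = 0.78),
    regimens = regimen_list,
    costs = list(statin_annual = 846.1, mi_year1 = 3275.0,
                 mi_subsequent_annual = 1893.9, is_year1 = 1390.4,
                 is_subsequent_annual = 1141.1, revascularization = 16543.2,
                 cv_death = 2332.7, non_cv_death = 0),
    utilities = list(baseline = 0.964, mi_year1 = 0.866, mi_post = 0.950,
                     mi2_year1 = 0.819, mi2_post = 0.940, is_year1 = 0.510,
                     is_post = 0.750, is2_year1 = 0.340, is2_post = 0.420,
                     disutility_injection = -0.0003, disutility_revasc = -0.007),
    distributions = .base_case_distributions(regimen_list),
    life_table = life_table)
}

# -- file I/O -----------------------------------------------------------------

#' Load or write a parameter set as JSON
#'
#' The on-disk schema mirrors the in-memory structure: top-level keys
#' `settings`, `baseline_rates`, `age_adj`, `multipliers`, `effects`,
#' `regimens`, `costs`, `utilities`, `distributions`, and (optionally) an
#' embedded `life_table` with `age` / `all_cause_rate` / `cv_rate` columns.
#' Missing optional values fall back to the base-case defaults; the loaded
#' set is fully validated, with errors naming the offending field. Numbers
#' are written with 17 significant digits, so a write/load cycle reproduces
#' every value bit-identically.
#'
#' @param path Path to a JSON parameter file.
#' @param life_table Optional `cua_life_table` overriding the file's
#'   embedded table; if neither is present the synthetic default is used.
#' @return `load_parameters()` a validated `cua_parameters`;
#'   `write_parameters()` the path, invisibly.
#' @export
load_parameters <- function(path, life_table = NULL) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  raw <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE, simplifyMatrix = FALSE),
    error = function(e) stop("parameter file did not parse as JSON: ",
                             conditionMessage(e)))
  if (is.null(raw) || !is.list(raw)) stop("parameter file is not a JSON object: ", path)
  # JSON whole numbers parse as integers; the model works in doubles
  raw <- rapply(raw, as.numeric, classes = "integer", how = "replace")

  if (is.null(life_table)) {
    life_table <- if (!is.null(raw$life_table)) {
      with(raw$life_table, life_table(age, all_cause_rate, cv_rate))
    } else {
      make_life_table()
    }
  }
  settings <- do.call(cohort_settings, raw$settings %||% list())

  regimens <- lapply(raw$regimens, function(r) {
    ci <- r$ldl_reduction_ci
    r$ldl_reduction_ci <- if (length(ci) == 2L) {
      vapply(ci, function(v) if (length(v) == 0L) NA_real_ else as.numeric(v),
             numeric(1))
    } else {
      c(NA_real_, NA_real_)
    }
    do.call(regimen_spec, r)
  })
  names(regimens) <- vapply(regimens, function(r) r$name, character(1))

  dists <- lapply(raw$distributions %||% list(), function(d) {
    d$paths <- lapply(d$paths, as.character)
    d$low <- d$low %||% NA_real_
    d$high <- d$high %||% NA_real_
    do.call(parameter_distribution, d)
  })

  defaults <- base_case_parameters(life_table = life_table)
  fill <- function(given, default) utils::modifyList(default, given %||% list())

  parameter_set(
    settings = settings,
    baseline_rates = fill(raw$baseline_rates, defaults$baseline_rates),
    age_adj = fill(raw$age_adj, defaults$age_adj),
    multipliers = fill(raw$multipliers, defaults$multipliers),
    effects = fill(raw$effects, defaults$effects),
    regimens = if (length(regimens)) regimens else defaults$regimens,
    costs = fill(raw$costs, defaults$costs),
    utilities = fill(raw$utilities, defaults$utilities),
    distributions = if (length(dists)) dists else defaults$distributions,
    life_table = life_table)
}

#' @rdname load_parameters
#' @param params A `cua_parameters` object.
#' @param embed_life_table Write the life table into the YAML file?
#' @export
write_parameters <- function(params, path, embed_life_table = TRUE) {
  validate_parameters(params)
  strip <- function(x) { attributes(x) <- list(names = names(x)); x }
  out <- list(
    settings = strip(params$settings),
    baseline_rates = params$baseline_rates,
    age_adj = params$age_adj,
    multipliers = params$multipliers,
    effects = params$effects,
    regimens = lapply(unname(params$regimens), strip),
    costs = params$costs,
    utilities = params$utilities,
    distributions = lapply(params$distributions, function(d) {
      d <- strip(d)
      d$paths <- lapply(d$paths, as.list)
      d
    }))
  if (embed_life_table) {
    out$life_table <- list(age = params$life_table$age,
                           all_cause_rate = params$life_table$all_cause_rate,
                           cv_rate = params$life_table$cv_rate)
  }
  jsonlite::write_json(out, path, digits = I(17), auto_unbox = TRUE,
                       pretty = TRUE, na = "null", null = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
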