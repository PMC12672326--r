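#' Synthetic Gompertz-Makeham life table
#'
#' Generates an age-indexed life table with the statistical structure the
#' model assumes of national mortality statistics: all-cause mortality that
#' rises smoothly (exponentially) with age,
#' `all_cause(age) = makeham + a * exp(b * age)`, and a cardiovascular
#' share of deaths that grows linearly with age between
#' `cv_fraction_young` and `cv_fraction_old` over the table's age range.
#' The defaults put 60-year-old all-cause mortality near 0.7\% per year,
#' within the range of published East-Asian general-population rates; the
#' table is illustrative, not authoritative, and a measured life table can
#' be substituted through [read_life_table()] at any time. The generator is
#' fully deterministic given its specification.
#'
#' @param makeham Age-independent background mortality (per person-year).
#' @param gompertz_a Gompertz scale (per person-year).
#' @param gompertz_b Gompertz shape (per year of age).
#' @param cv_fraction_young,cv_fraction_old CV share of all-cause mortality
#'   at the youngest and oldest table age, each in (0, 1).
#' @param age_range Integer length-2: first and last age (years).
#' @return `life_table_spec()` a list of class `cua_life_table_spec`;
#'   `make_life_table()` a validated `cua_life_table`.
#' @export
life_table_spec <- function(makeham = 0.001, gompertz_a = 2e-5,
                            gompertz_b = 0.095,
                            cv_fraction_young = 0.2, cv_fraction_old = 0.45,
                            age_range = c(40L, 100L)) {
  spec <- list(makeham = makeham, gompertz_a = gompertz_a,
               gompertz_b = gompertz_b,
               cv_fraction_young = cv_fraction_young,
               cv_fraction_old = cv_fraction_old,
               age_range = as.integer(age_range))
  class(spec) <- "cua_life_table_spec"
  if (makeham < 0 || gompertz_a < 0) stop("mortality rates must be non-negative")
  if (cv_fraction_young <= 0 || cv_fraction_young >= 1 ||
      cv_fraction_old <= 0 || cv_fraction_old >= 1)
    stop("cv fractions must lie in (0, 1)")
  if (cv_fraction_old < cv_fraction_young)
    stop("cv fraction must be non-decreasing with age")
  if (age_range[2] <= age_range[1]) stop("age_range must be increasing")
  spec
}

#' @rdname life_table_spec
#' @param spec A `cua_life_table_spec`.
#' @export
make_life_table <- function(spec = life_table_spec()) {
  ages <- seq(spec$age_range[1], spec$age_range[2])
  all_cause <- spec$makeham + spec$gompertz_a * exp(spec$gompertz_b * ages)
  frac <- spec$cv_fraction_young +
    (spec$cv_fraction_old - spec$cv_fraction_young) *
    (ages - ages[1]) / (ages[length(ages)] - ages[1])
  life_table(ages, all_cause, all_cause * frac)
}

#' Generated parameter sets for testing and validation
#'
#' Three tiers of fully generated inputs so every pipeline stage can be
#' exercised without external data:
#' \describe{
#'   \item{`degenerate`}{zero cardiovascular event and revascularization
#'     rates, no recurrence risk, and flat (age-constant) background
#'     mortality. The cohort trace then decays geometrically out of the
#'     event-free state, so lifetime discounted QALYs and costs have exact
#'     closed forms against which the discounting and half-cycle code paths
#'     can be checked independently of the transition logic.}
#'   \item{`simple`}{a 3-cycle horizon with three strategies and round-number
#'     rates, small enough to verify totals by hand.}
#'   \item{`paper_like`}{the full base case of [base_case_parameters()] with
#'     the synthetic life table.}
#' }
#'
#' @param seed Integer seed (kept for interface symmetry; generation is
#'   deterministic).
#' @param difficulty One of `"degenerate"`, `"simple"`, `"paper_like"`.
#' @return A validated `cua_parameters`.
#' @export
make_test_parameters <- function(seed = 1L,
                                 difficulty = c("paper_like", "degenerate", "simple")) {
  difficulty <- match.arg(difficulty)
  base <- base_case_parameters()
  if (difficulty == "paper_like") return(base)

  if (difficulty == "degenerate") {
    p <- base
    p$baseline_rates <- list(nonfatal_mi = 0, nonfatal_stroke = 0,
                             revascularization = 0)
    # flat mortality: Gompertz shape 0 collapses the table to constant rates
    p$life_table <- make_life_table(life_table_spec(
      makeham = 0.004, gompertz_a = 0.004, gompertz_b = 0,
      cv_fraction_young = 0.3, cv_fraction_old = 0.3))
    for (nm in c("rate.nonfatal_mi", "rate.nonfatal_stroke", "rate.revascularization"))
      p$distributions[[nm]]$base <- 0
    return(validate_parameters(p))
  }

  # simple: three strategies, three cycles, round numbers
  p <- base
  p$settings$horizon <- 3
  p$settings$start_age <- 60
  p$regimens <- base$regimens[c("Statins alone", "Evolocumab 140 mg Q2W",
                                "Inclisiran 300 mg Q6M")]
  keep <- vapply(p$distributions, function(d) {
    ok <- vapply(d$paths, function(path) {
      path[1] != "regimens" || path[2] %in% names(p$regimens)
    }, logical(1))
    all(ok)
  }, logical(1))
  p$distributions <- p$distributions[keep]
  p$life_table <- make_life_table(life_table_spec(
    makeham = 0.005, gompertz_a = 0.005, gompertz_b = 0,
    cv_fraction_young = 0.4, cv_fraction_old = 0.4))
  validate_parameters(p)
}
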