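# Independent vectorized re-computation of the per-cycle accounting, used as
# an arithmetic oracle against the engine's loop-based accumulation.
outcome_oracle <- function(tr, p, reg_name) {
  reg <- p$regimens[[reg_name]]
  s <- p$settings
  n <- tr$n_cycles
  occ <- tr$occupancy
  avg <- (occ[1:n, , drop = FALSE] + occ[2:(n + 1), , drop = FALSE]) / 2
  k <- 1:n
  vc <- (1 + s$discount_rate_costs)^(-k)
  ve <- (1 + s$discount_rate_outcomes)^(-k)
  vch <- (1 + s$discount_rate_costs)^(-(k - 0.5))
  veh <- (1 + s$discount_rate_outcomes)^(-(k - 0.5))
  alive <- rowSums(avg[, 1:9, drop = FALSE])

  cvec <- with(p$costs, c(0, mi_year1, mi_subsequent_annual, mi_year1,
                          mi_subsequent_annual, is_year1, is_subsequent_annual,
                          is_year1, is_subsequent_annual, 0, 0))
  uvec <- with(p$utilities, c(baseline, mi_year1, mi_post, mi2_year1, mi2_post,
                              is_year1, is_post, is2_year1, is2_post, 0, 0))
  drug <- if (reg$is_injectable) {
    reg$pens_per_administration * reg$price_per_pen *
      c(reg$administrations_year1, rep(reg$administrations_subsequent, n - 1))
  } else rep(0, n)
  new_cvd <- diff(occ[, "CVDeath"])

  cost <- sum((avg %*% cvec + alive * (p$costs$statin_annual + drug)) * vc) +
    sum((new_cvd * p$costs$cv_death +
           tr$revasc_events * p$costs$revascularization) * vch)
  inj <- if (reg$is_injectable) p$utilities$disutility_injection else 0
  qaly <- sum((avg %*% uvec + alive * inj) * ve) +
    sum(tr$revasc_events * p$utilities$disutility_revasc * veh)
  list(cost = unname(cost), qaly = unname(qaly))
}

test_that("one undiscounted person-year event-free accrues the statin cost and baseline utility", {
  p <- frozen_cohort_parameters(horizon = 1, discount = 0)
  o <- run_strategy(p, "Statins alone")
  expect_equal(o$total_cost, 846.1)
  expect_equal(o$total_qaly, 0.964)
  expect_equal(o$undiscounted_cost, o$total_cost)
  expect_equal(unname(o$cost_breakdown["statin"]), 846.1)
})

test_that("accumulated outcomes match an independent arithmetic oracle", {
  for (diff_level in c("simple", "paper_like")) {
    p <- make_test_parameters(difficulty = diff_level)
    for (reg in c("Statins alone", "Evolocumab 140 mg Q2W", "Inclisiran 300 mg Q6M")) {
      tr <- run_cohort(p, reg)
      o <- accumulate_outcomes(tr, p, reg)
      ora <- outcome_oracle(tr, p, reg)
      expect_equal(o$total_cost, ora$cost, tolerance = 1e-12, label = paste(diff_level, reg))
      expect_equal(o$total_qaly, ora$qaly, tolerance = 1e-12, label = paste(diff_level, reg))
    }
  }
})

test_that("cost breakdown components sum to the total and scale linearly in price", {
  p <- base_case_parameters()
  o <- run_strategy(p, "Evolocumab 140 mg Q2W")
  expect_equal(unname(sum(o$cost_breakdown)), o$total_cost, tolerance = 1e-9)
  expect_lt(o$total_cost, o$undiscounted_cost)
  expect_lt(o$total_qaly, o$undiscounted_qaly)

  p2 <- set_parameter(p, "price_per_pen.evolocumab",
                      2 * p$regimens[["Evolocumab 140 mg Q2W"]]$price_per_pen)
  o2 <- run_strategy(p2, "Evolocumab 140 mg Q2W")
  expect_equal(unname(o2$cost_breakdown["pcsk9_drug"]),
               2 * unname(o$cost_breakdown["pcsk9_drug"]), tolerance = 1e-12)
  expect_equal(o2$total_qaly, o$total_qaly)
})

test_that("discounting follows (1+d)^-k and totals shrink as the rate grows", {
  expect_identical(discount_factor(0, 0.05), 1)
  expect_equal(discount_factor(1, 0.05), 0.95238095238095233, tolerance = 1e-15)
  expect_equal(discount_factor(7, 0), 1)
  expect_error(discount_factor(1, -0.01), "non-negative")

  p <- base_case_parameters()
  res <- lapply(c(0, 0.03, 0.05, 0.08), function(d) {
    p$settings$discount_rate_costs <- d
    p$settings$discount_rate_outcomes <- d
    run_strategy(p, "Evolocumab 140 mg Q2W")
  })
  cost <- vapply(res, function(o) o$total_cost, numeric(1))
  qaly <- vapply(res, function(o) o$total_qaly, numeric(1))
  expect_true(all(diff(cost) < 0))
  expect_true(all(diff(qaly) < 0))
})

test_that("ICUR divides unrounded increments and rejects equal effectiveness", {
  out <- as_outcomes(c("ref", "b"), c(13706.18, 24815.45), c(12.32, 12.74))
  expect_equal(icur(out[[1]], out[[2]]), 26450.642857142859, tolerance = 1e-12)
  out2 <- as_outcomes(c("x", "y"), c(1000, 1100), c(10, 10.01))
  expect_equal(icur(out2[[1]], out2[[2]]), 10000)
  expect_error(icur(out2[[1]], out2[[1]]), "identical QALYs")
})

test_that("dominance classification handles strict and extended dominance", {
  # second strategy cheaper and more effective: first is dominated
  out <- as_outcomes(c("A", "B"), c(2000, 1500), c(1.0, 1.2))
  fr <- frontier(out, reference = "A")
  expect_equal(unname(fr$status[c("A", "B")]), c("dominated", "frontier"))

  # middle strategy with ICUR above the next option's: extended dominance
  out3 <- as_outcomes(c("A", "B", "C"), c(1000, 2000, 2500), c(1.0, 1.1, 1.5))
  expect_gt((2000 - 1000) / 0.1, (2500 - 2000) / 0.4)  # premise of the case
  fr3 <- frontier(out3, reference = "A")
  expect_equal(unname(fr3$status[c("A", "B", "C")]),
               c("frontier", "extended_dominated", "frontier"))
  expect_equal(unname(fr3$icur_frontier["C"]), 1500 / 0.5)
  expect_equal(unname(fr3$icur_vs_reference["B"]), 10000)
  expect_error(frontier(as_outcomes(c("A", "A"), c(1, 2), c(1, 2)), "A"),
               "duplicate")
})

test_that("dominance statuses do not depend on which strategy is the reference", {
  set.seed(11)
  out <- as_outcomes(letters[1:6], runif(6, 1e3, 5e4), runif(6, 10, 13))
  s1 <- frontier(out, reference = "a")$status
  s2 <- frontier(out, reference = "d")$status
  expect_identical(s1, s2)
})

test_that("the frontier agrees with an exhaustive hull oracle on random strategy sets", {
  set.seed(99)
  for (rep in 1:100) {
    m <- sample(2:8, 1)
    cost <- runif(m, 1e3, 6e4)
    qaly <- runif(m, 8, 14)
    labs <- sprintf("s%02d", 1:m)
    fr <- frontier(as_outcomes(labs, cost, qaly), reference = labs[1])
    got <- sort(match(names(fr$status)[fr$status == "frontier"], labs))
    expect_equal(got, hull_frontier_oracle(cost, qaly), label = paste("set", rep))
    # frontier ICURs non-decreasing, costs and QALYs strictly increasing
    tab <- fr$table[fr$table$status == "frontier", ]
    expect_true(all(diff(tab$total_cost) > 0))
    expect_true(all(diff(tab$total_qaly) > 0))
    ic <- tab$icur_frontier[-1]
    if (length(ic) > 1) expect_true(all(diff(ic) >= -1e-9))
  }
})

test_that("frontier results export to CSV with the expected columns", {
  p <- make_test_parameters(difficulty = "simple")
  fr <- frontier(run_strategies(p), "Statins alone")
  f <- tempfile(fileext = ".csv")
  write_results(fr, f)
  df <- read.csv(f, stringsAsFactors = FALSE)
  expect_equal(nrow(df), 3)
  expect_true(all(c("strategy", "total_cost", "total_qaly", "delta_cost",
                    "delta_qaly", "icur_vs_reference", "icur_frontier",
                    "status") %in% names(df)))
})
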