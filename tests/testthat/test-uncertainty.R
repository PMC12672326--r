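test_that("tornado entries bracket the base-case ICUR and degenerate ranges collapse", {
  p <- make_test_parameters(difficulty = "paper_like")
  target <- "Evolocumab 140 mg Q2W"

  # a parameter pinned to a zero-width range reproduces the base-case ICUR
  d <- p$distributions[["cost.mi_year1"]]
  d$low <- d$base; d$high <- d$base
  p$distributions[["cost.mi_year1"]] <- d
  tor <- one_way_sa(p, target, "Statins alone",
                    parameter_list = c("cost.mi_year1", "discount_rate",
                                       "price_per_pen.evolocumab",
                                       "rr_vascular_death"))
  base_icur <- attr(tor, "base_icur")
  pinned <- tor[tor$parameter == "cost.mi_year1", ]
  expect_equal(pinned$spread, 0)
  expect_equal(pinned$icur_at_low, base_icur, tolerance = 1e-12)
  expect_equal(pinned$icur_at_high, base_icur, tolerance = 1e-12)

  # benefits accrue late, so discounting them harder raises the ICUR
  dr <- tor[tor$parameter == "discount_rate", ]
  expect_lt(dr$icur_at_low, base_icur)
  expect_gt(dr$icur_at_high, base_icur)

  # entries are sorted by descending spread
  sp <- tor$spread[!is.na(tor$spread)]
  expect_true(all(diff(sp) <= 0))
  expect_error(one_way_sa(p, target, "Statins alone", "not_a_parameter"),
               "unknown parameter")
})

test_that("the ICUR rises monotonically with the target drug price", {
  p <- base_case_parameters()
  prices <- c(31.5, 39.4, 47.3)
  icurs <- vapply(prices, function(pr) {
    p2 <- set_parameter(p, "price_per_pen.evolocumab", pr)
    out <- run_strategies(p2, c("Statins alone", "Evolocumab 140 mg Q2W"))
    icur(out[["Statins alone"]], out[["Evolocumab 140 mg Q2W"]])
  }, numeric(1))
  expect_true(all(diff(icurs) > 0))
})

test_that("PSA is reproducible under a fixed seed and degenerate without sampled parameters", {
  p <- make_test_parameters(difficulty = "simple")
  a <- run_psa(p, n = 8, seed = 5)
  b <- run_psa(p, n = 8, seed = 5)
  expect_identical(a$draws, b$draws)
  expect_false(identical(a$draws$cost, run_psa(p, n = 8, seed = 6)$draws$cost))
  expect_equal(nrow(a$draws), 8 * 3)

  p0 <- p
  p0$distributions <- list()
  psa0 <- run_psa(p0, n = 4, seed = 1)
  det <- run_strategies(p0)
  for (nm in names(det)) {
    rows <- psa0$draws[psa0$draws$strategy == nm, ]
    expect_equal(rows$cost, rep(det[[nm]]$total_cost, 4), tolerance = 1e-12)
    expect_equal(rows$qaly, rep(det[[nm]]$total_qaly, 4), tolerance = 1e-12)
  }
})

test_that("CEAC probabilities partition the draws and obey limiting behaviour", {
  p <- make_test_parameters(difficulty = "simple")
  psa <- run_psa(p, n = 60, seed = 9)
  cc <- ceac(psa, wtp_grid = c(0, 2e4, 39875, 2e5))
  expect_equal(unname(rowSums(cc$prob)), rep(1, 4), tolerance = 1e-12)

  # at zero willingness-to-pay the cheapest strategy wins every draw
  cost <- matrix(psa$draws$cost, nrow = psa$n, byrow = TRUE,
                 dimnames = list(NULL, psa$strategies))
  cheapest <- table(factor(psa$strategies[max.col(-cost)], levels = psa$strategies))
  expect_equal(unname(cc$prob[1, ]), unname(as.vector(cheapest) / psa$n))
})

test_that("CEAC frequencies match a hand count on a constructed draw table", {
  draws <- data.frame(
    draw = rep(1:4, each = 2),
    strategy = rep(c("ref", "new"), 4),
    cost = c(100, 300, 100, 500, 100, 150, 100, 900),
    qaly = c(1.0, 1.02, 1.0, 1.01, 1.0, 1.05, 1.0, 0.99))
  psa <- structure(list(draws = draws, n = 4, seed = 0,
                        strategies = c("ref", "new"),
                        wtp_low = 100, wtp_high = 1e4),
                   class = "cua_psa")
  # at wtp 5000: NMB differences are 5000*dq - dc = 100-200, 50-400,
  # 250-50, -50-800  ->  "new" wins draw 3 only
  cc <- ceac(psa, wtp_grid = 5000)
  expect_equal(unname(cc$prob[1, ]), c(3 / 4, 1 / 4))
  expect_equal(prob_cost_effective(psa, "new", "ref", 5000), 1 / 4)
  # at wtp 50000 "new" wins draws 1, 2, 3
  expect_equal(prob_cost_effective(psa, "new", "ref", 5e4), 3 / 4)
})

test_that("doubling the PSA size moves acceptability estimates within sampling error", {
  p <- make_test_parameters(difficulty = "simple")
  wtp <- 39875
  p1 <- prob_cost_effective(run_psa(p, 150, seed = 21),
                            "Evolocumab 140 mg Q2W", "Statins alone", wtp)
  p2 <- prob_cost_effective(run_psa(p, 300, seed = 22),
                            "Evolocumab 140 mg Q2W", "Statins alone", wtp)
  pbar <- (150 * p1 + 300 * p2) / 450
  se <- sqrt(pbar * (1 - pbar) * (1 / 150 + 1 / 300))
  expect_lt(abs(p1 - p2), max(2 * se, 0.02))
})

test_that("horizon scenarios nest consistently with the base case", {
  p <- base_case_parameters()
  strategies <- c("Statins alone", "Evolocumab 140 mg Q2W")
  sc <- scenario_horizons(p, c(5, 30), strategies)
  base <- run_strategies(p, strategies)
  full <- sc[sc$horizon == 30, ]
  expect_equal(full$cost[full$strategy == "Evolocumab 140 mg Q2W"],
               base[["Evolocumab 140 mg Q2W"]]$total_cost, tolerance = 1e-12)
  expect_equal(full$qaly[full$strategy == "Statins alone"],
               base[["Statins alone"]]$total_qaly, tolerance = 1e-12)

  short <- sc[sc$horizon == 5 & sc$strategy == "Evolocumab 140 mg Q2W", ]
  expect_lt(short$delta_qaly,
            full$delta_qaly[full$strategy == "Evolocumab 140 mg Q2W"] / 3)
  expect_error(scenario_horizons(p, 80, strategies), "exceeds life-table")
})

test_that("price thresholds are exact fixed points and classify affordable regimens", {
  p <- base_case_parameters()
  out <- run_strategies(p, c("Statins alone", "Evolocumab 140 mg Q2W"))
  cur_icur <- icur(out[["Statins alone"]], out[["Evolocumab 140 mg Q2W"]])

  # willingness-to-pay equal to the current ICUR: threshold = current price
  pt <- price_threshold(p, "Evolocumab 140 mg Q2W", "Statins alone", cur_icur)
  expect_equal(pt$price, 39.4, tolerance = 1e-9)
  expect_equal(pt$icur_at_current_price, cur_icur, tolerance = 1e-12)

  # a generous threshold puts the admissible price above the current one
  pt2 <- price_threshold(p, "Evolocumab 140 mg Q2W", "Statins alone",
                         2 * cur_icur)
  expect_gt(pt2$price, 39.4)
  expect_true(pt2$no_reduction_needed)

  # a strict threshold demands a price cut
  pt3 <- price_threshold(p, "Evolocumab 140 mg Q2W", "Statins alone",
                         cur_icur / 2)
  expect_lt(pt3$price, 39.4)
  expect_false(pt3$no_reduction_needed)
  expect_lt(pt3$required_change_pct, 0)

  expect_error(price_threshold(p, "Statins alone", "Evolocumab 140 mg Q2W", 4e4),
               "does not gain QALYs")
})

test_that("lifetime cost is affine in the per-pen price", {
  p <- base_case_parameters()
  cost_at <- function(pr) {
    p$regimens[["Inclisiran 300 mg Q6M"]]$price_per_pen <- pr
    run_strategy(p, "Inclisiran 300 mg Q6M")$total_cost
  }
  probe <- c(0, 700, 1387.2)
  costs <- vapply(probe, cost_at, numeric(1))
  slope <- (costs[3] - costs[1]) / (probe[3] - probe[1])
  # the middle probe lies on the line through the endpoints
  expect_equal(costs[2], costs[1] + slope * probe[2],
               tolerance = 1e-12)
  # slope consistency on an out-of-sample point
  pred <- costs[1] + slope * 2000
  expect_equal(cost_at(2000), pred, tolerance = 1e-9)
})
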