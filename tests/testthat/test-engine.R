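test_that("life-years match the geometric closed form under constant
           mortality", {
  q <- 0.02
  p <- life_year_params(no_disease_params)
  p <- set_param(p, "discount_rate", 0)
  run <- run_cohort(NULL, p, flat_life_table(q),
                    make_baseline_distribution(1, 0),
                    stratum = "py30", half_cycle = FALSE)
  qc <- annual_to_cycle(q, 4)
  s <- (1 - qc)^(0:179)           # start-of-cycle survival
  expect_equal(run$totals[["qaly"]], sum(s) / 4, tolerance = 1e-10)
  # half-cycle correction averages adjacent survival
  run_hc <- run_cohort(NULL, p, flat_life_table(q),
                       make_baseline_distribution(1, 0),
                       stratum = "py30", half_cycle = TRUE)
  s_mid <- (s + (1 - qc)^(1:180)) / 2
  expect_equal(run_hc$totals[["qaly"]], sum(s_mid) / 4, tolerance = 1e-10)
})

test_that("trace is a valid cohort history", {
  s <- strategy(55, 79, 20)
  run <- run_cohort(s, base_params, base_life, base_start, stratum = "py30")
  expect_identical(nrow(run$trace), 181L)
  expect_true(all(abs(rowSums(run$trace) - 1) < 1e-12))
  expect_true(all(run$trace >= -1e-15))
  expect_true(all(diff(run$trace[, "Death"]) >= -1e-15))
  # discounted streams never exceed undiscounted ones
  expect_true(all(run$cycles$cost_disc <= run$cycles$cost + 1e-12))
  expect_true(all(run$cycles$qaly_disc <= run$cycles$qaly + 1e-12))
  # screening rounds occur annually within the window only
  ev_ages <- vapply(run$events, `[[`, numeric(1), "age")
  expect_equal(ev_ages, 55:79)
  expect_identical(run$events[[1]]$round, "baseline")
  expect_true(all(vapply(run$events[-1], `[[`, character(1), "round") ==
                    "annual"))
})

test_that("zero discounting equates discounted and undiscounted totals", {
  p <- set_param(base_params, "discount_rate", 0)
  s <- strategy(60, 74, 20)
  run <- run_cohort(s, p, base_life, base_start, stratum = "py30")
  expect_identical(run$totals[["cost"]], run$totals[["cost_disc"]])
  expect_identical(run$totals[["qaly"]], run$totals[["qaly_disc"]])
})

test_that("the engine is deterministic", {
  s <- strategy(50, 74, 30)
  r1 <- run_cohort(s, base_params, base_life, base_start, stratum = "py30")
  r2 <- run_cohort(s, base_params, base_life, base_start, stratum = "py30")
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$totals, r2$totals)
})

test_that("widening the screening window raises both cost and QALYs", {
  cache <- new.env(parent = emptyenv())
  out <- function(s) cohort_outcomes(s, base_params, base_life, base_start,
                                     cache = cache)
  narrow <- out(strategy(60, 74, 20))
  earlier <- out(strategy(55, 74, 20))
  later <- out(strategy(60, 79, 20))
  both <- out(strategy(55, 79, 20))
  none <- out(NULL)
  for (pair in list(list(none, narrow), list(narrow, earlier),
                    list(narrow, later), list(earlier, both),
                    list(later, both))) {
    expect_gte(pair[[2]]$cost, pair[[1]]$cost)
    expect_gte(pair[[2]]$qaly, pair[[1]]$qaly)
  }
})

test_that("blend_strata weights qualifying strata of the eligible
           population", {
  s30 <- strategy(65, 74, 30)
  bl <- blend_strata(s30, base_params, base_life, base_start)
  solo <- run_cohort(s30, base_params, base_life, base_start,
                     stratum = "py30")
  expect_identical(unname(bl$weights), 1)
  expect_identical(bl$cost, unname(solo$totals[["cost_disc"]]))
  expect_identical(bl$qaly, unname(solo$totals[["qaly_disc"]]))

  s20 <- strategy(65, 74, 20)
  bl20 <- blend_strata(s20, base_params, base_life, base_start)
  manual_cost <- sum(bl20$weights * vapply(bl20$runs, function(r)
    r$totals[["cost_disc"]], numeric(1)))
  expect_equal(bl20$cost, manual_cost)
  # male-only population gives the documented normalized stratum weight
  p <- base_params
  p$sex_mix <- c(male = 1, female = 0)
  blm <- blend_strata(s20, p, base_life, base_start)
  expect_equal(unname(blm$weights["py30"]), 0.3468 / (0.3036 + 0.3468))
})

test_that("common-population outcomes mix screened and unscreened strata
           by criterion", {
  s30 <- strategy(65, 74, 30)
  o <- cohort_outcomes(s30, base_params, base_life, base_start)
  w <- o$weights
  scr <- run_cohort(s30, base_params, base_life, base_start,
                    stratum = "py30")
  uns <- run_cohort(NULL, base_params, base_life, base_start,
                    stratum = "py20_29")
  expect_equal(o$cost,
               unname(w["py20_29"] * uns$totals[["cost_disc"]] +
                        w["py30"] * scr$totals[["cost_disc"]]))
  expect_equal(o$qaly,
               unname(w["py20_29"] * uns$totals[["qaly_disc"]] +
                        w["py30"] * scr$totals[["qaly_disc"]]))
})

test_that("trace CSV export round-trips the per-cycle streams", {
  run <- run_cohort(NULL, base_params, base_life, base_start,
                    stratum = "py30")
  f <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(run, f)
  df <- utils::read.csv(f)
  expect_identical(nrow(df), 180L)
  expect_equal(df$cost_disc, run$cycles$cost_disc, tolerance = 1e-12)
  expect_equal(df$NoLC, run$trace[1:180, "NoLC"], tolerance = 1e-12)
})
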