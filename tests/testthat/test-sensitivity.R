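s5 <- strategy(60, 79, 20)
s6 <- strategy(55, 79, 20)

base_icer_56 <- local({
  cache <- new.env(parent = emptyenv())
  a <- cohort_outcomes(s5, base_params, base_life, base_start, cache = cache)
  b <- cohort_outcomes(s6, base_params, base_life, base_start, cache = cache)
  icer(a, b)
})

test_that("method-of-moments fits reproduce the requested moments", {
  f <- fit_distribution(list(name = "u", base = 0.5, min = 0.4, max = 0.6,
                             dist = "beta"))
  expect_identical(f$dist, "beta")
  m <- f$shape1 / (f$shape1 + f$shape2)
  v <- f$shape1 * f$shape2 /
    ((f$shape1 + f$shape2)^2 * (f$shape1 + f$shape2 + 1))
  expect_equal(m, 0.5)
  expect_equal(sqrt(v), 0.2 / (2 * 1.96))

  g <- fit_distribution(list(name = "c", base = 50, min = 40, max = 60,
                             dist = "gamma"))
  expect_equal(g$shape / g$rate, 50)
  expect_equal(sqrt(g$shape) / g$rate, 20 / (2 * 1.96))

  # large-sample mean stays within the CLT band
  set.seed(99)
  draws <- g$sample(10000)
  expect_lt(abs(mean(draws) - 50), 3 * (20 / 3.92) / sqrt(10000))

  # degenerate range gives a point mass
  pm <- fit_distribution(list(name = "k", base = 3, min = 3, max = 3,
                              dist = "gamma"))
  expect_identical(pm$sample(5), rep(3, 5))

  # infeasible beta moments fall back to the published range
  expect_warning(
    fb <- fit_distribution(list(name = "w", base = 0.5, min = 0, max = 2.94,
                                dist = "beta")),
    "infeasible")
  expect_identical(fb$dist, "beta_rescaled")
})

test_that("one-way bounds at the base value return the base ICER", {
  ic <- one_way("cost_ldct", base_params, base_life, base_start, s5, s6,
                lo = 53.94, hi = 53.94)
  expect_equal(unname(ic["icer_lo"]), base_icer_56, tolerance = 1e-12)
  expect_equal(unname(ic["icer_hi"]), base_icer_56, tolerance = 1e-12)
  expect_error(one_way("nope", base_params, base_life, base_start, s5, s6),
               "unknown")
})

test_that("parameters with no pathway to either arm leave the ICER
           bit-identical", {
  # baseline-round rates at age 40 are never used by strategies starting
  # at 55 or 60
  for (nm in c("early_recall_baseline_40", "immediate_referral_baseline_40")) {
    ic <- one_way(nm, base_params, base_life, base_start, s5, s6)
    expect_identical(unname(ic["icer_lo"]), base_icer_56)
    expect_identical(unname(ic["icer_hi"]), base_icer_56)
  }
})

test_that("a lower discount rate lowers the screening ICER", {
  ic <- one_way("discount_rate", base_params, base_life, base_start, s5, s6)
  expect_lt(ic[["icer_lo"]], base_icer_56)
  expect_gt(ic[["icer_hi"]], base_icer_56)
})

test_that("PSA is reproducible and degenerates to the base case", {
  strategies <- list(no_screening = NULL, s5 = s5, s6 = s6)
  ps1 <- run_psa(5, 123, strategies, base_params, base_life, base_start)
  ps2 <- run_psa(5, 123, strategies, base_params, base_life, base_start)
  expect_identical(as.data.frame(ps1), as.data.frame(ps2))
  expect_error(run_psa(5, NULL, strategies, base_params, base_life,
                       base_start), "seed")

  # all-fixed distributions reproduce the deterministic totals exactly
  p_fix <- base_params
  for (nm in names(p_fix$uncertain)) p_fix$uncertain[[nm]]$dist <- "fixed"
  ps_fix <- run_psa(3, 7, strategies, p_fix, base_life, base_start)
  det6 <- cohort_outcomes(s6, p_fix, base_life, base_start)
  expect_true(all(ps_fix$cost[ps_fix$strategy == "s6"] == det6$cost))
  expect_true(all(ps_fix$qaly[ps_fix$strategy == "s6"] == det6$qaly))
  det_icer <- icer(cohort_outcomes(s5, p_fix, base_life, base_start), det6)
  for (i in 1:3) {
    it <- ps_fix[ps_fix$iteration == i, ]
    expect_identical(icer(it[it$strategy == "s5", c("cost", "qaly")],
                          it[it$strategy == "s6", c("cost", "qaly")]),
                     det_icer)
  }
})

test_that("CEAC probabilities partition and step at the deterministic
           ICER under point-mass PSA", {
  strategies <- list(no_screening = NULL, s5 = s5, s6 = s6)
  p_fix <- base_params
  for (nm in names(p_fix$uncertain)) p_fix$uncertain[[nm]]$dist <- "fixed"
  ps <- run_psa(2, 1, strategies, p_fix, base_life, base_start)
  grid <- c(1000, 15000, 20000, 21000, 22000, 23000, 30000, 60000)
  cc <- ceac(ps, grid)
  # exhaustive comparison: probabilities sum to 1 at each threshold
  sums <- tapply(cc$probability, cc$wtp, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))
  # each threshold puts all mass on the deterministic NB maximiser
  det <- lapply(strategies, function(s)
    cohort_outcomes(s, p_fix, base_life, base_start))
  for (w in grid) {
    nb <- vapply(det, function(o) net_benefit(o, w), numeric(1))
    top <- names(strategies)[which.max(nb)]
    expect_identical(cc$probability[cc$wtp == w & cc$strategy == top], 1)
  }
  # the more effective strategy's curve is non-decreasing in WTP
  p6 <- cc$probability[cc$strategy == "s6"]
  expect_true(all(diff(p6) >= 0))
})
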