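ref <- reference_outcomes()
row_of <- function(lab) ref[ref$label == lab, ]

test_that("ICER divides cost difference by QALY difference", {
  expect_equal(round(icer(row_of("no_screening"), row_of("s1")), 2),
               22875.00)
  expect_equal(round(icer(row_of("s5"), row_of("s6")), 2), 35000.00)
  expect_true(is.na(icer(c(100, 5), c(200, 5))))
  expect_equal(icer(c(100, 5), c(150, 6)), 50)
})

test_that("ICERs scale with costs and are invariant to argument-order
           sign flips", {
  a <- c(cost = 100, qaly = 5)
  b <- c(cost = 180, qaly = 5.4)
  expect_equal(icer(a, b), icer(b, a))
  k <- 3.7
  expect_equal(icer(a * c(k, 1), b * c(k, 1)), k * icer(a, b))
})

test_that("the reference outcomes reproduce the published frontier", {
  fr <- build_frontier(ref)
  expect_identical(fr$comparator, "no_screening")
  expect_identical(fr$frontier,
                   c("no_screening", paste0("s", 1:9)))
  g <- fr$outcomes
  cls <- stats::setNames(g$classification, g$label)
  expect_true(all(cls[c("guideline_2018", "guideline_2021",
                        "guideline_2022")] == "absolutely dominated"))
  expect_true(all(cls[paste0("s", 1:9)] == "efficient"))
  frontier_icers <- round(g$icer_frontier[match(paste0("s", 1:9),
                                                g$label)], 2)
  expect_equal(frontier_icers,
               c(22875.00, 23534.48, 23830.19, 24254.90, 26629.27,
                 35000.00, 62489.36, 219862.07, 244805.56))
  vs_none <- round(g$icer_vs_comparator, 2)
  expect_equal(vs_none[g$label == "s6"], 26469.12)
  expect_equal(vs_none[g$label == "guideline_2018"], 30799.76)
  expect_equal(vs_none[g$label == "guideline_2021"], 29842.55)
  expect_equal(vs_none[g$label == "guideline_2022"], 37154.11)
})

test_that("simple dominance cases classify correctly", {
  df <- data.frame(label = c("a", "b"),
                   cost = c(100, 150), qaly = c(5, 4.9))
  fr <- build_frontier(df)
  expect_identical(fr$outcomes$classification,
                   c("efficient", "absolutely dominated"))

  # exactly collinear middle strategy stays, with equal ICERs both sides
  df3 <- data.frame(label = c("a", "b", "c"),
                    cost = c(0, 100, 200), qaly = c(1, 2, 3))
  fr3 <- build_frontier(df3)
  expect_identical(fr3$frontier, c("a", "b", "c"))
  expect_equal(fr3$outcomes$icer_frontier, c(NA, 100, 100))

  # kinked middle strategy is extendedly dominated
  df4 <- data.frame(label = c("a", "b", "c"),
                    cost = c(0, 150, 200), qaly = c(1, 2, 3))
  fr4 <- build_frontier(df4)
  expect_identical(fr4$outcomes$classification[2], "extendedly dominated")
  expect_identical(fr4$frontier, c("a", "c"))
})

test_that("equal outcomes keep the strategy with fewer screening rounds", {
  df <- data.frame(label = c("wide", "narrow", "cheap"),
                   cost = c(100, 100, 50), qaly = c(5, 5, 4),
                   n_rounds = c(30, 10, 0))
  fr <- build_frontier(df)
  cls <- stats::setNames(fr$outcomes$classification, fr$outcomes$label)
  expect_identical(unname(cls["wide"]), "absolutely dominated")
  expect_identical(unname(cls["narrow"]), "efficient")
})

test_that("frontier matches a brute-force minimum-slope oracle", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    df <- data.frame(label = paste0("x", seq_len(n)),
                     cost = round(stats::runif(n, 0, 1000), 4),
                     qaly = round(stats::runif(n, 10, 11), 6))
    fr <- build_frontier(df)
    expect_identical(fr$frontier, oracle_frontier(df))
    # frontier ICERs are non-decreasing
    ics <- fr$outcomes$icer_frontier
    ics <- ics[!is.na(ics)][order(fr$outcomes$qaly[!is.na(ics)])]
    expect_true(all(diff(ics) >= -1e-9))
  }
})

test_that("WTP decision rule selects the published optima", {
  fr <- build_frontier(ref)
  expect_identical(optimal_at_wtp(fr, 37653), "s6")
  expect_identical(optimal_at_wtp(fr, 25102), "s4")
  expect_true(is.na(optimal_at_wtp(fr, 12551)))
  expect_error(optimal_at_wtp(fr, 0), "wtp")
})

test_that("a higher WTP never selects a less effective strategy", {
  fr <- build_frontier(ref)
  grid <- seq(1000, 300000, by = 4999)
  picks <- vapply(grid, function(w) {
    lab <- optimal_at_wtp(fr, w)
    if (is.na(lab)) 0L else match(lab, fr$frontier)
  }, integer(1))
  expect_true(all(diff(picks) >= 0))
})

test_that("net benefit underpins the WTP selection", {
  expect_equal(net_benefit(c(cost = 100, qaly = 5), 0), -100)
  expect_equal(net_benefit(c(cost = 100, qaly = 5), 1000), 4900)
  fr <- build_frontier(ref)
  affordable <- fr$frontier[!is.na(fr$outcomes$icer_frontier[
    match(fr$frontier, fr$outcomes$label)])]
  affordable <- affordable[fr$outcomes$icer_frontier[
    match(affordable, fr$outcomes$label)] <= 37653]
  nbs <- vapply(affordable, function(lab)
    net_benefit(row_of(lab), 37653), numeric(1))
  expect_identical(names(which.max(nbs)), "s6")
  expect_error(net_benefit(c(100, 5), -1), "wtp")
})

test_that("guideline comparison recovers the published QALY increment", {
  dq <- row_of("guideline_2018")$qaly - row_of("guideline_2021")$qaly
  expect_equal(dq, 0.00364, tolerance = 1e-12)
  expect_gt(row_of("guideline_2018")$cost, row_of("guideline_2021")$cost)
})
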