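# Pipeline entry points tying the modules together, with CSV/JSON report
# writers. These functions, together with the packaged scripts, are the
# package's operational interface.

#' Base-case analysis over a strategy grid
#'
#' Runs every strategy plus the no-screening comparator on the common
#' modelled population and builds the efficiency frontier. Per-stratum
#' cohort runs are memoised across strategies sharing a screening window,
#' so the full 36-strategy grid needs only 38 cohort runs.
#'
#' @param params,life_table,baseline Model inputs; defaults are the
#'   packaged base case and synthetic fixtures.
#' @param strategies List of \code{ldct_strategy} objects; default is the
#'   36-strategy grid plus the three guideline strategies.
#' @param participation Screening attendance fraction.
#' @return An \code{ldct_frontier} whose outcomes table carries the
#'   strategy descriptors and discounted totals.
#' @export
run_basecase <- function(params = default_parameters(),
                         life_table = make_life_table(),
                         baseline = make_baseline_distribution(),
                         strategies = strategy_grid(include_guidelines = TRUE),
                         participation = 1) {
  cache <- new.env(parent = emptyenv())
  comp <- cohort_outcomes(NULL, params, life_table, baseline,
                          participation = participation, cache = cache)
  rows <- lapply(strategies, function(s) {
    o <- cohort_outcomes(s, params, life_table, baseline,
                         participation = participation, cache = cache)
    data.frame(label = s$label, start_age = s$start_age,
               stop_age = s$stop_age, criterion = s$criterion,
               cost = o$cost, qaly = o$qaly, n_rounds = .n_rounds(s))
  })
  outcomes <- rbind(
    data.frame(label = "no_screening", start_age = NA, stop_age = NA,
               criterion = NA, cost = comp$cost, qaly = comp$qaly,
               n_rounds = 0),
    do.call(rbind, rows))
  build_frontier(outcomes)
}

#' Scenario summary report
#'
#' Optimal strategy per willingness-to-pay multiple (1, 2, 3 times
#' per-capita GDP) for the national base case, the overdiagnosis and
#' participation scenarios, and the four regional profiles.
#'
#' @inheritParams run_basecase
#' @param participation_rate Attendance fraction for the participation
#'   scenario.
#' @param seed Seed recorded in regional profiles.
#' @return Data frame: \code{scenario}, \code{wtp_1x}, \code{wtp_2x},
#'   \code{wtp_3x} holding optimal strategy labels or \code{"None"}.
#' @export
run_scenarios <- function(params = default_parameters(),
                          life_table = make_life_table(),
                          baseline = make_baseline_distribution(),
                          strategies = strategy_grid(),
                          participation_rate = 0.356, seed = 1L) {
  pick <- function(fr, gdp) vapply(1:3, function(m) {
    lab <- optimal_at_wtp(fr, m * gdp)
    if (is.na(lab)) "None" else lab
  }, character(1))
  gdp <- params$gdp_per_capita

  base_fr <- run_basecase(params, life_table, baseline, strategies)
  od_fr <- run_basecase(apply_overdiagnosis(params), life_table, baseline,
                        strategies)
  part_fr <- run_basecase(params, life_table, baseline, strategies,
                          participation = participation_rate)

  rows <- list(
    data.frame(scenario = "national_basecase",
               t(stats::setNames(pick(base_fr, gdp),
                                 c("wtp_1x", "wtp_2x", "wtp_3x")))),
    data.frame(scenario = "overdiagnosis",
               t(stats::setNames(pick(od_fr, gdp),
                                 c("wtp_1x", "wtp_2x", "wtp_3x")))),
    data.frame(scenario = "participation",
               t(stats::setNames(pick(part_fr, gdp),
                                 c("wtp_1x", "wtp_2x", "wtp_3x")))))
  for (reg in c("south", "east", "west", "north")) {
    rr <- run_regional(reg, params, life_table, baseline, strategies, seed)
    lab <- ifelse(is.na(rr$optimal$optimal), "None", rr$optimal$optimal)
    rows[[length(rows) + 1L]] <-
      data.frame(scenario = reg,
                 t(stats::setNames(lab, c("wtp_1x", "wtp_2x", "wtp_3x"))))
  }
  do.call(rbind, rows)
}

#' Write a frontier report to CSV
#'
#' Costs are rounded to 2 decimals, QALYs to 5 and ICERs to 2, mirroring
#' the conventional print precision; classifications are carried through.
#'
#' @param frontier An \code{ldct_frontier}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_frontier_csv <- function(frontier, path) {
  df <- frontier$outcomes
  df$cost <- round(df$cost, 2)
  df$qaly <- round(df$qaly, 5)
  df$icer_vs_comparator <- round(df$icer_vs_comparator, 2)
  df$icer_frontier <- round(df$icer_frontier, 2)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a frontier summary to JSON
#'
#' @param frontier An \code{ldct_frontier}.
#' @param path Output path.
#' @param seed Optional seed to record in the metadata.
#' @return \code{path}, invisibly.
#' @export
write_frontier_json <- function(frontier, path, seed = NULL) {
  obj <- list(comparator = frontier$comparator,
              frontier = frontier$frontier,
              outcomes = frontier$outcomes)
  if (!is.null(seed)) obj$seed <- as.integer(seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
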