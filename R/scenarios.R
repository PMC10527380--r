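# Scenario analyses: overdiagnosis, imperfect participation, and regional
# incidence/willingness-to-pay profiles. Each wrapper is a pure transform
# of its inputs; base parameter objects are never mutated.

#' Overdiagnosis scenario transform
#'
#' Inflates the screen-detection probability by \code{rr_diagnosis}
#' (capped at 1 inside the screen) and flags \code{rate} of screen-detected
#' cases as overdiagnosed: they incur the diagnostic workup, stage-I
#' treatment costs and stage-I utility but would never have progressed, so
#' their survival follows the no-cancer (other-cause only) curve. The
#' default values (1.15, 0.185) are the NLST-derived estimates; (1, 0)
#' is an exact identity.
#'
#' @param params An \code{ldct_params} object.
#' @param rr_diagnosis Detection inflation factor (>= 0).
#' @param rate Overdiagnosed fraction of screen-detected cases in \[0, 1\].
#' @return A modified copy of \code{params}.
#' @export
apply_overdiagnosis <- function(params, rr_diagnosis = 1.15, rate = 0.185) {
  stopifnot(inherits(params, "ldct_params"))
  if (!is.finite(rr_diagnosis) || rr_diagnosis < 0)
    stop("validation error: rr_diagnosis must be >= 0", call. = FALSE)
  .check_prob(rate, "overdiagnosis rate")
  p <- params
  p$overdiagnosis <- list(rr_diagnosis = rr_diagnosis, rate = rate)
  p
}

#' Imperfect-participation scenario
#'
#' Re-runs a strategy with the screening attendance fraction scaled in
#' every round; non-attenders follow unscreened natural history within
#' the same cohort, and attendance is drawn independently each year.
#'
#' @param strategy An \code{ldct_strategy}.
#' @param params,life_table,baseline Model inputs.
#' @param rate Participation fraction in (0, 1\]; the scenario value from
#'   a national community screening cohort is 0.356.
#' @return List with discounted \code{cost} and \code{qaly} on the common
#'   modelled population (see [cohort_outcomes()]).
#' @export
apply_participation <- function(strategy, params, life_table, baseline,
                                rate = 0.356) {
  if (!is.finite(rate) || rate <= 0 || rate > 1)
    stop("validation error: participation rate must lie in (0, 1]",
         call. = FALSE)
  cohort_outcomes(strategy, params, life_table, baseline,
                  participation = rate)
}

#' Regional scenario: incidence profile and local WTP thresholds
#'
#' Multiplies age-band incidence by the region's synthetic profile,
#' re-runs the full strategy grid and frontier, and selects the optimal
#' strategy at 1, 2 and 3 times the regional per-capita GDP.
#'
#' @param region \code{"east"}, \code{"west"}, \code{"south"} or
#'   \code{"north"}.
#' @param params,life_table,baseline Model inputs.
#' @param strategies Strategy list; defaults to the 36-strategy grid.
#' @param seed Seed recorded in the profile.
#' @return List with the \code{profile}, the regional
#'   \code{frontier} (an \code{ldct_frontier}) and \code{optimal}, a data
#'   frame of the optimal strategy label (or \code{NA}) per GDP multiple.
#' @export
run_regional <- function(region, params, life_table, baseline,
                         strategies = strategy_grid(), seed = 1L) {
  profile <- make_regional_profile(region, seed)
  p <- params
  p$incidence[names(profile$multipliers)] <-
    pmin(1, p$incidence[names(profile$multipliers)] * profile$multipliers)
  fr <- run_basecase(p, life_table, baseline, strategies = strategies)
  mult <- 1:3
  optimal <- data.frame(
    gdp_multiple = mult,
    wtp = mult * profile$gdp_per_capita,
    optimal = vapply(mult * profile$gdp_per_capita,
                     function(w) optimal_at_wtp(fr, w), character(1)))
  list(region = region, profile = profile, frontier = fr, optimal = optimal)
}
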