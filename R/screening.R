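# LDCT screening overlay. Screens occur at the start of a cycle, every 4th
# cycle while the cohort age lies in the strategy window. Attendance is
# participation x undiagnosed occupancy; detection moves preclinical mass
# to the diagnosed state of the same stage; imperfect specificity creates
# false positives among disease-free attendees, who incur a one-cycle
# disutility but stay disease-free.

# nearest-lower grid age for baseline management rates
.baseline_rate_row <- function(params, start_age) {
  ages <- params$baseline_rates$age
  ok <- ages[ages <= start_age]
  if (!length(ok))
    stop("configuration error: no baseline screening rates at or below age ",
         start_age, call. = FALSE)
  params$baseline_rates[params$baseline_rates$age == max(ok), ]
}

#' Cost of one screening round per attendee
#'
#' One LDCT scan, plus a repeat scan for the early-recall fraction, plus a
#' full diagnostic workup (biopsy and pre-diagnosis) for the
#' immediate-referral fraction. Baseline (first) rounds use
#' starting-age-specific management rates; annual rounds use the pooled
#' annual rates.
#'
#' @param round \code{"baseline"} or \code{"annual"}.
#' @param start_age Strategy starting age (selects baseline rates; ages
#'   between grid points use the nearest lower grid age).
#' @param params An \code{ldct_params} object.
#' @return Cost in USD per attendee.
#' @export
screen_round_cost <- function(round, start_age, params) {
  stopifnot(inherits(params, "ldct_params"))
  round <- match.arg(round, c("baseline", "annual"))
  if (round == "baseline") {
    r <- .baseline_rate_row(params, start_age)
    er <- r$early_recall
    ir <- r$immediate_referral
  } else {
    er <- params$annual_rates[["early_recall"]]
    ir <- params$annual_rates[["immediate_referral"]]
  }
  unname(params$costs[["ldct"]] + er * params$costs[["ldct"]] +
           ir * params$costs[["workup"]])
}

#' Apply one screening round to an occupancy vector
#'
#' Among attendees (participation times the undiagnosed occupancy), each
#' preclinical stage moves to the diagnosed state of the same stage with
#' probability equal to the test sensitivity (optionally inflated by the
#' overdiagnosis detection factor and capped at 1); a fraction
#' \code{params$overdiagnosis$rate} of detected mass is diverted to the
#' auxiliary overdiagnosed compartment. Disease-free attendees test
#' falsely positive with probability one minus specificity; they incur the
#' false-positive disutility for one cycle and remain disease free.
#' Detected cases are charged the diagnostic workup once; every attendee
#' is charged the round cost.
#'
#' @param occupancy Named occupancy vector over [health_states()]
#'   (sums to at most 1; any remaining mass is outside the screen's reach).
#' @param round \code{"baseline"} or \code{"annual"}.
#' @param params An \code{ldct_params} object.
#' @param strategy An \code{ldct_strategy} (provides the starting age for
#'   baseline rates).
#' @param participation Fraction of the eligible population attending, in
#'   \[0, 1\].
#' @return List with \code{occupancy} (post-screen vector),
#'   \code{overdx_add} (mass diverted to the overdiagnosed compartment)
#'   and \code{event}: cycle bookkeeping (detected mass by stage,
#'   false-positive mass, cost, disutility).
#' @export
apply_screen <- function(occupancy, round, params, strategy,
                         participation = 1) {
  stopifnot(inherits(params, "ldct_params"))
  if (!is.finite(participation) || participation < 0 || participation > 1)
    stop("validation error: participation must lie in [0, 1]", call. = FALSE)
  x <- occupancy
  sens <- min(1, params$sensitivity * params$overdiagnosis$rr_diagnosis)
  od_rate <- params$overdiagnosis$rate

  pre_idx <- paste0("pre_", .stages)
  detected <- x[pre_idx] * participation * sens
  overdx_add <- sum(detected) * od_rate
  to_dx <- detected * (1 - od_rate)

  x[pre_idx] <- x[pre_idx] - detected
  x[paste0("dx_", .stages)] <- x[paste0("dx_", .stages)] + to_dx

  fp_mass <- x[["NoLC"]] * participation * (1 - params$specificity)
  attendees <- participation * (occupancy[["NoLC"]] + sum(occupancy[pre_idx]))
  cost <- attendees * screen_round_cost(round, strategy$start_age, params) +
    sum(detected) * params$costs[["workup"]]

  list(occupancy = x,
       overdx_add = unname(overdx_add),
       event = list(round = round,
                    attendees = unname(attendees),
                    detected = stats::setNames(unname(detected), .stages),
                    fp_mass = unname(fp_mass),
                    cost = unname(cost),
                    disutility = unname(fp_mass * params$fp_disutility /
                                          params$cycles_per_year)))
}
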