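# Cohort engine: runs the closed cohort from entry (age 40) to the horizon
# (age 85) in 3-month cycles, composing the natural-history transitions
# with the screening overlay and accumulating discounted costs and QALYs.
# An auxiliary "Overdx" compartment (13th trace column, zero unless the
# overdiagnosis scenario is active) carries screen-detected cases that
# would never have progressed: they die only of other causes but accrue
# stage-I utility and stage-I treatment costs.

# per-state utility and per-cycle cost vectors over the 13 trace columns
.reward_vectors <- function(params) {
  u <- c(params$utilities[["no_lc"]],
         rep(params$utilities[["no_lc"]], 5),               # preclinical
         params$utilities[["I"]], params$utilities[["II"]],
         params$utilities[["III"]], params$utilities[["III"]],
         params$utilities[["IV"]],
         0,                                                  # death
         params$utilities[["I"]])                            # overdiagnosed
  cst <- c(rep(0, 6),
           params$costs[["tx_I"]], params$costs[["tx_II"]],
           params$costs[["tx_III"]], params$costs[["tx_III"]],
           params$costs[["tx_IV"]],
           0,
           params$costs[["tx_I"]])
  list(utility = u, cost = cst)
}

#' Run the cohort model for one stratum
#'
#' Simulates state occupancy over the full horizon for a single pack-year
#' stratum, with or without a screening strategy, and accumulates
#' per-cycle and total (discounted and undiscounted) costs and QALYs.
#' Cycle rewards use the state-membership half-cycle correction (the mean
#' of start- and end-of-cycle occupancy) by default; one-off event costs
#' (screening rounds, diagnostic workups) and the one-cycle false-positive
#' disutility are charged at the event. Discounting applies the annual
#' rate at the cycle's starting time: \eqn{(1+r)^{-t/4}} for cycle t.
#'
#' @param strategy An \code{ldct_strategy}, or \code{NULL} for the
#'   no-screening comparator.
#' @param params An \code{ldct_params} object.
#' @param life_table An \code{ldct_life_table}.
#' @param baseline Named baseline occupancy over [health_states()].
#' @param stratum Pack-year stratum run, \code{"py20_29"} or \code{"py30"}.
#' @param participation Screening attendance fraction in \[0, 1\]
#'   (independently each round).
#' @param half_cycle Use the half-cycle correction (default) or plain
#'   start-of-cycle rewards.
#' @return Object of class \code{ldct_trace}: occupancy trace, per-cycle
#'   reward streams and totals.
#' @export
run_cohort <- function(strategy, params, life_table, baseline,
                       stratum = "py30", participation = 1,
                       half_cycle = TRUE) {
  stopifnot(inherits(params, "ldct_params"))
  if (!is.null(strategy)) stopifnot(inherits(strategy, "ldct_strategy"))
  if (abs(sum(baseline) - 1) > 1e-9)
    stop("validation error: baseline occupancy must sum to 1", call. = FALSE)

  k <- params$cycles_per_year
  n_cycles <- (params$horizon_age - params$entry_age) * k
  sw <- .stratum_weights(params, 20)$sex_mix[, stratum]
  ts <- .transition_set(params, stratum, life_table, sw)
  rw <- .reward_vectors(params)
  r <- params$discount_rate

  cols <- c(health_states(), "Overdx")
  trace <- matrix(0, n_cycles + 1L, length(cols),
                  dimnames = list(NULL, cols))
  x <- c(as.numeric(baseline[health_states()]), 0)
  trace[1L, ] <- x

  cost <- qaly <- numeric(n_cycles)
  events <- list()

  pre_i <- .s_pre
  for (t in seq_len(n_cycles) - 1L) {
    age <- params$entry_age + t / k
    yr <- floor(age)
    ai <- yr - params$entry_age + 1L
    M <- ts$matrices[[ai]]
    qc <- ts$q_oc[[ai]]

    scr_cost <- 0
    fp_dis <- 0
    if (!is.null(strategy) && t %% k == 0L &&
        yr >= strategy$start_age && yr <= strategy$stop_age) {
      round <- if (yr == strategy$start_age) "baseline" else "annual"
      scr <- apply_screen(stats::setNames(x[1:.n_states], health_states()),
                          round, params, strategy, participation)
      x[1:.n_states] <- scr$occupancy
      x[13L] <- x[13L] + scr$overdx_add
      scr_cost <- scr$event$cost
      fp_dis <- scr$event$disutility
      events[[length(events) + 1L]] <-
        c(list(cycle = t, age = age), scr$event)
    }

    # diagnostic workup charged at clinical presentation this cycle
    clin_dx <- sum(x[pre_i] * .clinical_dx_prob(qc, params)) *
      params$costs[["workup"]]

    x_end <- c(as.numeric(x[1:.n_states] %*% M), x[13L] * (1 - qc))
    x_end[.s_death] <- x_end[.s_death] + x[13L] * qc

    basis <- if (half_cycle) (x + x_end) / 2 else x
    qaly[t + 1L] <- sum(basis * rw$utility) / k - fp_dis
    cost[t + 1L] <- sum(basis * rw$cost) + scr_cost + clin_dx

    x <- x_end
    trace[t + 2L, ] <- x
  }

  disc <- (1 + r)^(-(seq_len(n_cycles) - 1L) / k)
  structure(list(
    strategy = strategy, stratum = stratum,
    participation = participation, half_cycle = half_cycle,
    trace = trace,
    cycles = data.frame(cycle = seq_len(n_cycles) - 1L,
                        age = params$entry_age +
                          (seq_len(n_cycles) - 1L) / k,
                        cost = cost, qaly = qaly,
                        cost_disc = cost * disc, qaly_disc = qaly * disc),
    events = events,
    totals = c(cost = sum(cost), qaly = sum(qaly),
               cost_disc = sum(cost * disc),
               qaly_disc = sum(qaly * disc))
  ), class = "ldct_trace")
}

#' @export
print.ldct_trace <- function(x, ...) {
  lab <- if (is.null(x$strategy)) "no screening" else x$strategy$label
  cat(sprintf(
    "Cohort trace [%s, stratum %s]: %d cycles\n  discounted cost %.2f USD, discounted QALYs %.5f\n",
    lab, x$stratum, nrow(x$cycles), x$totals[["cost_disc"]],
    x$totals[["qaly_disc"]]))
  invisible(x)
}

#' Export a cohort trace as a per-cycle CSV
#'
#' @param trace An \code{ldct_trace}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  df <- cbind(trace$cycles,
              as.data.frame(trace$trace[seq_len(nrow(trace$cycles)), ]))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Population-weighted outcomes for the eligible population of a strategy
#'
#' Runs the cohort per qualifying pack-year stratum and mixes discounted
#' totals with weights proportional to each stratum's share of the
#' strategy's eligible population (sex mix times smoking prevalence times
#' stratum proportion). A 30-pack-year criterion therefore reduces to the
#' \code{py30} stratum run alone.
#'
#' @inheritParams run_cohort
#' @return List with \code{cost}, \code{qaly} (discounted totals per
#'   eligible person), stratum \code{weights} and the per-stratum runs.
#' @export
blend_strata <- function(strategy, params, life_table, baseline,
                         participation = 1, half_cycle = TRUE) {
  stopifnot(inherits(strategy, "ldct_strategy"))
  w <- .stratum_weights(params, strategy$criterion)$weights
  runs <- lapply(names(w), function(s)
    run_cohort(strategy, params, life_table, baseline, stratum = s,
               participation = participation, half_cycle = half_cycle))
  names(runs) <- names(w)
  cost <- sum(w * vapply(runs, function(r) r$totals[["cost_disc"]],
                         numeric(1)))
  qaly <- sum(w * vapply(runs, function(r) r$totals[["qaly_disc"]],
                         numeric(1)))
  list(cost = cost, qaly = qaly, weights = w, runs = runs)
}

#' Outcomes on the common modelled population
#'
#' All strategies are compared on one cohort: current smokers with at
#' least 20 pack-years (both Table strata pooled). Under a 30-pack-year
#' strategy the 20-29 stratum is not invited and follows unscreened
#' natural history; under no screening both strata are unscreened. This
#' common denominator makes every strategy's (cost, QALY) pair directly
#' comparable on a single cost-effectiveness plane.
#'
#' @inheritParams run_cohort
#' @param strategy An \code{ldct_strategy} or \code{NULL} (no screening).
#' @param cache Optional environment for memoising per-stratum runs across
#'   a strategy grid (keyed by window/stratum/screened).
#' @return List with discounted \code{cost} and \code{qaly} per person of
#'   the common population, and the stratum \code{weights}.
#' @export
cohort_outcomes <- function(strategy, params, life_table, baseline,
                            participation = 1, half_cycle = TRUE,
                            cache = NULL) {
  w <- .stratum_weights(params, 20)$weights
  get_run <- function(strat, stratum) {
    key <- paste(if (is.null(strat)) "none"
                 else paste(strat$start_age, strat$stop_age, sep = "-"),
                 stratum, participation, sep = "|")
    if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
    out <- run_cohort(strat, params, life_table, baseline, stratum = stratum,
                      participation = participation, half_cycle = half_cycle)
    if (!is.null(cache)) cache[[key]] <- out
    out
  }
  runs <- lapply(names(w), function(s) {
    screened <- !is.null(strategy) &&
      s %in% .qualifying_strata(strategy$criterion)
    get_run(if (screened) strategy else NULL, s)
  })
  names(runs) <- names(w)
  list(cost = sum(w * vapply(runs, function(r) r$totals[["cost_disc"]],
                             numeric(1))),
       qaly = sum(w * vapply(runs, function(r) r$totals[["qaly_disc"]],
                             numeric(1))),
       weights = w)
}
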