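# Natural-history transition dynamics: onset into preclinical stage I,
# per-cycle stage progression, clinical presentation and death. Other-cause
# death competes with disease transitions within a cycle: it is applied
# first at the life-table per-cycle rate, and the printed per-cycle disease
# probabilities are then allocated over the surviving mass, so rows can
# never exceed 1 while the published per-cycle values are kept intact.

# incidence band index for an integer age
.band_index <- function(age) {
  if (any(age < 40)) stop("age outside model horizon", call. = FALSE)
  pmin(floor((age - 40) / 5) + 1L, 10L)
}

#' Per-cycle lung-cancer onset probability
#'
#' Annual onset for a smoking stratum is the general-population age-band
#' incidence times the stratum relative risk; the result is converted to a
#' per-cycle probability under a constant hazard and capped at 1.
#'
#' @param age Age in years (40 to 85+).
#' @param stratum Pack-year stratum, \code{"py20_29"} or \code{"py30"}.
#' @param params An \code{ldct_params} object.
#' @return Per-cycle probability of transition from no lung cancer to
#'   preclinical stage I.
#' @export
onset_probability <- function(age, stratum, params) {
  stopifnot(inherits(params, "ldct_params"))
  if (!stratum %in% c("py20_29", "py30"))
    stop("validation error: unknown stratum '", stratum, "'", call. = FALSE)
  if (any(age < 40) || any(age > 120))
    stop("age outside model horizon", call. = FALSE)
  annual <- pmin(1, params$incidence[.band_index(age)] * params$rr[[stratum]])
  annual_to_cycle(annual, params$cycles_per_year)
}

#' Per-cycle transition matrix at a given age
#'
#' Builds the 12x12 row-stochastic matrix over [health_states()] for one
#' cycle at the given age: the no-lung-cancer row combines other-cause
#' death and stratum-specific onset; preclinical rows use the per-cycle
#' progression/presentation/death probabilities; diagnosed rows combine
#' other-cause death with the stage-at-diagnosis fatality; death is
#' absorbing.
#'
#' @param age Integer age in years.
#' @param stratum Pack-year stratum, \code{"py20_29"} or \code{"py30"}.
#' @param params An \code{ldct_params} object.
#' @param life_table An \code{ldct_life_table}.
#' @param sex_weights Named weights \code{c(male=, female=)} used to pool
#'   sex-specific mortality; defaults to the eligible mix of the stratum.
#' @return 12x12 matrix with unit row sums.
#' @export
build_matrix <- function(age, stratum, params, life_table,
                         sex_weights = NULL) {
  stopifnot(inherits(params, "ldct_params"))
  if (is.null(sex_weights))
    sex_weights <- .stratum_weights(params, 20)$sex_mix[, stratum]
  q_oc <- annual_to_cycle(.mortality_at(life_table, age, sex_weights),
                          params$cycles_per_year)

  S <- health_states()
  M <- matrix(0, .n_states, .n_states, dimnames = list(S, S))

  # no lung cancer: other-cause death, then onset among survivors
  onset <- onset_probability(age, stratum, params)
  M["NoLC", "Death"] <- q_oc
  M["NoLC", "pre_I"] <- (1 - q_oc) * onset
  M["NoLC", "NoLC"] <- (1 - q_oc) * (1 - onset)

  # preclinical stages: printed disease exits scaled onto survivors of
  # other-cause death; disease-specific death adds to the Death column
  for (s in .stages) {
    row <- paste0("pre_", s)
    ex <- params$progression[[s]]
    stay <- 1 - sum(ex)
    if (stay < -1e-12)
      stop("model inconsistency: preclinical stage ", s,
           " exits exceed 1", call. = FALSE)
    stay <- max(stay, 0)
    M[row, "Death"] <- q_oc + (1 - q_oc) * ex[["death"]]
    for (k in names(ex)) {
      if (k == "death") next
      col <- if (k == "dx") paste0("dx_", s) else paste0("pre_", k)
      M[row, col] <- M[row, col] + (1 - q_oc) * ex[[k]]
    }
    M[row, row] <- M[row, row] + (1 - q_oc) * stay
  }

  # diagnosed stages: stage fatality competes with other-cause death
  for (s in .stages) {
    row <- paste0("dx_", s)
    f <- params$fatality[[s]]
    M[row, "Death"] <- q_oc + (1 - q_oc) * f
    M[row, row] <- (1 - q_oc) * (1 - f)
  }

  M["Death", "Death"] <- 1
  M
}

# per-cycle clinical-presentation probability (preclinical -> diagnosed),
# net of other-cause death, per preclinical stage; used to cost the
# diagnostic workup at clinical presentation
.clinical_dx_prob <- function(q_oc, params) {
  vapply(.stages, function(s) (1 - q_oc) * params$progression[[s]][["dx"]],
         numeric(1))
}

# Transition matrices for every integer age of the horizon, plus the
# matching per-cycle other-cause death rates. ages run entry..horizon-1.
.transition_set <- function(params, stratum, life_table, sex_weights) {
  ages <- params$entry_age:(params$horizon_age - 1L)
  q_oc <- annual_to_cycle(.mortality_at(life_table, ages, sex_weights),
                          params$cycles_per_year)
  mats <- lapply(ages, build_matrix, stratum = stratum, params = params,
                 life_table = life_table, sex_weights = sex_weights)
  list(ages = ages, matrices = mats, q_oc = q_oc)
}

#' Export a transition matrix as CSV
#'
#' @inheritParams build_matrix
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_matrix_csv <- function(age, stratum, params, life_table, path) {
  M <- build_matrix(age, stratum, params, life_table)
  utils::write.csv(as.data.frame(M), path, row.names = TRUE)
  invisible(path)
}
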