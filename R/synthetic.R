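# Synthetic stand-ins for inputs the analysis needs but that are not
# publicly deposited: an age/sex life table, the baseline preclinical state
# distribution, and regional incidence profiles. These are deliberately
# simple parametric fixtures, not demographic estimates.

#' Synthetic age/sex life table
#'
#' Gompertz-form annual all-cause mortality for ages 40-100:
#' \eqn{q(a) = \min(0.7,\ c\, e^{b a} \cdot level)} with \eqn{b, c} fixed so
#' that \eqn{q(40) = 0.002} and \eqn{q(80) = 0.06} at \code{level = 1}.
#' Female mortality is 0.8 times the male curve. The generator is fully
#' deterministic; \code{seed} is recorded for provenance only.
#'
#' @param seed Integer recorded as an attribute.
#' @param level Positive multiplier on overall mortality.
#' @return Data frame (class \code{ldct_life_table}) with columns
#'   \code{age}, \code{male}, \code{female} (annual death probabilities).
#' @export
make_life_table <- function(seed = 1L, level = 1) {
  if (!is.finite(level) || level <= 0)
    stop("validation error: `level` must be > 0", call. = FALSE)
  age <- 40:100
  b <- log(0.06 / 0.002) / 40      # log(30)/40
  a0 <- 0.002 / exp(b * 40)
  male <- pmin(0.7, a0 * exp(b * age) * level)
  female <- pmin(0.7, 0.8 * a0 * exp(b * age) * level)
  structure(data.frame(age = age, male = male, female = female),
            class = c("ldct_life_table", "data.frame"),
            seed = as.integer(seed), level = level)
}

#' Constant-mortality life table
#'
#' Helper for analytic checks: every age carries the same annual death
#' probability.
#'
#' @param q Annual death probability applied to all ages and both sexes.
#' @return An \code{ldct_life_table}.
#' @export
flat_life_table <- function(q) {
  .check_prob(q, "life-table probability")
  age <- 40:100
  structure(data.frame(age = age, male = rep(q, length(age)),
                       female = rep(q, length(age))),
            class = c("ldct_life_table", "data.frame"),
            seed = NA_integer_, level = NA_real_)
}

# annual other-cause mortality at integer age, sex-weighted
.mortality_at <- function(life_table, age, sex_weights) {
  i <- match(age, life_table$age)
  if (any(is.na(i)))
    stop("life table does not cover age ", paste(age[is.na(i)], collapse = ","),
         call. = FALSE)
  sex_weights[["male"]] * life_table$male[i] +
    sex_weights[["female"]] * life_table$female[i]
}

#' Synthetic baseline state distribution at model entry
#'
#' Nearly the whole cohort enters without lung cancer; a small preclinical
#' mass (at most 1\%) is split across preclinical stages
#' I:II:IIIA:IIIB:IV = 50:20:10:10:10, reflecting the early-stage
#' predominance seen in first screening rounds. Diagnosed states and death
#' start empty. Deterministic; \code{seed} recorded only.
#'
#' @param seed Integer recorded as an attribute.
#' @param preclinical_mass Total preclinical fraction in \[0, 0.01\].
#' @return Named numeric vector over [health_states()] summing to 1.
#' @export
make_baseline_distribution <- function(seed = 1L, preclinical_mass = 0.004) {
  if (!is.finite(preclinical_mass) || preclinical_mass < 0 ||
      preclinical_mass > 0.01)
    stop("validation error: `preclinical_mass` must lie in [0, 0.01]",
         call. = FALSE)
  split <- c(I = 0.5, II = 0.2, IIIA = 0.1, IIIB = 0.1, IV = 0.1)
  x <- stats::setNames(numeric(.n_states), health_states())
  x["NoLC"] <- 1 - preclinical_mass
  x[paste0("pre_", names(split))] <- preclinical_mass * split
  attr(x, "seed") <- as.integer(seed)
  x
}

#' Synthetic regional incidence profile and willingness-to-pay
#'
#' Returns age-band incidence multipliers emulating the qualitative
#' regional contrasts the model explores (east: higher incidence shifted
#' younger; west: lower overall, especially under 60; south: moderately
#' elevated; north: at the national level), together with the regional
#' per-capita GDP used to form willingness-to-pay thresholds. Multipliers
#' are synthetic fixtures, not registry rates. Deterministic; \code{seed}
#' recorded only.
#'
#' @param region One of \code{"east"}, \code{"west"}, \code{"south"},
#'   \code{"north"}.
#' @param seed Integer recorded as an attribute.
#' @return List with \code{region}, \code{multipliers} (named by incidence
#'   band), \code{gdp_per_capita} (USD) and \code{wtp} = 3 x GDP.
#' @export
make_regional_profile <- function(region, seed = 1L) {
  regions <- c("east", "west", "south", "north")
  if (length(region) != 1L || !region %in% regions)
    stop("validation error: unknown region '", region, "'", call. = FALSE)
  bands <- c("40-44", "45-49", "50-54", "55-59", "60-64",
             "65-69", "70-74", "75-79", "80-84", "85+")
  young <- bands[1:4]
  mult <- stats::setNames(rep(1, length(bands)), bands)
  gdp <- switch(region, south = 15234, east = 17520, west = 8941,
                north = 7326)
  if (region == "east") {
    mult[young] <- c(1.35, 1.30, 1.25, 1.20)
    mult[setdiff(bands, young)] <- 1.05
  } else if (region == "west") {
    mult[young] <- 0.70
    mult[setdiff(bands, young)] <- 0.85
  } else if (region == "south") {
    mult[] <- 1.10
  }
  structure(list(region = region, multipliers = mult,
                 gdp_per_capita = gdp, wtp = 3 * gdp),
            seed = as.integer(seed), class = "ldct_regional_profile")
}

#' Write a life table to CSV
#' @param life_table An \code{ldct_life_table}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_life_table <- function(life_table, path) {
  utils::write.csv(as.data.frame(life_table), path, row.names = FALSE)
  invisible(path)
}

#' Read a life table from CSV
#' @param path CSV with columns age, male, female.
#' @return An \code{ldct_life_table}.
#' @export
read_life_table <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("age", "male", "female") %in% names(df)))
  .check_prob(c(df$male, df$female), "life-table probability")
  structure(df[, c("age", "male", "female")],
            class = c("ldct_life_table", "data.frame"),
            seed = NA_integer_, level = NA_real_)
}

#' Write a baseline state distribution to CSV
#' @param baseline Named occupancy vector over [health_states()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_baseline_distribution <- function(baseline, path) {
  utils::write.csv(data.frame(state = names(baseline),
                              fraction = as.numeric(baseline)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a baseline state distribution from CSV
#' @param path CSV with columns state, fraction.
#' @return Named occupancy vector over [health_states()].
#' @export
read_baseline_distribution <- function(path) {
  df <- utils::read.csv(path)
  x <- stats::setNames(df$fraction, df$state)[health_states()]
  if (any(is.na(x)) || abs(sum(x) - 1) > 1e-9)
    stop("validation error: baseline distribution must cover all states ",
         "and sum to 1", call. = FALSE)
  x
}
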