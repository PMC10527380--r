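#' Convert an annual risk to a per-cycle risk
#'
#' Constant-hazard conversion of an annual event probability to the
#' probability over one model cycle:
#' \eqn{p_{cycle} = 1 - (1 - p_{year})^{1/k}} for \eqn{k} cycles per year.
#'
#' @param risk_annual Annual event probability in \[0, 1\].
#' @param cycles_per_year Number of cycles per year (default 4, i.e.
#'   3-month cycles).
#' @return Per-cycle probability; compounding it \code{cycles_per_year}
#'   times recovers \code{risk_annual} exactly.
#' @examples
#' annual_to_cycle(0.2, 4)            # ~0.05426
#' 1 - (1 - annual_to_cycle(0.2, 4))^4  # 0.2
#' @export
annual_to_cycle <- function(risk_annual, cycles_per_year = 4L) {
  if (any(!is.finite(risk_annual)) || any(risk_annual < 0) || any(risk_annual > 1))
    stop("`risk_annual` must lie in [0, 1]", call. = FALSE)
  if (cycles_per_year < 1) stop("`cycles_per_year` must be >= 1", call. = FALSE)
  1 - (1 - risk_annual)^(1 / cycles_per_year)
}

#' Per-cycle fatality from a two-year survival probability
#'
#' Post-diagnosis fatality is parameterised from stage-specific two-year
#' survival: with 8 cycles in two years, the constant per-cycle death
#' probability satisfying \eqn{(1 - p)^8 = S_2} is
#' \eqn{p = 1 - S_2^{1/8}}.
#'
#' @param two_year_survival Survival probability at two years, in (0, 1].
#' @return Per-cycle death probability.
#' @export
fatality_from_survival <- function(two_year_survival) {
  if (any(!is.finite(two_year_survival)) || any(two_year_survival <= 0) ||
      any(two_year_survival > 1))
    stop("`two_year_survival` must lie in (0, 1]", call. = FALSE)
  1 - two_year_survival^(1 / 8)
}

# ---- parameter loading ------------------------------------------------------

.uncertain <- function(x, name) {
  if (!is.list(x) || is.null(x$base))
    stop("parameter '", name, "' must have a `base` value", call. = FALSE)
  out <- list(name = name,
              base = as.numeric(x$base),
              min = as.numeric(if (is.null(x$min)) x$base else x$min),
              max = as.numeric(if (is.null(x$max)) x$base else x$max),
              dist = if (is.null(x$dist)) "fixed" else as.character(x$dist))
  if (!out$dist %in% c("beta", "gamma", "fixed"))
    stop("parameter '", name, "': unknown distribution '", out$dist, "'",
         call. = FALSE)
  if (out$min > out$base || out$base > out$max)
    stop("parameter '", name, "': requires min <= base <= max", call. = FALSE)
  if (out$dist == "beta" && (out$min < 0 || out$max > 1))
    stop("parameter '", name, "': beta parameters must lie in [0, 1]",
         call. = FALSE)
  if (out$dist == "gamma" && out$min < 0)
    stop("parameter '", name, "': gamma parameters must be >= 0", call. = FALSE)
  out
}

.need <- function(cfg, key) {
  if (is.null(cfg[[key]]))
    stop("configuration error: missing key '", key, "'", call. = FALSE)
  cfg[[key]]
}

.check_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop("validation error: ", what, " outside [0, 1]", call. = FALSE)
  invisible(x)
}

#' Load and validate model parameters
#'
#' Reads a structured YAML configuration holding every model input: smoking
#' prevalence and pack-year strata, age-band lung-cancer incidence, relative
#' risks, per-cycle preclinical progression, post-diagnosis fatality,
#' screening performance and management rates, utilities, costs and the
#' discount rate. Each uncertain entry carries \code{base}, \code{min},
#' \code{max} and a distribution family (\code{beta}, \code{gamma} or
#' \code{fixed}) used by the sensitivity-analysis machinery.
#'
#' @param path Path to a YAML parameter file; defaults to the fixture
#'   shipped with the package.
#' @return A validated object of class \code{ldct_params}.
#' @seealso [default_parameters()], [param_table()], [set_param()]
#' @export
load_parameters <- function(path = system.file("extdata", "parameters.yaml",
                                               package = "ldctcea")) {
  cfg <- yaml::read_yaml(path)

  u <- list()  # registry of uncertain parameters
  grab <- function(node, name) {
    p <- .uncertain(node, name)
    u[[name]] <<- p
    p$base
  }

  prev <- .need(cfg, "smoking_prevalence")
  props <- .need(cfg, "packyear_proportions")
  rrs <- .need(cfg, "relative_risk")
  prog <- .need(cfg, "progression")
  fat <- .need(cfg, "fatality")
  scr <- .need(cfg, "screening")
  utils_ <- .need(cfg, "utilities")
  costs <- .need(cfg, "costs")

  inc_raw <- .need(cfg, "incidence")
  bands <- c("40-44", "45-49", "50-54", "55-59", "60-64",
             "65-69", "70-74", "75-79", "80-84", "85+")
  missing_bands <- setdiff(bands, names(inc_raw))
  if (length(missing_bands))
    stop("configuration error: missing incidence band(s) ",
         paste(missing_bands, collapse = ", "), call. = FALSE)
  incidence <- vapply(bands, function(b) as.numeric(inc_raw[[b]]), numeric(1))
  .check_prob(incidence, "incidence")

  baseline_ages <- c(40, 45, 50, 55, 60, 65)
  br <- lapply(baseline_ages, function(a) {
    node <- scr$baseline[[as.character(a)]]
    if (is.null(node))
      stop("configuration error: missing baseline screening rates for age ",
           a, call. = FALSE)
    c(early_recall = grab(node$early_recall,
                          paste0("early_recall_baseline_", a)),
      immediate_referral = grab(node$immediate_referral,
                                paste0("immediate_referral_baseline_", a)))
  })
  baseline_rates <- data.frame(
    age = baseline_ages,
    early_recall = vapply(br, `[[`, numeric(1), "early_recall"),
    immediate_referral = vapply(br, `[[`, numeric(1), "immediate_referral"))

  progression <- lapply(.stages, function(s) {
    node <- prog[[s]]
    if (is.null(node) && s != "IV")
      stop("configuration error: missing progression for stage ", s,
           call. = FALSE)
    out <- vapply(names(node), function(k) as.numeric(node[[k]]), numeric(1))
    .check_prob(out, paste("progression from stage", s))
    if (sum(out) > 1)
      stop("validation error: preclinical stage ", s,
           " outgoing probabilities sum to ", round(sum(out), 4), " > 1",
           call. = FALSE)
    out
  })
  names(progression) <- .stages

  params <- structure(list(
    cycles_per_year = as.integer(.need(cfg, "cycles_per_year")),
    entry_age = as.integer(.need(cfg, "entry_age")),
    horizon_age = as.integer(.need(cfg, "horizon_age")),
    discount_rate = grab(.need(cfg, "discount_rate"), "discount_rate"),
    gdp_per_capita = as.numeric(.need(cfg, "gdp_per_capita")),
    smoking_prevalence = c(
      male = grab(prev$male, "smoking_prevalence_male"),
      female = grab(prev$female, "smoking_prevalence_female")),
    packyear_props = list(
      male = c(py20_29 = grab(props$male$py20_29, "prop_py20_29_male"),
               py30 = grab(props$male$py30, "prop_py30_male")),
      female = c(py20_29 = grab(props$female$py20_29, "prop_py20_29_female"),
                 py30 = grab(props$female$py30, "prop_py30_female"))),
    incidence = incidence,
    rr = c(py20_29 = grab(rrs$py20_29, "rr_py20_29"),
           py30 = grab(rrs$py30, "rr_py30")),
    progression = progression,
    fatality = c(I = grab(fat$I, "fatality_I"),
                 II = grab(fat$II, "fatality_II"),
                 IIIA = grab(fat$IIIA, "fatality_IIIA"),
                 IIIB = grab(fat$IIIB, "fatality_IIIB"),
                 IV = grab(fat$IV, "fatality_IV")),
    sensitivity = grab(scr$sensitivity, "sensitivity"),
    specificity = grab(scr$specificity, "specificity"),
    baseline_rates = baseline_rates,
    annual_rates = c(
      early_recall = grab(scr$annual$early_recall, "early_recall_annual"),
      immediate_referral = grab(scr$annual$immediate_referral,
                                "immediate_referral_annual")),
    utilities = c(no_lc = grab(utils_$no_lc, "utility_no_lc"),
                  I = grab(utils_$I, "utility_I"),
                  II = grab(utils_$II, "utility_II"),
                  III = grab(utils_$III, "utility_III"),
                  IV = grab(utils_$IV, "utility_IV")),
    fp_disutility = grab(.need(cfg, "fp_disutility"), "fp_disutility"),
    costs = c(ldct = grab(costs$ldct, "cost_ldct"),
              workup = grab(costs$workup, "cost_workup"),
              tx_I = grab(costs$tx_I, "cost_tx_I"),
              tx_II = grab(costs$tx_II, "cost_tx_II"),
              tx_III = grab(costs$tx_III, "cost_tx_III"),
              tx_IV = grab(costs$tx_IV, "cost_tx_IV")),
    sex_mix = c(male = as.numeric(.need(cfg, "sex_mix")$male),
                female = as.numeric(cfg$sex_mix$female)),
    overdiagnosis = list(
      rr_diagnosis = as.numeric(.need(cfg, "overdiagnosis")$rr_diagnosis),
      rate = as.numeric(cfg$overdiagnosis$rate)),
    uncertain = u
  ), class = "ldct_params")

  .validate_params(params)
  params
}

.validate_params <- function(p) {
  .check_prob(p$smoking_prevalence, "smoking prevalence")
  .check_prob(unlist(p$packyear_props), "pack-year proportions")
  .check_prob(p$fatality, "post-diagnosis fatality")
  .check_prob(c(p$sensitivity, p$specificity), "screening performance")
  .check_prob(unlist(p$baseline_rates[, -1]), "baseline screening rates")
  .check_prob(p$annual_rates, "annual screening rates")
  .check_prob(p$utilities, "utilities")
  .check_prob(p$fp_disutility, "false-positive disutility")
  if (any(p$costs < 0)) stop("validation error: negative cost", call. = FALSE)
  if (p$discount_rate < 0) stop("validation error: negative discount rate",
                                call. = FALSE)
  if (abs(sum(p$sex_mix) - 1) > 1e-9)
    stop("validation error: sex mix must sum to 1", call. = FALSE)
  .check_prob(p$overdiagnosis$rate, "overdiagnosis rate")
  invisible(p)
}

#' Default base-case parameter set
#'
#' @return The validated \code{ldct_params} object built from the packaged
#'   configuration fixture.
#' @export
default_parameters <- function() load_parameters()

#' Write a parameter set back to YAML
#'
#' Serialises a parameter object (including uncertainty ranges and
#' distribution families) so that \code{load_parameters()} on the output
#' reproduces it.
#'
#' @param params An \code{ldct_params} object.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "ldct_params"))
  u <- params$uncertain
  node <- function(name) {
    p <- u[[name]]
    list(base = p$base, min = p$min, max = p$max, dist = p$dist)
  }
  bands <- names(params$incidence)
  cfg <- list(
    cycles_per_year = params$cycles_per_year,
    entry_age = params$entry_age,
    horizon_age = params$horizon_age,
    discount_rate = node("discount_rate"),
    gdp_per_capita = params$gdp_per_capita,
    smoking_prevalence = list(male = node("smoking_prevalence_male"),
                              female = node("smoking_prevalence_female")),
    packyear_proportions = list(
      male = list(py20_29 = node("prop_py20_29_male"),
                  py30 = node("prop_py30_male")),
      female = list(py20_29 = node("prop_py20_29_female"),
                    py30 = node("prop_py30_female"))),
    incidence = as.list(stats::setNames(as.numeric(params$incidence), bands)),
    relative_risk = list(py20_29 = node("rr_py20_29"),
                         py30 = node("rr_py30")),
    progression = lapply(params$progression, as.list),
    fatality = list(I = node("fatality_I"), II = node("fatality_II"),
                    IIIA = node("fatality_IIIA"), IIIB = node("fatality_IIIB"),
                    IV = node("fatality_IV")),
    screening = list(
      sensitivity = node("sensitivity"),
      specificity = node("specificity"),
      baseline = stats::setNames(lapply(params$baseline_rates$age, function(a) {
        list(early_recall = node(paste0("early_recall_baseline_", a)),
             immediate_referral = node(paste0("immediate_referral_baseline_", a)))
      }), as.character(params$baseline_rates$age)),
      annual = list(early_recall = node("early_recall_annual"),
                    immediate_referral = node("immediate_referral_annual"))),
    utilities = list(no_lc = node("utility_no_lc"), I = node("utility_I"),
                     II = node("utility_II"), III = node("utility_III"),
                     IV = node("utility_IV")),
    fp_disutility = node("fp_disutility"),
    costs = list(ldct = node("cost_ldct"), workup = node("cost_workup"),
                 tx_I = node("cost_tx_I"), tx_II = node("cost_tx_II"),
                 tx_III = node("cost_tx_III"), tx_IV = node("cost_tx_IV")),
    sex_mix = as.list(params$sex_mix),
    overdiagnosis = params$overdiagnosis)
  yaml::write_yaml(cfg, path, precision = 12)
  invisible(path)
}

#' Table of uncertain parameters
#'
#' @param params An \code{ldct_params} object.
#' @return Data frame with one row per named parameter: \code{name},
#'   \code{base}, \code{min}, \code{max}, \code{dist}.
#' @export
param_table <- function(params) {
  stopifnot(inherits(params, "ldct_params"))
  u <- params$uncertain
  data.frame(name = vapply(u, `[[`, character(1), "name"),
             base = vapply(u, `[[`, numeric(1), "base"),
             min = vapply(u, `[[`, numeric(1), "min"),
             max = vapply(u, `[[`, numeric(1), "max"),
             dist = vapply(u, `[[`, character(1), "dist"),
             row.names = NULL)
}

#' Override one named model parameter
#'
#' Applies a new value to the base model structure by the flat parameter
#' name used in [param_table()] (e.g. \code{"sensitivity"},
#' \code{"cost_ldct"}, \code{"utility_I"}). Used by the one-way and
#' probabilistic sensitivity analyses.
#'
#' @param params An \code{ldct_params} object.
#' @param name Parameter name from [param_table()].
#' @param value New numeric value.
#' @return A modified copy of \code{params}.
#' @export
set_param <- function(params, name, value) {
  stopifnot(inherits(params, "ldct_params"), length(value) == 1L)
  if (is.null(params$uncertain[[name]]))
    stop("validation error: unknown parameter '", name, "'", call. = FALSE)
  p <- params
  set_rate <- function(df, age, col, v) { df[df$age == age, col] <- v; df }
  if (name == "discount_rate") p$discount_rate <- value
  else if (name == "smoking_prevalence_male") p$smoking_prevalence["male"] <- value
  else if (name == "smoking_prevalence_female") p$smoking_prevalence["female"] <- value
  else if (grepl("^prop_", name)) {
    sex <- if (grepl("_male$", name)) "male" else "female"
    stratum <- if (grepl("py20_29", name)) "py20_29" else "py30"
    p$packyear_props[[sex]][stratum] <- value
  }
  else if (name == "rr_py20_29") p$rr["py20_29"] <- value
  else if (name == "rr_py30") p$rr["py30"] <- value
  else if (grepl("^fatality_", name))
    p$fatality[sub("^fatality_", "", name)] <- value
  else if (name == "sensitivity") p$sensitivity <- value
  else if (name == "specificity") p$specificity <- value
  else if (grepl("^early_recall_baseline_", name))
    p$baseline_rates <- set_rate(p$baseline_rates,
                                 as.numeric(sub(".*_", "", name)),
                                 "early_recall", value)
  else if (grepl("^immediate_referral_baseline_", name))
    p$baseline_rates <- set_rate(p$baseline_rates,
                                 as.numeric(sub(".*_", "", name)),
                                 "immediate_referral", value)
  else if (name == "early_recall_annual") p$annual_rates["early_recall"] <- value
  else if (name == "immediate_referral_annual")
    p$annual_rates["immediate_referral"] <- value
  else if (grepl("^utility_", name))
    p$utilities[sub("^utility_", "", name)] <- value
  else if (name == "fp_disutility") p$fp_disutility <- value
  else if (grepl("^cost_", name)) p$costs[sub("^cost_", "", name)] <- value
  else stop("internal error: no setter for '", name, "'", call. = FALSE)
  p$uncertain[[name]]$base <- value
  .validate_params(p)
  p
}

#' Fraction of each sex eligible for screening
#'
#' The eligible fraction is the product of the sex-specific current-smoking
#' prevalence and the proportion of smokers meeting the cumulative
#' pack-year criterion (20 pools the 20-29 and >=30 strata; 30 uses the
#' >=30 stratum alone).
#'
#' @param params An \code{ldct_params} object.
#' @param criterion Minimum pack-years, 20 or 30.
#' @return Named numeric vector \code{c(male=, female=)}.
#' @examples
#' \dontrun{eligible_fraction(default_parameters(), 30)["male"]  # ~0.257}
#' @export
eligible_fraction <- function(params, criterion) {
  stopifnot(inherits(params, "ldct_params"))
  if (!criterion %in% c(20, 30))
    stop("validation error: pack-year criterion must be 20 or 30",
         call. = FALSE)
  strata <- if (criterion == 20) c("py20_29", "py30") else "py30"
  vapply(c("male", "female"), function(sex) {
    unname(params$smoking_prevalence[sex] *
             sum(params$packyear_props[[sex]][strata]))
  }, numeric(1))
}

# strata qualifying for a pack-year criterion
.qualifying_strata <- function(criterion) {
  if (criterion == 20) c("py20_29", "py30") else "py30"
}

# normalized stratum weights (and per-stratum sex mix) in the eligible
# population, from sex mix x prevalence x stratum proportions
.stratum_weights <- function(params, criterion = 20) {
  strata <- .qualifying_strata(criterion)
  mass <- sapply(strata, function(s) {
    vapply(c("male", "female"), function(sex) {
      params$sex_mix[[sex]] * params$smoking_prevalence[[sex]] *
        params$packyear_props[[sex]][[s]]
    }, numeric(1))
  })
  mass <- matrix(mass, nrow = 2, dimnames = list(c("male", "female"), strata))
  tot <- sum(mass)
  if (tot <= 0) stop("validation error: empty eligible population",
                     call. = FALSE)
  list(weights = colSums(mass) / tot,
       sex_mix = sweep(mass, 2, colSums(mass), "/"))
}
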