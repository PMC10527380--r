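#' Health states of the cohort model
#'
#' The state space comprises 12 states: no lung cancer (\code{NoLC}),
#' five preclinical (asymptomatic, undiagnosed) stages
#' (\code{pre_I} ... \code{pre_IV}), five diagnosed stages
#' (\code{dx_I} ... \code{dx_IV}) and absorbing \code{Death}.
#' Preclinical occupants carry the no-lung-cancer utility until they are
#' diagnosed, either clinically or by screening; costs and utilities after
#' diagnosis depend on the stage at diagnosis only.
#'
#' @return Character vector of the 12 state labels, in canonical order.
#' @export
health_states <- function() {
  c("NoLC",
    "pre_I", "pre_II", "pre_IIIA", "pre_IIIB", "pre_IV",
    "dx_I", "dx_II", "dx_IIIA", "dx_IIIB", "dx_IV",
    "Death")
}

# canonical stage labels used throughout
.stages <- c("I", "II", "IIIA", "IIIB", "IV")

# internal index helpers
.s_nolc <- 1L
.s_pre <- 2:6
.s_dx <- 7:11
.s_death <- 12L
.n_states <- 12L
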