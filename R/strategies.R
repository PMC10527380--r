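#' Define a screening strategy
#'
#' A strategy is annual LDCT screening from \code{start_age} to
#' \code{stop_age} for current smokers meeting a minimum cumulative
#' pack-year criterion.
#'
#' @param start_age First age screened; one of 40, 45, 50, 55, 60, 65.
#' @param stop_age Last age screened; one of 69, 74, 79.
#' @param criterion Minimum pack-years for eligibility; 20 or 30.
#' @param label Optional strategy label; defaults to
#'   \code{"<start>-<stop>-<criterion>py"}.
#' @return An object of class \code{ldct_strategy}.
#' @export
strategy <- function(start_age, stop_age, criterion, label = NULL) {
  if (!start_age %in% c(40, 45, 50, 55, 60, 65))
    stop("validation error: start_age must be one of 40,45,50,55,60,65",
         call. = FALSE)
  if (!stop_age %in% c(69, 74, 79))
    stop("validation error: stop_age must be one of 69,74,79", call. = FALSE)
  if (!criterion %in% c(20, 30))
    stop("validation error: criterion must be 20 or 30", call. = FALSE)
  if (start_age >= stop_age)
    stop("validation error: start_age must be < stop_age", call. = FALSE)
  structure(list(
    start_age = as.integer(start_age),
    stop_age = as.integer(stop_age),
    interval = "annual",
    criterion = as.integer(criterion),
    label = if (is.null(label))
      sprintf("%d-%d-%dpy", start_age, stop_age, criterion) else label
  ), class = "ldct_strategy")
}

#' The full 36-strategy grid
#'
#' Cross-product of starting ages \{40..65\}, stopping ages \{69, 74, 79\}
#' and pack-year criteria \{20, 30\}.
#'
#' @param include_guidelines Also append the three Chinese
#'   guideline-recommended strategies (2018: 50-74, 20py; 2021: 50-74,
#'   30py; 2022: 45-74, 20py).
#' @return List of \code{ldct_strategy} objects (36, or 39 with
#'   guidelines).
#' @export
strategy_grid <- function(include_guidelines = FALSE) {
  grid <- expand.grid(start = c(40, 45, 50, 55, 60, 65),
                      stop = c(69, 74, 79),
                      criterion = c(20, 30))
  out <- mapply(function(a, b, c) strategy(a, b, c),
                grid$start, grid$stop, grid$criterion, SIMPLIFY = FALSE)
  if (include_guidelines) out <- c(out, guideline_strategies())
  out
}

#' Guideline-recommended screening strategies
#'
#' @return Named list of the three national guideline strategies.
#' @export
guideline_strategies <- function() {
  list(guideline_2018 = strategy(50, 74, 20, "guideline_2018"),
       guideline_2021 = strategy(50, 74, 30, "guideline_2021"),
       guideline_2022 = strategy(45, 74, 20, "guideline_2022"))
}

#' @export
print.ldct_strategy <- function(x, ...) {
  cat(sprintf("LDCT strategy %s: annual screening ages %d-%d, >=%d pack-years\n",
              x$label, x$start_age, x$stop_age, x$criterion))
  invisible(x)
}

# number of screening rounds a strategy offers (used for tie-breaking)
.n_rounds <- function(s) {
  if (is.null(s)) 0L else s$stop_age - s$start_age + 1L
}
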