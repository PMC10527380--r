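# Strategy comparison: ICERs, strict and extended dominance, efficiency
# frontier and willingness-to-pay decision rules.

#' Incremental cost-effectiveness ratio
#'
#' \eqn{(cost_b - cost_a) / (QALY_b - QALY_a)}, in USD per QALY. With no
#' QALY difference the ratio is undefined and \code{NA} is returned; the
#' dominance logic, not the ICER, handles such pairs.
#'
#' @param a,b Outcomes: either lists/rows with elements \code{cost} and
#'   \code{qaly}, or numeric vectors \code{c(cost, qaly)}.
#' @return ICER in USD per QALY (full precision), or \code{NA}.
#' @examples
#' icer(c(552.87, 15.64662), c(600.45, 15.64870))  # 22875
#' @export
icer <- function(a, b) {
  get <- function(x, i, nm) {
    if (!is.null(names(x)) && nm %in% names(x)) as.numeric(x[[nm]])
    else as.numeric(x[[i]])
  }
  dc <- get(b, 1, "cost") - get(a, 1, "cost")
  dq <- get(b, 2, "qaly") - get(a, 2, "qaly")
  if (dq == 0) return(NA_real_)
  dc / dq
}

#' Net monetary benefit
#'
#' \eqn{WTP \times QALYs - cost}.
#'
#' @param outcome List/row with \code{cost} and \code{qaly}, or numeric
#'   \code{c(cost, qaly)}.
#' @param wtp Willingness to pay, USD per QALY, non-negative.
#' @return Net monetary benefit in USD.
#' @export
net_benefit <- function(outcome, wtp) {
  if (any(wtp < 0)) stop("validation error: wtp must be >= 0", call. = FALSE)
  cost <- if (!is.null(names(outcome)) && "cost" %in% names(outcome))
    as.numeric(outcome[["cost"]]) else as.numeric(outcome[[1]])
  qaly <- if (!is.null(names(outcome)) && "qaly" %in% names(outcome))
    as.numeric(outcome[["qaly"]]) else as.numeric(outcome[[2]])
  wtp * qaly - cost
}

#' Efficiency frontier with strict and extended dominance
#'
#' Classifies every strategy as efficient, absolutely dominated (another
#' strategy costs no more and yields at least as many QALYs, with one
#' inequality strict) or extendedly dominated (its incremental ICER
#' exceeds that of a more effective alternative). The surviving frontier,
#' ordered by increasing QALYs, has non-decreasing pairwise ICERs
#' (strictly increasing unless strategies are exactly collinear).
#' Cost/QALY ties are broken in favour of the strategy with fewer
#' screening rounds when \code{n_rounds} is supplied, otherwise by input
#' order.
#'
#' @param outcomes Data frame with columns \code{label}, \code{cost},
#'   \code{qaly} and optionally \code{n_rounds}; must include the
#'   comparator (e.g. no screening) as a row.
#' @return Object of class \code{ldct_frontier}: the outcomes table with
#'   \code{classification}, \code{icer_vs_comparator} (vs the least costly
#'   row) and \code{icer_frontier} (vs the previous efficient strategy)
#'   columns, plus the ordered frontier labels.
#' @export
build_frontier <- function(outcomes) {
  df <- as.data.frame(outcomes)
  stopifnot(all(c("label", "cost", "qaly") %in% names(df)),
            nrow(df) >= 2)
  if (anyDuplicated(df$label))
    stop("validation error: duplicate strategy labels", call. = FALSE)
  n <- nrow(df)
  rounds <- if ("n_rounds" %in% names(df)) df$n_rounds else rep(NA_real_, n)

  # strict dominance, with the fewer-rounds tie-break on exact ties
  dominated <- vapply(seq_len(n), function(i) {
    any(vapply(seq_len(n), function(j) {
      if (i == j) return(FALSE)
      if (df$cost[j] <= df$cost[i] && df$qaly[j] >= df$qaly[i] &&
          (df$cost[j] < df$cost[i] || df$qaly[j] > df$qaly[i]))
        return(TRUE)
      if (df$cost[j] == df$cost[i] && df$qaly[j] == df$qaly[i]) {
        # identical outcomes: keep fewer screening rounds, else first row
        if (!is.na(rounds[i]) && !is.na(rounds[j]) && rounds[i] != rounds[j])
          return(rounds[j] < rounds[i])
        return(j < i)
      }
      FALSE
    }, logical(1)))
  }, logical(1))

  classification <- ifelse(dominated, "absolutely dominated", "efficient")

  # extended dominance on the survivors, in QALY order
  repeat {
    idx <- which(classification == "efficient")
    idx <- idx[order(df$qaly[idx], df$cost[idx])]
    if (length(idx) < 3) break
    ic <- vapply(seq_along(idx)[-1], function(k)
      icer(df[idx[k - 1], ], df[idx[k], ]), numeric(1))
    bad <- which(diff(ic) < 0)    # ICER decreases: extended dominance
                                  # (equal ICERs = collinear, retained)
    if (!length(bad)) break
    classification[idx[bad[1] + 1]] <- "extendedly dominated"
  }

  idx <- which(classification == "efficient")
  idx <- idx[order(df$qaly[idx], df$cost[idx])]

  comparator <- which.min(df$cost)
  df$classification <- classification
  df$icer_vs_comparator <- vapply(seq_len(n), function(i)
    if (i == comparator) NA_real_ else icer(df[comparator, ], df[i, ]),
    numeric(1))
  df$icer_frontier <- NA_real_
  if (length(idx) > 1)
    df$icer_frontier[idx[-1]] <- vapply(seq_along(idx)[-1], function(k)
      icer(df[idx[k - 1], ], df[idx[k], ]), numeric(1))

  structure(list(outcomes = df,
                 frontier = df$label[idx],
                 comparator = df$label[comparator]),
            class = "ldct_frontier")
}

#' @export
print.ldct_frontier <- function(x, ...) {
  cat("Efficiency frontier (", length(x$frontier), " strategies):\n  ",
      paste(x$frontier, collapse = " -> "), "\n", sep = "")
  df <- x$outcomes
  df$cost <- round(df$cost, 2)
  df$qaly <- round(df$qaly, 5)
  df$icer_vs_comparator <- round(df$icer_vs_comparator, 2)
  df$icer_frontier <- round(df$icer_frontier, 2)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Optimal strategy at a willingness-to-pay threshold
#'
#' The most effective frontier strategy whose incremental ICER (versus the
#' previous efficient strategy) does not exceed the threshold; this is
#' also the frontier strategy with the largest net monetary benefit among
#' those affordable. Returns \code{NA} (no screening strategy
#' cost-effective) when even the first frontier step exceeds the
#' threshold.
#'
#' @param frontier An \code{ldct_frontier}.
#' @param wtp Willingness to pay, USD per QALY, positive.
#' @return Strategy label, or \code{NA_character_}.
#' @export
optimal_at_wtp <- function(frontier, wtp) {
  stopifnot(inherits(frontier, "ldct_frontier"))
  if (!is.finite(wtp) || wtp <= 0)
    stop("validation error: wtp must be > 0", call. = FALSE)
  df <- frontier$outcomes
  labs <- frontier$frontier
  best <- NA_character_
  for (lab in labs) {
    ic <- df$icer_frontier[df$label == lab]
    if (is.na(ic)) next             # the comparator anchors the frontier
    if (ic <= wtp) best <- lab else break
  }
  best
}

#' Reference strategy outcomes for validation
#'
#' Discounted total cost (USD) and QALYs per eligible person for the nine
#' efficiency-frontier strategies, the three guideline-recommended
#' strategies and the no-screening comparator, as reported by the
#' reference analysis this model re-implements. Shipped as a plain-text
#' fixture and used to validate the ICER, dominance and decision-rule
#' machinery independently of the cohort engine.
#'
#' @return Data frame with columns \code{label}, \code{start_age},
#'   \code{stop_age}, \code{criterion}, \code{cost}, \code{qaly},
#'   \code{n_rounds}.
#' @export
reference_outcomes <- function() {
  df <- utils::read.csv(system.file("extdata",
                                    "reference_strategy_outcomes.csv",
                                    package = "ldctcea"))
  df$n_rounds <- ifelse(is.na(df$start_age), 0,
                        df$stop_age - df$start_age + 1)
  df
}
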