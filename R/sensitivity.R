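# One-way and probabilistic sensitivity analysis. Distribution fitting
# uses method-of-moments with mean at the base value and standard
# deviation derived from the published range treated as a 95% interval:
# sd = (max - min) / (2 * 1.96).

#' Fit a sampling distribution to an uncertain parameter
#'
#' Beta and gamma families are fitted by the method of moments with mean
#' equal to the base value and \code{sd = (max - min) / 3.92}. Zero-width
#' ranges and \code{dist = "fixed"} give a point mass at the base value.
#' Infeasible beta moments (variance at or above \eqn{m(1-m)}) fall back
#' to a beta refitted on the \[min, max\] interval, with a warning.
#'
#' @param p One row of [param_table()] as a list, or an element of
#'   \code{params$uncertain}: fields \code{name}, \code{base}, \code{min},
#'   \code{max}, \code{dist}.
#' @return List with \code{name}, \code{dist}, a \code{sample(n)} function
#'   and the fitted shape parameters.
#' @export
fit_distribution <- function(p) {
  stopifnot(all(c("name", "base", "min", "max", "dist") %in% names(p)))
  m <- p$base
  sd <- (p$max - p$min) / (2 * 1.96)
  point <- function() list(name = p$name, dist = "fixed",
                           sample = function(n) rep(m, n))
  if (p$dist == "fixed" || sd == 0) return(point())
  v <- sd^2
  if (p$dist == "gamma") {
    if (m <= 0) return(point())
    shape <- m^2 / v
    rate <- m / v
    return(list(name = p$name, dist = "gamma", shape = shape, rate = rate,
                sample = function(n) stats::rgamma(n, shape, rate)))
  }
  # beta
  if (v < m * (1 - m) && m > 0 && m < 1) {
    nu <- m * (1 - m) / v - 1
    a <- m * nu
    b <- (1 - m) * nu
    return(list(name = p$name, dist = "beta", shape1 = a, shape2 = b,
                sample = function(n) stats::rbeta(n, a, b)))
  }
  # infeasible on [0,1]: refit on the published range
  warning("parameter '", p$name,
          "': beta moments infeasible, refitting on [min, max]",
          call. = FALSE)
  width <- p$max - p$min
  m2 <- (m - p$min) / width
  v2 <- v / width^2
  if (v2 >= m2 * (1 - m2) || m2 <= 0 || m2 >= 1) return(point())
  nu <- m2 * (1 - m2) / v2 - 1
  a <- m2 * nu
  b <- (1 - m2) * nu
  list(name = p$name, dist = "beta_rescaled", shape1 = a, shape2 = b,
       sample = function(n) p$min + width * stats::rbeta(n, a, b))
}

#' One-way sensitivity of an ICER to a single parameter
#'
#' Re-runs both compared strategies (and their shared comparator
#' population) with the parameter at each bound and returns the resulting
#' pair of ICERs for strategy \code{b} versus strategy \code{a}.
#'
#' @param name Parameter name from [param_table()].
#' @param params,life_table,baseline Model inputs.
#' @param strategy_a,strategy_b The comparison: ICER of \code{b} vs
#'   \code{a}. \code{strategy_a = NULL} compares against no screening.
#' @param lo,hi Bounds; default to the parameter's published range.
#' @param participation Screening attendance fraction.
#' @return Named vector \code{c(icer_lo=, icer_hi=)}.
#' @export
one_way <- function(name, params, life_table, baseline,
                    strategy_a, strategy_b, lo = NULL, hi = NULL,
                    participation = 1) {
  u <- params$uncertain[[name]]
  if (is.null(u))
    stop("validation error: unknown parameter '", name, "'", call. = FALSE)
  lo <- if (is.null(lo)) u$min else lo
  hi <- if (is.null(hi)) u$max else hi
  if (lo == hi && u$min == u$max && u$base == u$min)
    stop("validation error: parameter '", name, "' has no range to vary",
         call. = FALSE)
  eval_at <- function(v) {
    p <- set_param(params, name, v)
    cache <- new.env(parent = emptyenv())
    a <- cohort_outcomes(strategy_a, p, life_table, baseline,
                         participation = participation, cache = cache)
    b <- cohort_outcomes(strategy_b, p, life_table, baseline,
                         participation = participation, cache = cache)
    icer(a, b)
  }
  c(icer_lo = eval_at(lo), icer_hi = eval_at(hi))
}

#' Tornado analysis over all ranged parameters
#'
#' Runs [one_way()] for every parameter with a non-degenerate range and
#' orders the results by descending ICER swing \code{|icer_hi - icer_lo|}.
#'
#' @inheritParams one_way
#' @param names Parameters to vary; defaults to all with min < max.
#' @return Data frame \code{parameter, lo, hi, icer_lo, icer_hi, swing},
#'   sorted by decreasing swing.
#' @export
tornado <- function(params, life_table, baseline, strategy_a, strategy_b,
                    names = NULL, participation = 1) {
  pt <- param_table(params)
  if (is.null(names)) names <- pt$name[pt$min < pt$max]
  rows <- lapply(names, function(nm) {
    u <- params$uncertain[[nm]]
    ic <- one_way(nm, params, life_table, baseline, strategy_a, strategy_b,
                  participation = participation)
    data.frame(parameter = nm, lo = u$min, hi = u$max,
               icer_lo = ic[["icer_lo"]], icer_hi = ic[["icer_hi"]])
  })
  out <- do.call(rbind, rows)
  out$swing <- abs(out$icer_hi - out$icer_lo)
  out[order(-out$swing), , drop = FALSE]
}

#' Probabilistic sensitivity analysis
#'
#' Draws every beta/gamma parameter from its fitted distribution,
#' independently across parameters but with common random numbers across
#' strategies within an iteration (one joint draw is applied to every
#' strategy), and records discounted cost/QALY totals per strategy per
#' iteration. Fixed parameters stay at base. Deterministic given
#' \code{seed}.
#'
#' @param n_iter Number of iterations (the reference analysis uses
#'   10,000).
#' @param seed Integer RNG seed (required, for reproducibility).
#' @param strategies Named list of \code{ldct_strategy} objects or
#'   \code{NULL} (no screening) entries to evaluate.
#' @param params,life_table,baseline Model inputs.
#' @param participation Screening attendance fraction.
#' @return Data frame of class \code{ldct_psa}: \code{iteration},
#'   \code{strategy}, \code{cost}, \code{qaly}; parameter draws attached
#'   as attribute \code{"draws"}.
#' @export
run_psa <- function(n_iter, seed, strategies, params, life_table, baseline,
                    participation = 1) {
  if (missing(seed) || is.null(seed))
    stop("validation error: an explicit `seed` is required", call. = FALSE)
  stopifnot(n_iter >= 1, length(strategies) >= 1)
  if (is.null(names(strategies)))
    names(strategies) <- vapply(strategies, function(s)
      if (is.null(s)) "no_screening" else s$label, character(1))

  pt <- param_table(params)
  sampled <- pt$name[pt$dist %in% c("beta", "gamma") & pt$min < pt$max]
  samplers <- lapply(sampled, function(nm)
    fit_distribution(params$uncertain[[nm]]))
  names(samplers) <- sampled

  set.seed(as.integer(seed))
  draws <- vapply(samplers, function(s) s$sample(n_iter),
                  numeric(n_iter))
  if (n_iter == 1) draws <- matrix(draws, nrow = 1,
                                   dimnames = list(NULL, sampled))

  res <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    p <- params
    for (nm in sampled) p <- set_param(p, nm, draws[i, nm])
    cache <- new.env(parent = emptyenv())
    outs <- lapply(strategies, function(s)
      cohort_outcomes(s, p, life_table, baseline,
                      participation = participation, cache = cache))
    res[[i]] <- data.frame(iteration = i,
                           strategy = names(strategies),
                           cost = vapply(outs, `[[`, numeric(1), "cost"),
                           qaly = vapply(outs, `[[`, numeric(1), "qaly"),
                           row.names = NULL)
  }
  out <- do.call(rbind, res)
  attr(out, "draws") <- draws
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("ldct_psa", "data.frame")
  out
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value, the fraction of PSA iterations in
#' which each strategy attains the maximal net monetary benefit within
#' the comparison set. Over an exhaustive set the probabilities sum to 1
#' at every threshold.
#'
#' @param samples Output of [run_psa()].
#' @param wtp_grid Numeric vector of thresholds (USD per QALY).
#' @param strategies Labels to compare; defaults to all in \code{samples}.
#' @return Data frame \code{wtp, strategy, probability}.
#' @export
ceac <- function(samples, wtp_grid, strategies = NULL) {
  stopifnot(nrow(samples) > 0)
  if (is.null(strategies)) strategies <- unique(samples$strategy)
  sub <- samples[samples$strategy %in% strategies, ]
  iters <- unique(sub$iteration)
  cost <- matrix(sub$cost[order(match(sub$strategy, strategies),
                                sub$iteration)],
                 nrow = length(iters), ncol = length(strategies),
                 dimnames = list(NULL, strategies))
  qaly <- matrix(sub$qaly[order(match(sub$strategy, strategies),
                                sub$iteration)],
                 nrow = length(iters), ncol = length(strategies),
                 dimnames = list(NULL, strategies))
  out <- lapply(wtp_grid, function(w) {
    nb <- w * qaly - cost
    best <- max.col(nb, ties.method = "first")
    data.frame(wtp = w, strategy = strategies,
               probability = vapply(seq_along(strategies), function(k)
                 mean(best == k), numeric(1)))
  })
  do.call(rbind, out)
}
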