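# Shared fixtures: built once per test run; everything is generated in
# code, nothing is read from disk except the packaged parameter file.

base_params <- default_parameters()
base_life <- make_life_table()
base_start <- make_baseline_distribution()

# params with no disease: zero incidence, empty preclinical start
no_disease_params <- local({
  p <- base_params
  p$incidence[] <- 0
  p
})

# set every state utility to 1 (life-years instead of QALYs)
life_year_params <- function(p) {
  for (nm in c("utility_no_lc", "utility_I", "utility_II", "utility_III",
               "utility_IV"))
    p <- set_param(p, nm, 1)
  set_param(p, "fp_disutility", 0)
}

# brute-force frontier oracle: greedy minimum-slope walk from the
# cheapest strategy; independent of build_frontier's removal loop
oracle_frontier <- function(df) {
  ord <- order(df$cost, -df$qaly)
  cur <- ord[1]
  hull <- cur
  repeat {
    cand <- which(df$qaly > df$qaly[cur] + 1e-15)
    if (!length(cand)) break
    slopes <- (df$cost[cand] - df$cost[cur]) /
      (df$qaly[cand] - df$qaly[cur])
    nxt <- cand[which.min(slopes)]
    if (min(slopes) < 0) { cur <- nxt; hull <- nxt; next }  # dominator
    cur <- nxt
    hull <- c(hull, nxt)
  }
  df$label[hull]
}
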