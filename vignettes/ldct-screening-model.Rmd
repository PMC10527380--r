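---
title: "A Markov cohort model for LDCT lung-cancer screening in current smokers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model for LDCT lung-cancer screening in current smokers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldctcea)
```

## The decision problem

Annual low-dose CT (LDCT) screening reduces lung-cancer mortality in heavy
smokers, but who exactly should be screened — from what age, until what age,
and above which cumulative smoking exposure — is contested. `ldctcea`
implements a deterministic Markov cohort model that compares 36 candidate
strategies (starting ages 40–65 in 5-year steps, stopping ages 69/74/79,
minimum exposure 20 or 30 pack-years) plus three national
guideline-recommended strategies against no screening, from the
healthcare-system perspective, and ranks them by incremental
cost-effectiveness.

## Model structure

The cohort enters at age 40 and is followed in 3-month cycles to age 85
(180 cycles). The state space has 12 states: no lung cancer; preclinical
(asymptomatic, undiagnosed) stages I, II, IIIA, IIIB, IV; diagnosed stages
I–IV; and absorbing death. Within a cycle a preclinical occupant may remain,
progress to a higher stage, present clinically (moving to the diagnosed
state of the same stage and incurring the diagnostic workup cost once), or
die; diagnosed occupants face a constant per-cycle stage-at-diagnosis
fatality. Disease progression after diagnosis is not modelled explicitly:
costs and utilities depend on the stage at diagnosis only.

Onset into preclinical stage I is the general-population age-band incidence
multiplied by the stratum relative risk (2.70 for 20–29 pack-years, 6.10 for
≥30), converted to a cycle probability by the constant-hazard identity
$p_{1/4} = 1 - (1-p_1)^{1/4}$ (`annual_to_cycle()`). Post-diagnosis
fatality derives from two-year survival via $p = 1 - S_2^{1/8}$
(`fatality_from_survival()`).

**Competing risks.** The parameter table lists disease exits and all-cause
mortality separately. Within a cycle the engine applies other-cause death
first, at the life-table per-cycle rate, and then allocates the printed
per-cycle disease probabilities over the surviving mass, with "stay" as the
residual. This keeps the printed probabilities intact and guarantees
row-stochastic matrices. The preclinical stage-specific death rates are
treated as lung-cancer-attributable (they originate from a disease model at
that grain) and are therefore composed with, not replaced by, the life
table. Diagnosed-state death is $q_{oc} + (1-q_{oc})\,f_s$, so with zero
other-cause mortality the diagnosed stage-I death probability is exactly
the printed 0.0121 per cycle.

## Screening overlay

Screening occurs at the start of a cycle, every 4th cycle while age lies in
the strategy window; this fixed event order (screen, then transition) is a
reproducibility choice, since discrete-event order is otherwise
underdetermined. Attendance is `participation` × undiagnosed occupancy
(base case 1; perfect attendance). Each preclinical attendee is detected
with probability equal to the sensitivity (0.8913) and moves to the
diagnosed state of the same stage — detection itself is not assumed to
stage-shift. Disease-free attendees test falsely positive with probability
1 − specificity (0.9436); they incur a utility decrement of 0.063 lasting
one cycle (0.063/4 QALYs undiscounted) and remain in the model's
no-lung-cancer state.

Round costs per attendee are one LDCT scan (USD 53.94) plus a repeat scan
for the early-recall fraction and a full diagnostic workup (USD 333.89)
for the immediate-referral fraction; first (baseline) rounds use
starting-age-specific management rates, later rounds the pooled annual
rates (`screen_round_cost()`). The published baseline rates exist only at
starting ages 40–65 in 5-year steps; ages between grid points use the
nearest lower grid age — piecewise-constant and auditable, where any
interpolation would be equally arbitrary. Screen-detected cases are charged
the diagnostic workup once, in addition to the aggregate referral-rate
costing; the two blocks represent management of all positives versus
confirmation of true positives.

## Rewards, discounting, half-cycle correction

Cycle QALYs are occupancy-weighted utilities divided by 4 (no clinical
lung cancer 0.933 — preclinical states carry this utility too, because the
utility is defined for people without a clinical diagnosis; diagnosed
stage I 0.84, II 0.79, III 0.79 shared by IIIA/IIIB, IV 0.77), minus the
false-positive decrement. Cycle costs are per-cycle treatment costs for
diagnosed occupants (stage III cost shared by IIIA/IIIB), charged every
cycle spent in a diagnosed state for the remaining lifetime — only
per-cycle figures are published, with maintenance treated as embedded —
plus screening and diagnosis event costs.

State rewards use the state-membership half-cycle correction: the mean of
start- and end-of-cycle occupancy (switchable to plain start-of-cycle
rewards via `half_cycle = FALSE`, since the exact variant used in the
original TreeAge implementation is not stated). One-off event costs are
charged at the event. Both streams are discounted at 5% per year at the
cycle's starting time, $(1.05)^{-t/4}$.

## The modelled population

Only sex-linked inputs are smoking prevalence/strata and mortality, and the
cohort sex mix is not published; the package assumes a 50/50 base
population (a config override) and derives each stratum's sex mix from
prevalence × stratum proportions, using it to weight sex-specific
mortality. All strategies are compared on one common cohort — current
smokers with ≥20 pack-years, the union of the two published strata — so
that every (cost, QALY) pair lives on a single cost-effectiveness plane: a
30-pack-year strategy simply leaves the 20–29 stratum unscreened
(`cohort_outcomes()`). `blend_strata()` retains the per-eligible-person
view, where a 30-pack-year strategy is exactly the ≥30-stratum run.

## Synthetic inputs

Three inputs of the original analysis are not publicly deposited and are
replaced by labelled synthetic generators; they are fixtures with the right
qualitative structure, not demographic estimates:

* **Life table** (`make_life_table()`): Gompertz curve
  $q(a) = \min(0.7, c\,e^{ba} \cdot \mathrm{level})$ anchored at
  $q(40)=0.002$ and $q(80)=0.06$, female = 0.8 × male — a smooth,
  monotone adult mortality curve of realistic magnitude.
* **Baseline state distribution** (`make_baseline_distribution()`): 0.4%
  preclinical mass at entry, split I:II:IIIA:IIIB:IV = 50:20:10:10:10,
  reflecting the early-stage predominance of first screening rounds;
  everyone else disease-free.
* **Regional profiles** (`make_regional_profile()`): fixed age-band
  incidence multipliers (east: elevated and shifted younger; west: lower,
  especially under 60; south: moderately elevated; north: national level)
  plus the published regional per-capita GDP values (USD 15,234 south;
  17,520 east; 8,941 west; 7,326 north) for willingness-to-pay thresholds.

Because the true life table, baseline distribution and TreeAge internals
are unavailable, absolute cost/QALY totals are **not** comparable with the
published table; the validated surface is (i) the ICER/dominance/decision
arithmetic, checked exactly against the published cost/QALY pairs shipped
as `reference_outcomes()`, and (ii) structural properties of the engine:
row-stochastic matrices, exact agreement with analytic matrix powers on a
reduced chain, mass conservation through screening, monotone response to
widening the screening window, and discounting identities. Passing these
shows the machinery is right, not that the synthetic cohort mimics any
real population.

## Strategy comparison

`build_frontier()` removes absolutely dominated strategies (another costs
no more and yields at least as many QALYs), then extendedly dominated ones
(incremental ICER exceeding that of a more effective option), leaving a
frontier with non-decreasing pairwise ICERs; exactly collinear strategies
are retained. Cost/QALY ties keep the strategy with fewer screening
rounds, favouring less intervention. `optimal_at_wtp()` implements the
decision rule: the most effective frontier strategy whose incremental ICER
is below the willingness-to-pay threshold, equivalently the affordable
frontier strategy with the largest net monetary benefit
(`net_benefit()`). Reports round costs to 2 decimals, QALYs to 5 and
ICERs to 2, with comparisons always at full precision.

## Sensitivity analysis

One-way analysis (`one_way()`, `tornado()`) re-runs both compared
strategies at each bound of one parameter. Parameters printed without a
range (incidence by age, the preclinical progression rates, mortality) are
held fixed; the discount rate is varied over 0–8%, a conventional range
for Chinese pharmacoeconomic practice. Probabilistic analysis
(`run_psa()`) draws every beta/gamma parameter by method-of-moments fits
with mean at base and SD = (max − min)/(2 × 1.96), the published range
being read as a 95% interval; draws are independent across parameters (no
correlation structure is published, and recall/referral rates are sampled
independently per age group) and common across strategies within an
iteration. Infeasible beta moments fall back to a beta refitted on the
published range, with a warning. `ceac()` converts samples into
cost-effectiveness acceptability curves via net-benefit maximisation. The
reference iteration count is 10,000; package checks run 2,000 (and the
degenerate reproducibility check at 100), sizes at which the
Monte-Carlo-error bound 0.5/√n already separates signal from noise.

Under the synthetic fixtures the tornado for the 55–79 versus 60–79
(≥20 pack-year) comparison ranks the discount rate, stage-I utility and
stage-I treatment cost as the top drivers, with relative risk, LDCT cost
and sensitivity following. The prominence of stage-I treatment cost
follows directly from charging per-cycle treatment for the remaining
lifetime of screen-detected early-stage cases, whose post-diagnosis
life expectancy is long; its rank relative to LDCT cost and sensitivity is
fixture-dependent.

## Scenarios

* **Overdiagnosis** (`apply_overdiagnosis()`): detection inflated by 1.15
  (capped at 1) and 18.5% of screen-detected cases flagged overdiagnosed.
  No mechanism is published for these two figures, so the package commits
  to one and exposes it: overdiagnosed cases enter an auxiliary
  compartment where they accrue the diagnostic workup, stage-I per-cycle
  treatment cost and stage-I utility, but die only of other causes — cost
  without counterfactual benefit. The engine trace carries this 13th
  column; it is identically zero in the base case, where the 12-state
  contract holds exactly.
* **Participation** (`apply_participation()`): attendance scaled to 35.6%
  in every round, drawn independently each year (whether non-attenders
  were permanently lost is not stated; independent annual attendance is
  the weaker assumption). Non-attenders follow unscreened natural history
  in the same cohort.
* **Regions** (`run_regional()`): incidence multiplied by the synthetic
  profile, the full grid re-run, and the optimum selected at 1/2/3 × the
  regional GDP per capita.

## Numerical choices and limitations

Probability arithmetic is all closed-form; the only tolerance-bearing
steps are the row-sum (1e−10) and conservation (1e−12) checks. The engine
is deterministic; all randomness flows through the PSA seed. A full
36-strategy grid evaluation memoises per-stratum runs by screening window
(38 cohort runs, under a second on one CPU).

Known limitations: current smokers only (no former/never smokers); no
stage shift at screen detection beyond earlier diagnosis; constant
post-diagnosis fatality (no tunnel states or cure fraction); treatment
cost accrues for the whole remaining lifetime in a diagnosed state;
nodule-management detail enters only through aggregate recall/referral
rates; no radiation-induced cancer risk; synthetic fixtures as above. The
command-line surface is intentionally thin: the exported functions and
the packaged scripts are the interface.

## A worked example

```{r example, eval = FALSE}
params <- default_parameters()
life <- make_life_table()
start <- make_baseline_distribution()

frontier <- run_basecase(params, life, start)
optimal_at_wtp(frontier, 3 * params$gdp_per_capita)

# validation of the decision arithmetic against the published pairs
fr_ref <- build_frontier(reference_outcomes())
round(fr_ref$outcomes$icer_frontier, 2)
```
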