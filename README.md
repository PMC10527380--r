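# ldctcea

Markov cohort cost-effectiveness analysis of risk-factor-based low-dose CT
(LDCT) lung-cancer screening in current smokers.

## What it does

Health-policy analysts comparing lung-cancer screening strategies need to
know not whether screening helps (it does) but *which eligibility rule* —
starting age, stopping age, minimum smoking exposure — buys health most
efficiently. `ldctcea` implements a deterministic Markov cohort model that
evaluates 36 annual-screening strategies (start 40–65, stop 69/74/79,
≥20 or ≥30 pack-years) plus three Chinese guideline-recommended strategies
against no screening, and ranks them on a single cost-effectiveness plane.

The model runs in 3-month cycles from age 40 to 85 over a 12-state space:
no lung cancer, preclinical stages I–IV (IIIA/IIIB split), diagnosed
stages I–IV, and death. Onset into preclinical stage I is
general-population incidence × stratum relative risk, converted with
`p_cycle = 1 − (1 − p_year)^{1/4}`; preclinical occupants progress, present
clinically or die; diagnosed occupants face constant per-cycle
stage-at-diagnosis fatality. Screening every 4th cycle detects preclinical
disease with sensitivity 0.8913, creates false positives at 1 − 0.9436
with a one-cycle utility decrement, and is costed through early-recall and
immediate-referral rates. Costs (2021 USD) and QALYs are discounted at 5%
per year with half-cycle correction.

Strategy comparison: incremental cost-effectiveness ratios
(`icer()` = Δcost/ΔQALY), efficiency-frontier construction with strict and
extended dominance (`build_frontier()`), willingness-to-pay decision rules
via net monetary benefit (`optimal_at_wtp()`, `net_benefit()`), one-way
and probabilistic sensitivity analysis with acceptability curves
(`tornado()`, `run_psa()`, `ceac()`), and overdiagnosis, participation and
regional scenarios (`apply_overdiagnosis()`, `apply_participation()`,
`run_regional()`).

Unpublished inputs — the life table, baseline state distribution and
regional incidence — are replaced by documented synthetic generators
(`make_life_table()`, `make_baseline_distribution()`,
`make_regional_profile()`). Absolute cohort totals therefore do not mirror
any published table; the decision arithmetic is validated exactly against
the published cost/QALY pairs shipped as `reference_outcomes()`.

## Worked example

```r
library(ldctcea)

fr <- build_frontier(reference_outcomes())
print(fr)
#> Efficiency frontier (10 strategies):
#>   no_screening -> s1 -> s2 -> s3 -> s4 -> s5 -> s6 -> s7 -> s8 -> s9
#>          label start_age stop_age criterion   cost     qaly ... icer_frontier
#>   no_screening        NA       NA        NA 552.87 15.64662 ...            NA
#>             s1        65       74        30 600.45 15.64870 ...      22875.00
#>  ...
#>             s6        55       79        20 775.74 15.65504 ...      35000.00
#>             s7        50       79        20 834.48 15.65598 ...      62489.36
#>  ...
#>  guideline_2018        50       74        20 809.74 15.65496 ...            NA

optimal_at_wtp(fr, 37653)   # 3x GDP per capita -> "s6" (55-79, >=20 pack-years)
optimal_at_wtp(fr, 25102)   # 2x GDP            -> "s4" (65-79, >=20 pack-years)
optimal_at_wtp(fr, 12551)   # 1x GDP            -> NA (no strategy cost-effective)
```

Each frontier ICER is the cost per extra QALY of moving to the next more
effective efficient strategy; the three guideline strategies are
absolutely dominated (another strategy is cheaper and more effective). At
a willingness-to-pay of three times per-capita GDP (USD 37,653/QALY),
annual screening at ages 55–79 for smokers of ≥20 pack-years is optimal.

Running the engine itself on the synthetic fixtures:

```r
params <- default_parameters()
fr2 <- run_basecase(params, make_life_table(), make_baseline_distribution())
optimal_at_wtp(fr2, 3 * params$gdp_per_capita)
```

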