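# Base-case model parameters with uncertainty ranges and distribution
# families for sensitivity analysis. Probabilities are annual unless the
# key says per-cycle (cycle = 3 months). Costs are 2021 USD.
# dist: beta | gamma | fixed. Ranges on utilities are +/-10%, most others
# +/-20% of base unless a source reported an exact interval.
cycles_per_year: 4
entry_age: 40
horizon_age: 85
discount_rate: {base: 0.05, min: 0.0, max: 0.08, dist: fixed}
gdp_per_capita: 12551

smoking_prevalence:
  male:   {base: 0.741, min: 0.718, max: 0.760, dist: beta}
  female: {base: 0.054, min: 0.040, max: 0.070, dist: beta}

# fraction of current smokers by cumulative pack-year stratum
packyear_proportions:
  male:
    py20_29: {base: 0.3036, min: 0.2429, max: 0.3643, dist: beta}
    py30:    {base: 0.3468, min: 0.2774, max: 0.4162, dist: beta}
  female:
    py20_29: {base: 0.1087, min: 0.0870, max: 0.1304, dist: beta}
    py30:    {base: 0.0651, min: 0.0521, max: 0.0781, dist: beta}

# annual lung-cancer incidence of the general population, by 5-year band
incidence:
  "40-44": 0.0001414
  "45-49": 0.0002867
  "50-54": 0.0005538
  "55-59": 0.0010131
  "60-64": 0.0016089
  "65-69": 0.0022856
  "70-74": 0.0029973
  "75-79": 0.0036277
  "80-84": 0.0040047
  "85+":   0.0032795

# relative risk of lung-cancer onset versus the general population
relative_risk:
  py20_29: {base: 2.70, min: 2.16, max: 3.24, dist: gamma}
  py30:    {base: 6.10, min: 4.88, max: 7.32, dist: gamma}

# per-cycle preclinical transition probabilities (no published range: fixed)
progression:
  I:    {II: 0.3558, IIIA: 0.0328, IIIB: 0.00000001, IV: 0.0869, dx: 0.0246, death: 0.1544}
  II:   {IIIA: 0.2480, IIIB: 0.0060, IV: 0.1290, dx: 0.0270, death: 0.1231}
  IIIA: {IIIB: 0.2246, IV: 0.1455, dx: 0.0811, death: 0.1527}
  IIIB: {IV: 0.0336, dx: 0.5177, death: 0.1853}
  IV:   {dx: 0.6584, death: 0.2978}

# per-cycle post-diagnosis fatality by stage at diagnosis
fatality:
  I:    {base: 0.0121, min: 0.0097, max: 0.0145, dist: beta}
  II:   {base: 0.0445, min: 0.0356, max: 0.0534, dist: beta}
  IIIA: {base: 0.0720, min: 0.0576, max: 0.0864, dist: beta}
  IIIB: {base: 0.1262, min: 0.1010, max: 0.1514, dist: beta}
  IV:   {base: 0.1986, min: 0.1589, max: 0.2383, dist: beta}

screening:
  sensitivity: {base: 0.8913, min: 0.7696, max: 0.9527, dist: beta}
  specificity: {base: 0.9436, min: 0.9388, max: 0.9481, dist: beta}
  # baseline (first-round) management rates by starting age
  baseline:
    "40": {early_recall: {base: 0.1442, min: 0.1154, max: 0.1730, dist: beta},
           immediate_referral: {base: 0.0134, min: 0.0107, max: 0.0161, dist: beta}}
    "45": {early_recall: {base: 0.1587, min: 0.1270, max: 0.1904, dist: beta},
           immediate_referral: {base: 0.0088, min: 0.0070, max: 0.0106, dist: beta}}
    "50": {early_recall: {base: 0.1534, min: 0.1227, max: 0.1841, dist: beta},
           immediate_referral: {base: 0.0122, min: 0.0098, max: 0.0146, dist: beta}}
    "55": {early_recall: {base: 0.1513, min: 0.1210, max: 0.1816, dist: beta},
           immediate_referral: {base: 0.0173, min: 0.0138, max: 0.0208, dist: beta}}
    "60": {early_recall: {base: 0.1511, min: 0.1209, max: 0.1813, dist: beta},
           immediate_referral: {base: 0.0284, min: 0.0227, max: 0.0341, dist: beta}}
    "65": {early_recall: {base: 0.1664, min: 0.1331, max: 0.1997, dist: beta},
           immediate_referral: {base: 0.0306, min: 0.0245, max: 0.0367, dist: beta}}
  annual:
    early_recall:       {base: 0.0442, min: 0.0354, max: 0.0530, dist: beta}
    immediate_referral: {base: 0.0237, min: 0.0190, max: 0.0284, dist: beta}

utilities:
  no_lc: {base: 0.933, min: 0.929, max: 0.951, dist: beta}
  I:     {base: 0.840, min: 0.756, max: 0.924, dist: beta}
  II:    {base: 0.790, min: 0.711, max: 0.869, dist: beta}
  III:   {base: 0.790, min: 0.711, max: 0.869, dist: beta}
  IV:    {base: 0.770, min: 0.693, max: 0.847, dist: beta}
fp_disutility: {base: 0.063, min: 0.057, max: 0.069, dist: beta}

costs:
  ldct:   {base: 53.94,   min: 43.15,   max: 64.73,   dist: gamma}
  workup: {base: 333.89,  min: 267.11,  max: 400.67,  dist: gamma}
  tx_I:   {base: 2258.33, min: 1806.66, max: 2710.00, dist: gamma}
  tx_II:  {base: 3739.69, min: 2991.75, max: 4487.63, dist: gamma}
  tx_III: {base: 4066.14, min: 3252.91, max: 4879.37, dist: gamma}
  tx_IV:  {base: 5224.76, min: 4179.81, max: 6269.71, dist: gamma}

# cohort sex mix of the base population before eligibility filtering
sex_mix:
  male: 0.5
  female: 0.5

# scenario knobs (base case: no overdiagnosis)
overdiagnosis:
  rr_diagnosis: 1.0
  rate: 0.0
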