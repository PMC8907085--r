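# Annotated cohort specification for t21screen::read_cohort_spec().
# Every distribution is summarized as a median with 2.5th and 97.5th
# percentiles; marker summaries are on the MoM scale, demographics on
# the natural scale. These values are the package defaults: a 40 + 40
# first-trimester trisomy-21 case-control cohort.
affected:
  n: 40                     # group size
  label: affected           # outcome class: affected | control
  age:                      # maternal age, years
    median: 29.92
    p_low: 24.11            # 2.5th percentile
    p_high: 37.79           # 97.5th percentile
  weight:                   # maternal weight, kg
    median: 53.30
    p_low: 39.13
    p_high: 74.73
  ga_days:                  # gestational age, days
    median: 87.00
    p_low: 69.10
    p_high: 96.98
  markers:                  # MoM summaries; names from marker_panel()
    papp_a:    {median: 0.37, p_low: 0.04, p_high: 1.65}
    free_bhcg: {median: 1.76, p_low: 0.15, p_high: 6.95}
    nt:        {median: 1.17, p_low: 0.59, p_high: 2.10}
    afp_l2:    {median: 1.59, p_low: 0.61, p_high: 3.61}
control:
  n: 40
  label: control
  age:     {median: 28.44, p_low: 20.35, p_high: 33.86}
  weight:  {median: 50.10, p_low: 42.90, p_high: 63.00}
  ga_days: {median: 89.00, p_low: 80.05, p_high: 97.00}
  markers:
    papp_a:    {median: 0.88, p_low: 0.20, p_high: 3.74}
    free_bhcg: {median: 1.02, p_low: 0.33, p_high: 3.98}
    nt:        {median: 0.87, p_low: 0.59, p_high: 1.15}
    afp_l2:    {median: 1.00, p_low: 0.39, p_high: 2.12}
# Inter-marker correlation on the log-MoM scale (Gaussian copula).
# Omit for independent markers; rows/columns follow the marker order
# above. Must be symmetric, unit diagonal, positive semidefinite.
#correlation:
#  - [1.0, 0.0, 0.0, 0.0]
#  - [0.0, 1.0, 0.0, 0.0]
#  - [0.0, 0.0, 1.0, 0.0]
#  - [0.0, 0.0, 0.0, 1.0]
seed: 20211108              # drives all generation randomness
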