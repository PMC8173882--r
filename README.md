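# fenocea

Cost-utility analysis of asthma management guided by fractional exhaled
nitric oxide (FeNO) monitoring versus standard symptom-guided therapy in
children aged 4–18 with mild-to-moderate allergic asthma.

FeNO is a noninvasive airway-inflammation biomarker; titrating therapy
against it reduces exacerbations but adds a monitoring cost. The question
for a payer — here, a middle-income health system costed in US$ at
COP$3,000 per dollar, from a societal perspective — is whether the saved
exacerbations pay for the monitoring. `fenocea` is for health economists
and guideline developers who want that analysis as reproducible, tested
code rather than a spreadsheet.

## The model

A three-state Markov cohort model with weekly cycles over a 12-month
horizon, no discounting. States: well-controlled (`W`, utility 0.99),
suboptimal control (`S`, 0.70), exacerbation (`A`, 0.31). The cohort
starts in `W` and evolves by a row-stochastic weekly matrix `P`; expected
QALYs and costs accumulate as

    QALY = Σ_c (π_c · u) / 52,     Cost = Σ_c (π_c · c + addon),

where `π_c` is the state distribution after cycle `c`, `u` the per-state
utilities and `c` the per-state weekly costs assembled from published
line items. The FeNO arm multiplies both transitions into `A` by a pooled
relative risk, RR 0.76 (95% CI 0.63–0.92), obtained by DerSimonian–Laird
random-effects meta-analysis:

    w_i = 1/se_i²,  Q = Σ w_i (y_i − ŷ)²,
    τ² = max(0, (Q − (k−1)) / (Σw − Σw²/Σw)),
    ŷ_RE = Σ y_i/(se_i²+τ²) / Σ 1/(se_i²+τ²).

Parameter uncertainty propagates by second-order Monte Carlo (Dirichlet
transition rows, beta utilities, gamma costs, lognormal RR — all
moment-matched to the published means and SDs), summarized as
cost-effectiveness plane quadrants, acceptability curves
(probability of maximal net monetary benefit `NMB = λ·QALY − Cost`), and
the expected value of perfect information
`EVPI = E[max_s NMB_s] − max_s E[NMB_s]`.

## Worked example

```r
library(fenocea)

# published baseline; per-state costs calibrated to the published totals,
# FeNO monitoring charged once per weekly cycle
config <- calibrate_state_costs(paper_fixture(feno_addon_basis = "weekly"))

run_base_case(config)
#> # A tibble: 2 × 3
#>   strategy  cost  qaly
#>   <chr>    <dbl> <dbl>
#> 1 standard 1452. 0.951
#> 2 feno     1334. 0.953

tidy(compare_strategies(run_base_case(config), comparator = "standard"))
#> # A tibble: 2 × 7
#>   strategy  cost  qaly delta_cost delta_qaly ce_ratio verdict
#>   <chr>    <dbl> <dbl>      <dbl>      <dbl>    <dbl> <chr>
#> 1 standard 1452. 0.951        NA    NA          1527. comparator
#> 2 feno     1334. 0.953      -119.    0.00195    1399. dominant
```

FeNO-guided management costs US$118.81 less per patient-year
(US$1333.57 vs US$1452.38) and yields slightly more QALYs — it *dominates*
standard therapy, so no incremental cost-effectiveness ratio applies.
Under parameter uncertainty:

```r
psa <- run_psa(config)          # 1000 iterations, seeded from the config
ce_plane_summary(psa)$quadrants
#> # A tibble: 5 × 3
#>   region         n fraction
#>   <chr>      <int>    <dbl>
#> 1 quadrant_1   478    0.478
#> 2 quadrant_2   521    0.521
#> 3 quadrant_3     0    0
#> 4 quadrant_4     1    0.001
#> 5 boundary       0    0

evpi(psa, wtp = 20000)
#> # A tibble: 1 × 5
#>     wtp e_max_nmb max_e_nmb  evpi pevpi
#>   <dbl>     <dbl>     <dbl> <dbl> <dbl>
#> 1 20000    17814.    17777.  36.5    NA
```

About half the simulations land in quadrant 2 (FeNO cheaper *and* more
effective) and nearly all the rest in quadrant 1 (more effective, more
costly); FeNO is essentially never less effective. At a willingness to
pay of US$20,000/QALY, eliminating all parameter uncertainty would be
worth about US$37 per patient. `autoplot()` methods draw the CE plane,
acceptability curve, tornado diagram and forest plot; `ceac()`,
`tornado_table()` and `dl_pool()` return the underlying tables.

A command-line wrapper covers the same pipeline
(`inst/cli/fenocea basecase|psa|ceac|evpi|owsa|meta|all`), reading YAML
configurations such as the shipped `inst/extdata/paper_baseline.yaml` and
writing CSVs plus a run manifest.

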