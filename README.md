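# stemipathway

Quantitative analysis of treatment delays for STEMI (ST-elevation
myocardial infarction) patients who present at a hospital without
catheterization capability and must be transferred to a PCI center.
Guidelines set the *door-in-door-out* goal at 30 minutes; in practice the
four sequential care stages — first medical contact (FMC), ECG acquisition
and review (ECG), ECG transmission and PCI-center feedback (TXF), and the
transfer wait (TWT) — routinely take far longer. The package is aimed at
health-services researchers and hospital quality teams who want to
quantify where a transfer pathway loses time and what stage-level
improvements would buy.

It provides four connected tools:

* **Synthetic cohorts.** Per-stage durations follow a calibrated
  two-component mixture: uniform on `(0, t*]` with probability `1 - e`,
  and `t* + Exp(mu)` with probability `e`, where `t*` is the stage's ideal
  time and `e` its exceedance fraction. Solving
  `mean = (1-e) t*/2 + e (t* + mu)` for `mu` makes the distribution match
  the observed stage mean *and* exceedance fraction exactly. Binary delay
  flags and two outcomes (reduced ejection fraction `EF`, elevated length
  of stay `LOS`) are linked to the flags by Boolean recipes.
* **Crisp-set QCA.** Truth-table construction, Quine–McCluskey
  minimization with exact Petrick-style cover search, complex /
  parsimonious / intermediate solutions, and necessity / sufficiency
  consistency and coverage. Expressions use the csQCA convention:
  `FMC*ecg*TWT` means FMC delayed AND ECG not delayed AND TWT delayed,
  terms joined by `+`.
* **System dynamics.** The pathway as a four-stage aging chain with
  first-order outflows `stock/tau`; improvement policies shrink residence
  times to `tau (1-u)`. Under constant arrivals the mean total time is
  `sum(tau_s (1-u_s))` by Little's law, which the explicit-Euler simulator
  reproduces; a hypoexponential closed form anchors the pulse response.
* **Monte-Carlo sensitivity.** Improvement fractions drawn uniformly from
  per-stage uncertainty intervals (defaults 10–50% for FMC/ECG, 10–60% for
  TXF/TWT), summarised as nested 50/75/95/100% percentile envelopes of the
  percent of patients retained in the pathway.

## Worked example

```r
library(stemipathway)

# a study-sized synthetic cohort of 29 patients
cohort <- generate_cohort(n = 29, seed = 7)
summarize_cohort(cohort)
#> Cohort summary (29 patients)
#> # A tibble: 4 × 5
#>   stage     n ideal_time mean_duration exceed_frac
#>   <chr> <int>      <dbl>         <dbl>       <dbl>
#> 1 FMC      29          2          5.86       0.690
#> 2 ECG      29          8         29.1        0.931
#> 3 TXF      29          5         72.5        0.724
#> 4 TWT      29         15         96.4        0.828
#> Mean total door-in-door-out time: 203.8 min
```

A 29-patient draw scatters around the calibration targets (means 7 / 28 /
76 / 78 min); at `n = 100000` the sample means land within 1% of them.
The full analysis chain runs from one configuration:

```r
report <- run_pipeline()
report
#> STEMI care-pathway analysis report
#>   cohort: 3000 patients, mean total time 188.3 min
#>   QCA [EF]: ecg*txf*TWT + FMC*ecg*TWT
#>   QCA [LOS]: FMC*ecg*TXF*TWT + FMC*ECG*txf*TWT
#>   steady-state total time: baseline=189, policy=98 min
#>   sensitivity: 2000 runs
```

Reading the report: the QCA stage recovers the outcome structure from the
generated data — reduced ejection fraction follows delay paths
`ecg*txf*TWT + FMC*ecg*TWT`, elevated length of stay follows
`FMC*ecg*TXF*TWT + FMC*ECG*txf*TWT`. The baseline pathway holds patients
for 189 minutes on average; the improvement-policy estimates
`u = (0.40, 0.40, 0.50, 0.50)` cut that to 98 minutes — a large gain, yet
still above the 30-minute guideline, which would need
`find_required_improvement(model, 30)` ≈ 0.84 uniformly.

Each result type has `tidy()` / `glance()` methods and an `autoplot()`
(cohort summaries, trajectories, sensitivity bands). A thin command-line
wrapper with `generate` / `qca` / `simulate` / `sensitivity` / `pipeline`
subcommands is installed at `inst/cli/stemi-pathway.R`.

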