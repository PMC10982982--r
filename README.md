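# lhonva

Externally controlled visual-acuity (VA) analyses for Leber hereditary
optic neuropathy (LHON).

LHON is a mitochondrial disease causing rapid, usually bilateral loss
of central vision. Long-term treated cohorts are commonly compared
against an *external control*: a natural-history (NH) cohort assembled
retrospectively from untreated case records, whose visits must first be
matched to the treated cohort's assessment schedule. `lhonva`
implements that full analysis chain:

* **VA canonicalization** — Snellen fractions, decimal acuities, logMAR
  values and off-chart categories (counting fingers, hand motion, light
  perception, no light perception) are converted to a single logMAR
  scale. Off-chart records map to exactly 1.8 logMAR with the off-chart
  flag retained; 1.68 logMAR is the worst measurable on-chart value.
  Changes are also expressed as ETDRS letters via
  `floor(50 * |delta logMAR|)`.
* **Eligibility** — treated-arm and NH rule chains with auditable
  first-failing-rule exclusion ledgers, plus restriction to the three
  common mtDNA mutations (m.11778G>A, m.3460G>A, m.14484T>C).
* **Baseline matching** — for each NH eye, a (baseline, follow-up)
  visit pair within ±3 months of the analysis timepoint is selected:
  in the subacute/dynamic phase (≤ 12 months since onset) the baseline
  closest to *onset_L* (the treated cohort's mean time from second-eye
  onset to treatment baseline), in the chronic phase the baseline
  closest to each 12-month bin's midpoint.
* **Responder outcomes** — clinically relevant recovery (CRR),
  stabilization (CRS), worsening (CRW) and benefit (CRB = CRR or CRS),
  each with its own eligibility denominator.
* **Statistics** — covariate-adjusted logistic regression (with a Firth
  fallback under separation), ANCOVA on VA change (LS-mean
  difference), Kaplan-Meier time to first recovery, crude odds ratios,
  and the two-proportion sample-size calculation.
* **Simulator** — a seeded longitudinal cohort generator so the whole
  pipeline is testable and demonstrable without patient data.

See `vignette("external-control-methods")` for the full methods
description, parameter rationale, and the calibration design used to
verify statistical correctness.

## Worked example

Simulate a treated cohort and an NH cohort, then run the externally
controlled analysis at 12 and 24 months:

```r
library(lhonva)

sim <- simulate_cohorts(sim_config(n_treated = 80, n_nh = 250, seed = 42))
fit <- suppressWarnings(lhon_analysis(sim$treated, sim$nh, timepoints = c(12, 24)))
fit
#> Externally controlled VA analysis (subacute_dynamic phase)
#> onset_L = 5.67 months; window = +/- 3 months
#> month12: 130 treated vs 372 NH eyes
#> month24: 121 treated vs 373 NH eyes

summary(fit)
#> == month12 ==
#>  outcome           group responders eligible rate
#>      CRB         treated         37      130 28.5
#>      CRR         treated         28      130 21.5
#>      CRS         treated         10       33 30.3
#>      CRW         treated         51      109 46.8
#>      CRB natural_history         90      372 24.2
#>      CRR natural_history         69      372 18.5
#>      CRS natural_history         31       77 40.3
#>      CRW natural_history        116      274 42.3
#> CRB: OR 1.30 (95% CI 0.83-2.06), p = 0.255
#> CRR: OR 1.27 (95% CI 0.76-2.11), p = 0.355
#> CRS: OR 0.61 (95% CI 0.25-1.49), p = 0.279
#> CRW: OR 1.19 (95% CI 0.76-1.87), p = 0.441
#> VA change LS-mean difference 0.02 logMAR (0 letters), p = 0.666
#> == month24 ==
#>  outcome           group responders eligible rate
#>      CRB         treated         44      121 36.4
#>      CRR         treated         34      121 28.1
#>      CRS         treated         12       30 40.0
#>      CRW         treated         44      100 44.0
#>      CRB natural_history         86      373 23.1
#>      CRR natural_history         67      373 18.0
#>      CRS natural_history         28       85 32.9
#>      CRW natural_history        127      275 46.2
#> CRB: OR 2.14 (95% CI 1.35-3.41), p = 0.00133
#> CRR: OR 1.99 (95% CI 1.20-3.30), p = 0.00745
#> CRS: OR 1.46 (95% CI 0.59-3.62), p = 0.41
#> CRW: OR 0.91 (95% CI 0.57-1.44), p = 0.68
#> VA change LS-mean difference -0.03 logMAR (1 letters), p = 0.352
#> Kaplan-Meier first-CRR cumulative incidence (144 eyes):
#>  month6 month12 month18 month24
#>    20.1    27.8    32.7    35.2
```

The simulated treatment effect (log-odds +0.8 on recovery) is diluted
at 12 months — many simulated recoveries begin after the 12-month
endpoint — and emerges clearly at 24 months, mirroring the
slow-recovery dynamics the simulator encodes.

`run_pipeline()` wraps the same analysis and writes every intermediate
table (visit tables, matched datasets, responder rates, model
summaries, exclusion ledgers) as CSV files; runs with the same seed are
byte-identical. A command-line wrapper is installed at
`system.file("exec", "lhonva", package = "lhonva")`:

```sh
Rscript "$(Rscript -e 'cat(system.file("exec", "lhonva", package = "lhonva"))')" \
  --simulate --seed 42 --out results/
```

## Testing

The test suite (testthat, edition 3) verifies every printed worked
example, brute-force oracle equivalence for matching and Kaplan-Meier
estimation, responder truth tables, ANCOVA/emmeans agreement, and the
statistical calibration of the whole chain (confidence-interval
coverage of an injected effect; type-I error of the treatment test):

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "lhonva", load_package = "installed")'
```

## License

MIT. See `LICENSE`.
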