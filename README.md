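# pvpd

Pharmacovigilance–pharmacodynamic (PV-PD) signal analysis for spontaneous
adverse-event reports, built around antipsychotic-associated sexual
dysfunction (SD).

Spontaneous-report databases (FAERS-like streams) let two questions be asked
together: *which drug–event pairs are disproportionately reported*, and *does
the strength of a drug's signal track its receptor pharmacology*? `pvpd`
answers both with a tested, reusable pipeline:

* **Disproportionality signal detection.** Report-level 2×2 tables under the
  primary-suspect rule; reporting odds ratio
  ROR = (a·d)/(b·c) with the Woolf 95% interval
  exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d)), signalling when ROR₀₂₅ > 1; the
  information component in the observed/expected shrinkage form
  IC = log₂((a+0.5)/(E+0.5)), E = (a+b)(a+c)/n, with
  IC₀₂₅ = IC − 3.3(a+0.5)^(−1/2) − 2.0(a+0.5)^(−3/2), signalling when
  IC₀₂₅ > 0. Pairs need more than 3 cases (a ≥ 4) to enter downstream
  analyses.
* **Receptor occupancy** from binding constants and unbound therapeutic
  concentrations: occupancy (%) = 100·C_U/(K_i + C_U) with
  C_U = 1000·F_U·C_T/MW in nM.
* **The PV-PD regression** (`pvpd()`): per-receptor ordinary least squares of
  each drug's *median ROR* on its occupancy, with activity-signed, pKi and
  ICD-term-exclusion sensitivity modes; a classed fit object with `print`,
  `summary`, `coef`, `predict`, `plot` and `residuals` methods.
* **Sensitivity analyses**: pre/post FDA-warning window split (notoriety
  bias) and rare-PT exclusion.
* **A synthetic FAERS-like generator** with planted drug–event effect
  multipliers and a closed-form population-ROR oracle (`expected_ror()`),
  so every estimator is validated against known truth.

## Worked example

```r
library(pvpd)

ts  <- default_termset()                      # SD preferred-term vocabulary
cfg <- demo_faers_config(n_reports = 50000, seed = 1)
rep <- generate_reports(cfg)                  # synthetic report stream

drugs <- setdiff(names(cfg$drugs), "background")
sig <- signal_scan(rep, drugs, ts)            # PT- and subgroup-level signals
occ <- occupancy_table(demo_pharmacology())   # synthetic demo pharmacology
fit <- pvpd(sig, occ, ts, mode = "main")      # median ROR ~ occupancy
```

The three strongest PT-level signals in that run:

```
         drug                      event   a   ror ror_lo    ic ic_lo
 aripiprazole compulsive sexual behavior 683 98.71  79.50 3.447 3.320
  iloperidone     retrograde ejaculation  55 66.47  47.03 4.823 4.376
 aripiprazole             hypersexuality 261 31.18  24.76 3.145 2.940
```

Each row is one drug–PT 2×2: `a` is the case count (reports with the drug as
primary suspect and the PT), `ror`/`ror_lo` the reporting odds ratio and its
lower 95% bound (a signal since ror_lo > 1), `ic`/`ic_lo` the shrinkage
information component in bits and its lower credibility bound. The planted
demo associations (aripiprazole–compulsive sexual behavior,
iloperidone–retrograde ejaculation) surface exactly where they were planted.

```r
print(fit)
#> Pharmacovigilance-pharmacodynamic regression suite
#>   response: median ROR over included PTs; excluded drug(s): iloperidone
#>
#>    receptor mode       beta intercept p_value        r2 n_points
#>      5-HT1A main  0.0093978    1.4069  0.6915 2.073e-02       10
#>      ...
#>          D2 main -0.0312461    3.8676  0.3686 1.019e-01       10
```

One row per receptor: `beta` is the OLS slope of median ROR on occupancy (%),
`p_value` the two-sided test of zero slope, `r2` the squared correlation,
`n_points` the drugs used. In this demo the planted effects were assigned
independently of the (synthetic) pharmacology table, so no receptor shows a
real association — which is exactly what the flat fits report.

The full pipeline — cohort description, signal scan, occupancy, all four
regression modes, window and rare-PT sensitivity analyses, figures and a run
manifest — runs end-to-end with:

```r
out <- run_pipeline(run_config(
  input = cfg, out_dir = "pvpd_out", seed = 1
))
```

A thin command-line wrapper with verbs `generate`, `scan`, `occupancy`,
`regress`, `sensitivity` and `run` ships in `inst/scripts/pvpd.R`.

## Caveats

The shipped term set approximates the licensed MedDRA PT list; the shipped
pharmacology table is synthetic demonstration data (see its `source` column).
Disproportionality quantifies reporting asymmetries, not incidence or causal
risk. See the methods vignette (`vignettes/pvpd-methods.Rmd`) for the model,
its assumptions and its limitations.
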