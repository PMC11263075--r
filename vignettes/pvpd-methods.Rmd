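---
title: "Methods: disproportionality signals and their pharmacodynamic correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signals and their pharmacodynamic correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvpd)
```

## The problem

Sexual dysfunction (SD) is an under-reported, quality-of-life-limiting adverse
effect of atypical antipsychotics. Spontaneous-report databases (FAERS-like
streams of individual case safety reports) allow two questions to be asked at
scale:

1. **Signal detection** — which drug–event pairs are reported together more
   often than the background reporting pattern predicts?
2. **Pharmacodynamic correlation** — does the strength of a drug's SD signal
   track its occupancy of specific neurotransmitter receptors (dopaminergic,
   serotonergic, adrenergic, muscarinic, histaminergic)?

`pvpd` implements both, plus the sensitivity analyses needed to interpret
them, and ships a synthetic report-stream generator with a closed-form
ground-truth oracle so every estimator can be validated against planted truth.

## Case/non-case disproportionality

For a drug $D$ and an event term set $E$ the package forms the report-level
2×2 table under the *primary-suspect* (PS) rule: a report is exposed only if
$D$ is its PS drug; suspect-secondary, concomitant and interacting entries
never count. With cells $a$ (PS = $D$, event), $b$, $c$, $d$:

* **Reporting odds ratio** $\mathrm{ROR} = \dfrac{a\,d}{b\,c}$, with the Woolf
  interval $\exp\left(\ln \mathrm{ROR} \pm 1.96\sqrt{\tfrac1a+\tfrac1b+\tfrac1c+\tfrac1d}\right)$.
  A pair signals when the lower bound $\mathrm{ROR}_{025} > 1$.
* **Information component** in the observed/expected shrinkage form,
  $\mathrm{IC} = \log_2 \dfrac{a + 0.5}{E + 0.5}$ with
  $E = (a+b)(a+c)/n$, and the lower credibility bound
  $\mathrm{IC}_{025} = \mathrm{IC} - 3.3\,(a{+}0.5)^{-1/2} - 2.0\,(a{+}0.5)^{-3/2}$.
  A pair signals when $\mathrm{IC}_{025} > 0$. The original Bayesian
  confidence-propagation posterior is a near-identical alternative at the
  counts this analysis operates on; the shrinkage form is the contemporary
  standard and is the single implementation shipped (a second, rarely
  exercised code path would add maintenance risk without changing any
  conclusion at these counts).

**Numerical choices.** Zero cells leave the ROR undefined (`NA`) rather than
Haldane-corrected: corrected values would silently leak into per-drug medians.
The case-count inclusion filter — a pair enters downstream analyses only when
$a \ge 4$, the strict reading of "more than 3 cases" — makes zero-$a$ tables
moot anyway. The IC needs no correction because the $+0.5$ shrinkage keeps it
finite everywhere.

**Comparator population.** Non-cases are *all* other reports in the supplied
dataset (whole-background comparator), not merely reports of other
antipsychotics. This matches how open pharmacovigilance front-ends tabulate
case/non-case counts and makes the background drug mass in the generator part
of the study conditions.

**Term sets.** Events are MedDRA-like preferred terms (PTs). The SD event set
is defined structurally: every PT whose high-level group term is one of the
two SD HLGTs ("sexual function and fertility disorders"; "sexual
dysfunctions, disturbances and gender identity disorders"). Four symptom
subgroups (hypersexuality, hyposexuality, erectile dysfunction, ejaculatory
dysfunction) partition a subset of those PTs; a report counts once per
subgroup regardless of how many member PTs it lists. The shipped default term
set contains the PTs that recur in the clinical literature on
antipsychotic-associated SD; it is an approximation — the full licensed
MedDRA 26.0 list cannot be redistributed — and every analysis function takes
the term set as an argument precisely so the real list can be substituted.
PT matching is case-insensitive after whitespace normalization, because
spontaneous-report PT casing varies across database eras.

**Median ROR.** A drug's scalar signal strength is the median of its PT-level
RORs over included pairs (even count: midpoint). Whether the median should be
restricted to *significant* pairs is ambiguous in practice; the default is
all included pairs, and `median_over = "significant"` switches the
restriction on so both can be reported.

## Receptor occupancy

Single-site competitive binding at the unbound therapeutic concentration:

$$\mathrm{occupancy}\,(\%) = 100 \cdot \frac{C_U}{K_i + C_U},
\qquad C_U = 1000 \cdot \frac{F_U \cdot C_T}{MW} \;\text{nM},$$

where $F_U$ is the unbound fraction, $C_T$ the upper bound of the recommended
therapeutic range in ng/mL, and $MW$ the molecular weight in g/mol. ng/mL is
the only unit assignment under which the formula lands on nM, and it is the
unit therapeutic-drug-monitoring consensus ranges are published in. Muscarinic
and adrenergic ($\alpha_1$, $\alpha_2$) receptors are treated as single
pseudo-receptors irrespective of subtype. When several $K_i$ values exist for
one drug×receptor pair the geometric mean is used (binding constants spread
over orders of magnitude). The shipped `pharmacology_synthetic.csv` is a
*synthetic demonstration table* with plausible magnitudes — users analysing
real data should substitute a curated snapshot (PDSP, IUPHAR/BPS).

pKi uses the standard molar convention $pK_i = 9 - \log_{10} K_i(\mathrm{nM})$.
Because ordinary least squares is equivariant under affine maps of the
predictor, the convention affects only the sign and scale of the slope, never
$p$ or $R^2$.

## The PV-PD regression

`pvpd()` is the package's central fitting function. Per receptor with at
least three usable drugs it regresses the per-drug median ROR on a
pharmacodynamic predictor by ordinary least squares (slope $\beta$, two-sided
$p$ from the $t$ distribution on $n-2$ df, $R^2$), in four modes:

| mode | predictor | purpose |
|---|---|---|
| `main` | occupancy (%) | primary analysis |
| `activity_signed` | occupancy, sign reversed for antagonists/inverse agonists; unknown-activity drugs dropped | direction of pharmacology |
| `pki` | $pK_i$ | avoids multi-source concentration inputs |
| `excl_icd_activity_signed` | signed occupancy, medians recomputed without impulse-control-disorder PTs | removes notoriety-prone terms |

Ten separate univariate fits per mode, raw $p$ values (no multiplicity
correction — the fits are reported side by side, not selected from);
iloperidone is excluded by default (`exclude_drugs`) because its small report
base produces unstable extreme estimates. Drugs missing either the median ROR
or the receptor's occupancy are dropped pairwise per receptor. The median ROR
enters untransformed by default; `log_ror = TRUE` switches to a
log-transformed response.

Degenerate inputs: a constant predictor is an error (slope undefined); a
constant response returns $\beta = 0$, $R^2 = 0$, $p = 1$ (the `summary.lm`
$R^2$ is 0/0 there); an exactly collinear fit would give $p = 0$ from a zero
residual SE and is clamped to the smallest positive double so $p$ stays in
$(0, 1]$.

## Sensitivity analyses

* **Warning-window split.** The May-2016 FDA warning on
  aripiprazole-associated impulse-control disorders (ICDs; compulsive sexual
  behavior, hypersexuality, excessive masturbation, increased libido) can
  inflate post-warning reporting — notoriety bias. `window_scan()` computes
  drug-level RORs (event = any SD PT) separately for a pre-warning and a
  post-warning window. Receipt time is quarterly in this data model, so the
  defaults are the whole quarters inside the conventional monthly boundaries:
  pre 2004Q1–2015Q1, post 2016Q3–2023Q3, with the 2015Q2–2016Q2 gap excluded
  from both windows.
* **Rare-PT exclusion.** `exclude_rare_pts()` removes SD PTs mentioned in
  fewer than 500 reports database-wide (any drug, any role; strict "fewer
  than", so a PT at exactly 500 survives) before a rescan — extreme RORs
  carried by a handful of reports disappear if they are count artefacts.
* **ICD-PT exclusion.** Rerunning the scan and regression after dropping the
  ICD PTs shows how much of a hypersexuality signal is carried by the
  notoriety-prone terms.

## The synthetic generator and what it does (not) show

`faers_config()`/`generate_reports()` produce a seedable report stream over
2004Q1–2023Q3: one PS drug per report drawn from configurable marginals
(including a dominant non-antipsychotic background mass), reaction PTs
included *conditionally independently given the PS drug* with probability
$p_{pt}\,\rho(\mathrm{drug},pt)$ (capped at 1 with a warning naming the
pair), Table-1-style demographics with realistic missingness (default: 75.8%
of reports lack dose), decoy concomitant drug entries that the PS filter must
ignore, and an optional post-2016Q2 multiplier on ICD-PT inclusion emulating
the notoriety surge (applied to quarters strictly after the cut, consistent
with the post-warning window).

Conditional independence is a deliberate trade of realism for testability: it
makes the *population* ROR of every pair available in closed form
(`expected_ror()`, by enumeration over the PS-drug mixture and quarter mix),
and `calibrate_rho()` inverts that oracle so a target ROR can be planted
exactly. A report whose PT draws all come up empty receives the background
filler PT "product ineffective" (never part of a term set); this keeps every
report's reaction list non-empty without perturbing any analyzed PT's
inclusion probability, so the oracle stays exact.

What the generator does **not** emulate: duplicate and versioned reports,
free-text drug-name noise, correlated PT co-reporting (syndromes),
reporter-type mixtures, and secular reporting trends other than the single
warning surge. Passing tests therefore demonstrate estimator correctness
under a clean generative model — not robustness to FAERS data-quality
pathology, which the deduplication and normalization layers of a production
ingest would have to address.

## Problem sizes and calibration checks

The validation suite exercises the estimators at sizes chosen to make the
statistical properties measurable while keeping a full run comfortably
interactive:

* CI coverage: 200 replicates of a 100,000-report stream with a planted true
  ROR of 10; the 95% Woolf interval should cover truth in 95% ± 3% of runs.
* Null calibration: 100 replicates under $\rho \equiv 1$; among pairs passing
  the $a \ge 4$ filter, the significant-ROR fraction is checked against 7.5%
  (the nominal one-sided 2.5% plus the selection effect of conditioning on
  the count filter — the filter preferentially retains upward count
  fluctuations).
* Slope recovery: 11 drugs, planted slope 4.5, Gaussian noise sd 1, 100
  replicates; the estimate should land within two (known-noise) standard
  errors of truth in at least 90 — with the noise sd planted, the sampling SE
  of the slope is known exactly as $\sigma/\sqrt{S_{xx}}$, which keeps the
  check about slope recovery rather than about the $t$-noise of an estimated
  SE.
* Oracle equivalence: 200 random small report sets recounted by a brute-force
  routine, exact agreement on counts and point estimates, $10^{-12}$ relative
  on intervals.

## Worked example

```{r, eval = FALSE}
library(pvpd)

ts  <- default_termset()
cfg <- demo_faers_config(n_reports = 50000, seed = 1)
rep <- generate_reports(cfg)

drugs <- setdiff(names(cfg$drugs), "background")
sig <- signal_scan(rep, drugs, ts)
occ <- occupancy_table(demo_pharmacology())

fit <- pvpd(sig, occ, ts)
summary(fit)
plot(fit, mode = "main")
```

## Known limitations

* The default term set approximates, but is not, the licensed MedDRA PT list;
  subgroup assignments for rare PTs are judgement calls.
* The shipped pharmacology table is synthetic demonstration data.
* Disproportionality is reporting, not risk: the package quantifies reporting
  asymmetries and their pharmacodynamic correlates, and none of its outputs
  are incidence estimates or causal effects.
* No stratified (age/sex-adjusted) disproportionality, no EBGM/MGPS, no
  duplicate detection beyond `report_id` collapsing.
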