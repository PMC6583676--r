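---
title: "Methods: cost-effectiveness analysis from aggregated trial data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cost-effectiveness analysis from aggregated trial data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggcea)
```

## The problem

Economic evaluation of osteoarthritis (OA) treatments needs individual
health-utility values, but OA trials rarely measure utilities directly and
almost never share individual patient data. What trials do publish are
aggregate statistics — means, SDs and sometimes correlations — of the WOMAC
subscales (pain 0–20, function 0–68, stiffness 0–8 on the normalized
scales), age, and years since OA diagnosis. `aggcea` implements a pipeline
that bridges that gap for the comparison of glucosamine formulations
(prescription crystalline glucosamine sulfate, pCGS, versus other
glucosamine preparations) against placebo:

1. **Pseudo-IPD reconstruction** — simulate individual clinical-variable
   vectors from the published aggregates (`sample_ipd()`).
2. **Utility mapping** — score each simulated patient with a linear
   utility regression on the five clinical variables plus a female
   indicator (`compute_utility()`).
3. **Evidence synthesis** — pool per-study mean utility changes into a
   per-arm trajectory over time, weighting by study size
   (`build_trajectory()`).
4. **QALY computation** — integrate the trajectory by the trapezoidal
   area-under-the-curve method (`qaly_auc()`).
5. **Economics** — accumulate drug costs from daily prices and compute
   incremental cost-effectiveness ratios with dominance handling
   (`icer()`).

## Pseudo-IPD model and its assumptions

Individual vectors of (pain, function, stiffness, age, years since OA) are
drawn from a multivariate normal with the published means and covariance
`diag(sd) %*% corr %*% diag(sd)`. Each whole vector is **rejected** if any
coordinate leaves its permissible range (pain 0–20, function 0–68,
stiffness 0–8, age 0–100, years since OA 0–100), and redrawn until the
requested number of patients is accepted. Two deliberate choices:

* **Joint rejection, not clipping.** Clipping out-of-range coordinates
  would place probability atoms on the boundaries and distort the
  correlation structure; discarding the whole vector keeps the sample a
  genuine truncated multivariate normal.
* **Published moments parameterize the untruncated normal.** No
  re-calibration step maps the published means onto the means of the
  truncated distribution, so when a mean sits close to a bound the
  accepted sample's moments are pulled slightly inward. This is
  documented behaviour, not corrected, because the reconstruction
  procedure being emulated performs no such correction either. With the
  bundled parameter ranges the effect is far below Monte-Carlo noise at
  10,000 patients per arm.

Baseline and endpoint visits are simulated independently from their own
published summaries; a longitudinal (within-patient) correlation only
exists in the synthetic-trial generator, where ground truth requires it.

Incomplete summaries are completed by `apply_fallback()`: any missing mean,
SD or correlation entry is taken from a fallback table and flagged
(`"observed"` versus `"fallback"`) so downstream reports can disclose the
substitution. The shipped `default_fallback()` values are a synthetic
moderate-knee-OA profile, not data from any trial.

Reproducibility of batch runs uses one root seed with a stated splitting
rule — unit `i` (studies × arms × visits in order) gets
`(root + 1009 * i) mod (2^31 - 1)` — so appending a study never perturbs
the streams of earlier studies.

## Utility mapping

Utility is a linear function
`u = b0 + b_pain*pain + b_fun*function + b_stiff*stiffness + b_age*age +
b_years*years + b_female*female` with `female = 1` for all simulated
patients. The coefficient values belong to an external utility-mapping
regression and are **configuration**, not code: the package ships only a
clearly-labelled synthetic placeholder profile
(`utility_profile_synthetic.yaml`) with plausible signs and magnitudes,
used by the test-suite and the synthetic generator. Substantive analyses
must supply a real profile. Utilities are raw regression outputs — they are
not clamped to [0, 1] by default, because observed utility changes can be
negative and published analyses report raw values; `clamp = TRUE` is
available. A diagnostic warning (never an error) flags utilities outside
[-0.5, 1].

## Pooling rules and the time axis

`pooled_change()` pools per-study mean utility changes with weights
proportional to **total study N** (the per-arm split is not published for
these trials; only the total enters the weighting, and equal halves are
assumed wherever a per-arm count is needed).

* **Main mode.** The pooled change at month *t* averages the studies whose
  duration is exactly *t*. Earlier grid points remain part of the
  trajectory, so the 36-month QALY still integrates over the 3- and
  6-month pooled changes. Duration-equality is the eligibility rule
  consistent with the published per-horizon tables.
* **Sensitivity mode.** Every study at least *t* months long contributes
  its change prorated by the exact fraction `t / duration` (a 36-month
  study contributes 3/36 ≈ 8.3% of its effect at month 3); shorter studies
  are excluded. At `t = duration` this reduces to main-mode inclusion.

Interval widths on the time axis are **year fractions truncated at two
decimals**: 2 months → 0.16 y, 1 month → 0.08 y, 3 months → 0.25 y,
30 months → 2.5 y. This convention was identified as the only one that
reproduces the published QALY tables exactly; it slightly shortens
non-quarter intervals. Exact twelfths are available with
`year_fraction = "exact"` for analyses that prefer correctness of the time
axis over replication fidelity.

## QALY and economics

`qaly_auc()` integrates the **utility change** from baseline (origin fixed
at change 0) by the trapezoid rule over the truncated-width intervals, so a
placebo arm with worsening utility accrues a negative "QALY change".
`qaly_auc_absolute()` offers the conventional absolute-utility area as a
non-default alternative.

Costs are `price/day × months × days/month` with placebo at 0. The default
is 30 days/month, which matches the published cost rows of the
other-formulation tables. The published pCGS cost rows imply 59 days/month
(e.g. a 3-month median cost of 139.83 EUR at 0.79 EUR/day is a 177-day
quarter) — an internal inconsistency of the source tables. Rather than
silently adopt either convention, `cost_at()` exposes `days_per_month`, and
`replicate_analysis()` documents its use of the 59-day preset for the pCGS
tables.

`price_range()` condenses a wide international price list: with `m` the
overall mean, "high" is the mean of prices ≥ 0.5·m, "low" the mean of
prices ≤ 1.5·m, and the reported median is the sample median of the
untrimmed list. The trimmed means and the median are distinct notions and
both are emitted; a warning flags the (possible) case where the median
leaves the [low, high] band.

`icer()` reports a ratio only when incremental cost and incremental QALYs
have the same strict sign; the comparator dominates when the intervention
is no more effective yet at least as costly (printed as "Placebo better" in
table output), and symmetrically for intervention dominance. Two exactly
zero increments are flagged indeterminate. `classify_icer()` applies a
willingness-to-pay threshold (default 30,000 EUR/QALY, configurable, and
never used in the replication tests).

## Synthetic-trial generator

`truth_spec()`/`generate_trial()` create trials with known ground truth so
the whole pipeline is testable without any external data. Per arm, paired
baseline/endpoint vectors are drawn from a 10-dimensional normal whose
covariance is `D (K ⊗ R) D`, with `R` the cross-sectional correlation, `K`
the 2×2 visit-correlation matrix (within-patient correlation 0.6 by
default — change scores would have unrealistically large variance if visits
were independent) and `D` the diagonal of SDs; the whole 10-vector is
rejected if either visit leaves the permissible boxes. Defaults emulate
moderate knee OA (baseline pain 10 ± 3, function 30 ± 10, stiffness
4 ± 1.5, age 62 ± 8, 6 ± 2 years since diagnosis) with a modest active-arm
improvement; all values are configurable and none is a claim about a real
trial.

What the generator does **not** emulate: non-normal (skewed, floor-effect)
WOMAC distributions, dropout and missingness mechanisms, measurement error
in published summaries, or between-centre heterogeneity. Passing the
recovery tests therefore demonstrates internal consistency of the
reconstruction machinery, not that real OA populations are normal.

Validation runs 100 replicate truth specifications at 10,000 patients per
arm (the scale of the reconstruction procedure itself) and requires the
re-simulated mean utility change to fall within 3 combined Monte-Carlo
standard errors of the ground truth in at least 95% of arms, with every
simulated record inside the permissible boxes.

## Numerical choices

* PSD checks of correlation/covariance matrices tolerate relative
  eigenvalue error 1e-8; `repair_psd = TRUE` projects onto the nearest PSD
  matrix (Higham projection via `Matrix::nearPD`) instead of failing.
* The rejection sampler draws in adaptively-sized batches and declares
  infeasibility when the acceptance rate is still below 1e-4 after 1e6
  draws (both configurable).
* Year-fraction truncation adds 1e-9 before truncating to guard against
  binary representations such as 16.999999....
* Pooled values and QALYs are kept at full double precision everywhere;
  rounding to table precision happens only in `print()` methods.
* Zero-SD (point-mass) aggregates are valid inputs and short-circuit
  nothing: the sampler simply accepts constant vectors (or fails fast if
  the constant mean is out of range).

## Known limitations

* Drug cost is the only cost category; no discounting, no probabilistic
  sensitivity analysis, no heterogeneity modelling (no random-effects
  pooling) — the replicated analysis performs none of these.
* The 59 vs 30 days/month inconsistency of the source cost tables is
  exposed, not resolved.
* In the sensitivity-mode tables for the other-formulation group, the
  published 3- and 6-month QALY cells are mutually consistent with a
  3-month pooled change that no systematic eligibility/proration rule
  reproduces (the same rule set reproduces every other published cell to
  all printed decimals, including the whole pCGS sensitivity table and the
  2-month column of the same table). The package computes the
  rule-consistent values; the replication test documents the four
  discrepant cells. All dominance verdicts ("Placebo better") agree either
  way.
* The bundled utility-coefficient profile is a synthetic placeholder;
  replication of published *utility levels* (as opposed to the published
  change-based tables, which take the per-study changes as inputs) requires
  the external regression coefficients.
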