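---
title: "The energy-balance model behind enbal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The energy-balance model behind enbal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enbal)
```

enbal implements the computational core of a workplace weight-reduction
program built on a single premise: weight change is driven by the cumulative
balance between calorie intake and total energy expenditure (TEE). This
vignette documents the model, its constants, the conventions we fixed where
the field offers several, and what the synthetic cohort simulator does and
does not emulate.

## Total energy expenditure

TEE is decomposed as

$$\mathrm{TEE} = \mathrm{RMR} + \mathrm{TEA}_{\mathrm{IPAQ}} +
\mathrm{TEA}_{\mathrm{daily}} + \mathrm{TEF}$$

* **RMR** (resting metabolic rate) uses the Cunningham fat-free-mass
  regression, $\mathrm{RMR} = 500 + 22 \cdot \mathrm{FFM}\,(\mathrm{kg})$
  kcal/day. The FFM form is preferred for obese adults because fat mass
  contributes little to resting expenditure; validation work in Korean
  adults supports it over weight-based predictors. Both constants are
  config-exposed (`energy$cunningham_intercept`, `energy$cunningham_slope`).
* **TEA (questionnaire)** scores the IPAQ Short Form with the protocol MET
  values — walking 3.3, moderate 4.0, vigorous 8.0 MET — as weekly
  MET-minutes $\sum \mathrm{MET} \times \mathrm{min/day} \times
  \mathrm{days/week}$, converted to kcal/day by
  $\mathrm{MET\text{-}min} \times \mathrm{weight}/60 \div 7$. The protocol's
  180 min/day per-domain truncation is applied by default
  (`energy$ipaq_truncate_min`; set `Inf` to disable). Walking bouts under
  10 minutes are excluded by the instrument and must not be entered.
* **TEA (daily living)** covers incidental activity the questionnaire
  misses (short walks, showering, talking). On the premise that the target
  population is sedentary it is fixed at 10% of RMR. The model keeps this
  premise constant as activity rises — the questionnaire domains and the
  daily-living remainder are treated as non-overlapping.
* **TEF** (thermic effect of food) is 10% of RMR plus activity expenditure.
  Whether "activity" includes the daily-living component is genuinely
  ambiguous; we default to including it (`energy$tef_base = "total"`) and
  expose `"ipaq_only"` as the alternative. With no reported activity the
  closed form is $\mathrm{TEE} = 1.21 \times \mathrm{RMR}$, which the test
  suite checks on randomized inputs.

## Calorie prescription and goal resetting

The program goal is a 7% loss of baseline weight over 12 weeks, split
3.0 / 2.5 / 1.5% over three 4-week periods. Weight targets convert to energy
via 7000 kcal per kg (config-exposed; 7700 is also used in the literature).
Each period's daily deficit is the period's kcal budget over its days; the
user's `activity_share` (default 0: all-diet) splits it between intake
restriction and added exercise, and prescribed intake is TEE minus the
diet-side deficit.

Safety floors of 1200 kcal/day (women) and 1500 kcal/day (men) are absolute:
when the floor binds, the prescription reports the deficit the diet could
not deliver (`unmet_deficit_kcal`) instead of silently shifting it into
activity — the floor is a guideline safety constraint and takes precedence
over the schedule.

Goals are reset at period boundaries from measured weight. The published
description says only that goals were "adjusted periodically", so the
resetting rule is a design choice of this package: the endpoint stays fixed
at 93% of baseline, and the remaining loss (measured weight minus the
endpoint, clamped at zero once the goal is exceeded) is redistributed across
the remaining periods in proportion to their *original* percentage splits.
This rule is idempotent for on-track weights, never produces negative
targets, and keeps the total program goal invariant under repeated
resetting.

## Diet and activity tracking

Food entries reference a plain CSV food table
(`id,name,kcal_per_serving,serving_desc,source`); portions are
multiplicative fractions of a serving. Search is case-insensitive substring
matching with pre-entered sources (cafeteria, nearby restaurants, frequent
items) ranked above user and bulk-database entries, ties broken by name, so
results are deterministic. Manual activity converts METs with the
compendium convention 1 MET ≈ 1 kcal/kg/h; tracker entries are taken at
their reported kcal. Daily status uses a ±50 kcal on-goal band
(`tracking$goal_tolerance_kcal`) — no published value exists, and ±50 kcal
is well inside any food diary's measurement error. Logged exercise is added
on top of TEE by default; since the IPAQ-based TEA already includes habitual
exercise this can double-count, so `add_logged_exercise = FALSE` is provided
for TEE estimates that already cover the logged session. Weekly summaries
aggregate by ISO week.

## Screening, scoring, ranking

Eligibility requires BMI ≥ 25 kg/m² and no exclusion among: positive PAR-Q,
positive eating-disorder screen, SBP ≥ 160 or DBP ≥ 100 mmHg, fasting
glucose ≥ 160, triglyceride ≥ 500, LDL-C ≥ 190 mg/dl, obesity treatment
within a month, weight change of more than 10% within a month (strict, both
directions), severe illness history, thyroid disease, or investigator veto.
The questionnaire/lab rules model the study's clinician judgement as a
threshold that fires unless `counseling_cleared` is set. Thresholds are
inclusive exactly as printed. Missing labs are invalid input, never a pass.

The achievement score combines 7%-loss success (binary), proximity to the
monthly goal weight (linear, clamped to [0, 1]) and logging adherence (the
better of diet-diary and tracker usage, as a fraction of period days). The
published description lists these ingredients without weights or functional
form; we combine them additively with equal weights by default, fully
config-driven. Leaderboards use competition ranking (ties share the best
rank: 10, 10, 5 → 1, 1, 3), matching leaderboard conventions.

## CT adipose quantification

Adipose tissue on a single umbilicus-level slice is segmented by Hounsfield
windowing: a pixel is fat when $-250 \le \mathrm{HU} \le -50$, inclusive at
both ends ("within a range" reads as closed). Areas are pixel counts times
the pixel area, reported in cm²; visceral obesity is VAT ≥ 100 cm²
(inclusive). Separating visceral from subcutaneous fat needs the
abdominal-wall contour, which commercial workstations segment; this package
takes the visceral compartment as an input mask. The per-participant CT fat
ratio is computed as VAT/SAT, the definition consistent with the magnitudes
reported for obese cohorts. `make_phantom()` builds synthetic slices with
exactly known (pixel-quantized) areas for testing; it is labelled synthetic
and emulates only geometry, not scanner physics.

## The synthetic cohort simulator

No individual-level data from the pilot study exist publicly, so the
simulator generates a cohort with the pilot's *marginal* structure
(`cohort_marginals()`): medians and IQRs for anthropometry, body
composition, blood pressure, labs and CT fat, with 93.3% men. Normal
marginals use sd = IQR/1.349 (the normal IQR-to-sd factor); triglyceride,
ALT and the CT areas are log-normal with matched median and IQR because
they are positive and right-skewed. Variables are drawn independently —
the published table gives no correlations — with two physiologic guards
(weight ≥ 45 kg, FFM ≤ 95% of weight).

Weight dynamics invert the 7000 kcal/kg constant: each day the participant
achieves a fraction of the prescribed deficit drawn from a clamped Gaussian
(`adherence_mean`, day-to-day `adherence_sd`), and true weight falls by the
achieved deficit over 7000. Weekly measurements add independent Gaussian
noise (default sd 0.3 kg, typical scale-and-clothing variation); goal
resetting uses the measured weight, as the deployed program would. The
default adherence mean is 0.83, chosen so the simulated cohort's expected
loss matches the pilot's reported mean loss (5.8% achieved of the 7%
scheduled); the day-to-day sd of 0.20 is a plausibility choice. Energy
bookkeeping runs on the *total* prescribed deficit: when the diet floor
binds, the remainder is assumed met through activity, which is what keeps
the full-adherence, zero-noise cohort at exactly 93% of baseline after 12
weeks (a mass-balance identity the tests verify to machine precision).

Two subtleties worth knowing:

* With goal resetting on, under-achievement inflates later targets, so mean
  loss exceeds `adherence_mean` × 7%. The clean analytic expectation
  (0.8 adherence → 5.6% loss) holds with `reassess = FALSE`, and
  `recover_adherence()` estimates adherence as achieved/prescribed deficit,
  which is unbiased under either mode.
* Secondary outcomes (BP, labs, CT fat) are *generated*, not mechanistic:
  each responds linearly to percent weight loss with slopes whose signs
  match the directions observed in the pilot (everything improves except
  HDL, which rises) plus Gaussian noise (`outcome_slopes()`). Passing tests
  therefore show the analysis pipeline is correct, not that real metabolic
  responses are linear.

The simulator does not model dropout (the pilot reported complete
follow-up), adaptive thermogenesis or RMR decline during weight loss,
seasonal or weekday eating patterns, or correlation between baseline
variables. TEE is held at its baseline value across the 12 weeks; over a 7%
loss this overstates late-program expenditure by roughly 2%, well below the
adherence noise.

## Pre/post analysis

Outcomes are summarized as median (IQR) at baseline and final, the median
(IQR) of per-participant differences — the median of differences, not the
difference of medians, which is what a paired design reports — and a
Wilcoxon signed-rank p-value. Quantiles use linear interpolation (R type 7)
throughout; the convention is fixed because small-sample IQR endpoints
depend on it.

The signed-rank test drops zero differences and mid-ranks ties. For n ≤ 25
non-zero pairs the two-sided p is computed *exactly*, conditional on the
observed midranks, by a dynamic-programming convolution over the $2^n$ sign
assignments (doubled midranks are integers, so the full null pmf costs
$O(n \sum r_i)$); this keeps the exact path available under ties, where
`stats::wilcox.test()` falls back to an approximation. Above 25 pairs the
normal approximation with tie-corrected variance is used, with a 0.5
continuity correction by default: in our checks the corrected approximation
agrees with the exact path to well under 0.01 at n = 20, while the
uncorrected one does not; both behaviors are config-exposed
(`analysis$continuity`). All p-values are two-sided. When every difference
is zero the test is flagged degenerate and p is NA rather than a made-up 1.

## Problem sizes and numerical choices

The test suite exercises the simulator at n = 1000 for the conservation and
parameter-recovery properties and n = 2000–4000 for marginal checks — large
enough that Monte-Carlo error is a small fraction of the tolerances (e.g.
adherence recovery to ±0.01 where the standard error is ~0.001), small
enough that the whole suite runs in well under a minute. The type-I-error
property uses 2000 null replicates at n = 30, giving a 3-sigma band of
about ±0.015 around 0.05. Acceptance checks of printed constants are exact:
the 7%/7000-kcal bookkeeping holds to machine precision by construction,
not within a tolerance.

Degenerate inputs are rejected loudly rather than coerced: non-positive
weights, negative FFM, days outside [0, 7], mixed-date logs, unknown food
ids, missing screening labs. Where a rule needed a tie-break or convention
we chose once, documented it here, and left it in the config.

## Reproducibility

`run_pipeline(config, seed, out_dir)` executes simulate → prescribe →
analyze → report over files and writes a manifest (config hash, seed, file
list); identical config and seed reproduce every artifact byte for byte,
which the tests assert. The command-line entry point
(`inst/cli/enbal.R`) exposes the same stages as subcommands.
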