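---
title: "A five-state Markov cost-utility model for lumbar facet arthroplasty versus fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A five-state Markov cost-utility model for lumbar facet arthroplasty versus fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facetCEA)
```

## The decision problem

Lumbar facet arthroplasty (the TOPS device) preserves segmental motion after
decompression for grade-1 degenerative spondylolisthesis with stenosis, at a
device upcharge over the standard comparator, transforaminal lumbar interbody
fusion (TLIF). The economic question is whether faster and more durable
functional recovery repays that upcharge — from a health-system perspective
(direct medical costs only) and from a societal perspective (adding
productivity loss). This package implements the full decision-analytic
pipeline: health-state construction, a cohort Markov engine, dual-perspective
costing, incremental cost-effectiveness metrics, and scenario / one-way /
probabilistic sensitivity analyses, plus a synthetic-trial generator that
stands in for the proprietary trial data.

## Health states from VAS and ODI

Pain (VAS, 0–10) and disability (ODI, 0–100) are combined into a composite
disability axis: a least-squares regression of ODI on VAS supplies the
predicted ODI, and the composite is the mean of observed and VAS-predicted
ODI. The axis is cut at 20/40/60/80 — the conventional ODI severity bands,
consistent with the five state labels (Minimal, Moderate, Severe, Crippled,
Bedbound). Both the regression anchor and the thresholds are configurable,
because the source analysis prints neither its regression coefficients nor
its exact section boundaries; the ODI-band default is the natural choice
given that the state names are the classic ODI taxonomy.

Two numerical conventions are fixed and tested rather than left implicit:

* **Boundary tie-break.** Bands are half-open, `[lo, hi)`: a composite score
  exactly on a threshold belongs to the band whose lower edge it is (a
  composite of 40 is Severe). This makes classification deterministic and
  the mapping from composite score to severity monotone.
* **Tie-corrected correlation.** The VAS/ODI association is summarised by
  Kendall τ-b (target 0.655). Scores are discrete, so the tie-corrected
  variant is the only defensible choice. For large discretised samples,
  `kendall_tau()` uses a contingency-table algorithm (O(levels²) via 2-D
  cumulative sums) that is exactly equal to the O(n²) pair enumeration, which
  the test suite keeps as an independent oracle.

Transition matrices are estimated separately per follow-up interval (1.5, 3,
6, 12 months), matching the visit schedule to the cycle schedule. This avoids
the embeddability problems of converting matrices across intervals via matrix
roots. Rows with no observed transitions default to the identity row, which
keeps every estimate row-stochastic.

## The cohort engine

The cycle schedule starts short where recovery is fast and lengthens as the
trajectory stabilises: 1.5, 1.5, 3, 3, 3, then 12-month cycles, truncated or
extended to sum exactly to the analysis horizon (90 days, 1, 2, 6, 10 years).
Per cycle, with occupancy after the transition,

* QALYs: occupancy-weighted utility × cycle length in years × discount factor
  `(1.03)^(-t)` at cycle end;
* costs: occupancy-weighted per-state annual direct + medication costs scaled
  by cycle length, plus expected adverse-event costs, plus (societal only)
  productivity loss; discounted the same way;
* the index operation enters undiscounted at t = 0.

Deliberate conventions, each testable:

* **No half-cycle correction by default** (an option exists). The source
  analysis gives no indication of one, and the convention — accumulate at the
  post-transition occupancy, discount at cycle end — is stated once and used
  everywhere, including by the microsimulation oracle.
* **Adverse-event rescaling.** The published AE incidence is interpreted as a
  probability over a 12-month observation window and converted to a cycle
  probability by `p_cycle = 1 − (1 − p_window)^(Δt/12)`, the standard
  rate-based conversion that can never leave [0, 1]. AEs price care (a
  supplemental-procedure bundle or a reoperation, per the published action
  splits) but do not override the transition matrices: observed transitions
  already embed their outcomes.
* **Extrapolation.** Horizons beyond the 24-month trial window reuse the
  final 12-month transition matrix and per-state costs stationarily.
* **Device upcharge after payer blending.** The $4 000 TOPS upcharge is a
  device cost, added after Medicare/private blending rather than scaled by
  the private multiplier. At Medicare rates this reproduces the published
  TOPS facility fee exactly ($24 459 + $4 000 = $28 459), and it is what
  makes payer-mix scenarios behave as published: Medicare-only deflates the
  downstream savings more than the (fixed) upcharge, so the ICER worsens,
  while private-only improves it. Had the upcharge scaled with payer mix,
  every cost would scale together and the scenario ordering would invert.
  A corollary worth knowing: because facility fees are identical across arms,
  the surgical *setting* moves per-arm totals but cancels out of ΔCost.
* **Unprinted private rates.** Private fees default to 1.5 × Medicare
  (overridable per item); outpatient facility fees default to 0.75 × the
  inpatient DRG fee; the "mixed" setting averages the two. Medication costs
  enter as a per-state annual table defaulting to zero rather than invented
  prices; inflation is a single load-time multiplier (default 1).

A patient-level microsimulation (`microsimulate()`) draws individual state
paths from the same matrices and accumulators. Its means converge to the
cohort totals — the engine's correctness oracle, checked at n = 50 000 within
three Monte Carlo standard errors — and conservation holds exactly: with zero
discounting and unit utilities, total QALYs equal the horizon in years for
*any* row-stochastic dynamics.

## The calibrated fixture

The published analysis prints its per-arm discounted totals (cost and QALYs,
two perspectives, five horizons) but not the underlying utilities, per-state
costs, or transition matrices. The packaged parameter set
(`inst/extdata/fixture_params.json`, loaded by `fixture_model_params()`) is
therefore a **synthetic, back-solved stand-in**: `calibrate_fixture()`
minimises the summed squared relative error over all twenty published cells,
holding fixed everything that *is* printed (the fee schedule, AE incidence
and action splits, payer mix, upcharge, discount rate, initial state
distribution). Free quantities are the five utilities (constrained to
decrease with severity), five annual state costs (constrained nondecreasing),
per-arm early occupancy trajectories (realised as rank-one transition
matrices over the first year), one 12-month matrix per arm (reused
stationarily, matching the extrapolation rule), and per-arm unable-to-work
probabilities, which enter the societal targets linearly and are profiled out
by ridge-regularised least squares. The optimiser is nlminb: alternating
per-arm and shared blocks, then a joint polish with a few deterministic
jittered restarts. The frozen fit reproduces every published per-arm total
within 0.8% (cost) and 0.3% (QALYs); `verify_calibration()` recomputes the
comparison at any time, and `analysis/03_calibrate_model.R` regenerates the
fixture from scratch.

Two consequences deserve emphasis. First, the fixture is a *parameter
reconstruction*, not an estimate from data: its trajectories are the simplest
family sufficient to match the totals, so individual matrix entries carry no
clinical meaning. Second, small (<1%) per-arm errors can still move
*incremental* quantities noticeably — the model's own 2-year health-system
ΔCost is $191 against a published $300 — which is why the incremental
reproduction checks work from the published totals directly while the engine
calibration is judged on per-arm values.

## The synthetic trial

`generate_trial()` emulates the trial conditions the analysis assumes: 121
patients (the enrolment with complete 1-year follow-up; 127 with ≥1 year is
supported via config), 2:1 randomization rounding toward the experimental
arm, baseline age N(64, 8.26²), the published baseline state distribution
(0/4/27/39/30%), visits at 0, 1.5, 3, 6, 12 and 24 months, per-state/per-arm
AE incidence rescaled to each visit interval, work status per state, and a
50% retiree fraction mirroring the 50/50 Medicare assumption.

Correlated scores come from a Gaussian copula calibrated by Greiner's
relation ρ = sin(πτ/2) with truncated-normal marginals (VAS ~ N(7, 2²) on
[0, 10], ODI ~ N(55, 18²) on [0, 100]) — score marginals are not printed, so
these were chosen once as clinically typical for a surgical stenosis cohort
and kept. Scores are rounded to a configurable precision. The default grid is
0.01 on both scales: coarse instrument rounding (VAS to 0.1, ODI to integers)
inflates sample τ-b by about +0.01, because the pairs that rounding converts
into ties are on average locally discordant, and the tie correction removes
them from the denominator asymmetrically. With the fine default the realised
τ-b of generated pairs stays within a few thousandths of the copula target;
the inflation effect is reproducible by passing coarser precisions.

At trial scale the generator draws each visit's state first (initial
distribution, then per-interval generating matrices — improvement-biased
recovery kernels, the arthroplasty arm slightly faster, with longer intervals
derived as matrix powers for mutual consistency) and then constructs a
(VAS, ODI) pair whose composite lies inside that state's band, splitting the
composite into the two scores with truncated-normal noise so classification
is exactly consistent with the drawn state. This conditional construction
trades some marginal rank correlation for state consistency (the trial-level
τ-b lands near 0.43–0.55 rather than 0.655); the copula path, which is what
the calibration target refers to, is exposed directly as `sample_vas_odi()`.
What passing tests show, therefore, is that the pipeline's statistical
machinery is self-consistent under data with the assumed structure — not that
real trial data look like this: there is no dropout, no missingness, no
within-patient serial correlation beyond the Markov property, and no
item-level instrument behaviour.

## Sensitivity analyses

* **Scenarios**: the 3 payer mixes × 3 settings grid minus the base case
  (eight scenarios). Identity overrides reproduce the base case exactly;
  Medicare-only worsens and private-only improves the ICER, as published.
* **One-way (tornado)**: all 39 inputs — 34 costs (21 fee-schedule items,
  5 state costs, 5 medication costs, wage, upcharge, supplemental bundle) and
  5 utilities — varied ±20% individually, probabilities clipped to [0, 1].
  The published text says "38 input parameters" in one place and "34 costs
  and 5 utilities" (= 39) in another; the registry exposes 39. When either
  ICER endpoint is a dominance label, tornado ordering falls back to the NMB
  range at $100 000/QALY.
* **PSA**: 5000 iterations, all registry parameters drawn simultaneously —
  gamma for costs with the conventional CV 15.3% (= 30%/1.96), and a beta
  with matched mean and SD on the utility *decrement* 1 − u. The source text
  assigns "gamma distributions … with lower and upper bounds of 0 and 1" to
  QALY decrements, which a gamma cannot satisfy; the beta honours the stated
  bounds, and a [0, 1]-truncated gamma is available behind a flag. Draws are
  made up front from one seed, so results are order-independent and exactly
  reproducible. The published 63.1% probability of cost-effectiveness at
  $100 000/QALY depends on per-parameter point estimates and CIs that are not
  printed, so it is not a reproduction target; the package's CEAC identities
  (value at λ = 0 equals P(ΔC < 0); the large-λ limit equals P(ΔE > 0)) hold
  exactly by construction.

## Problem sizes and numerical choices

The test suite and the acceptance script size their simulations for precision
with comfortable margins: 50 000 pairs for the copula check (Kendall τ
standard error ≈ 0.003), 100 000 patients for the baseline-state check
(binomial SE ≤ 0.0016 per state), 50 000 microsimulated patients for oracle
equivalence (3-SE criterion), 5000 draws per row for transition-matrix
recovery, and 100 random models for the conservation property. Currency is
kept in floating point throughout and rounded only for display. Simplex and
row-stochastic validity are enforced at 1e-9; occupancies are renormalised
never — they stay exact by construction.

## Known limitations

The model has no death state (consistent with its source), no patient-level
heterogeneity outside the microsimulation oracle, no multi-way efficiency
frontier, and no value-of-information analysis. The calibrated fixture's
trajectories are identifiable only up to the published totals; different
parameter sets could match them equally well. Scenario results for surgical
setting are structurally flat in the incrementals under the additive-upcharge
convention (see above), so setting uncertainty expresses itself in per-arm
totals only. Finally, the published initial-state text ("93% in the three
worst states") disagrees slightly with its own table (27 + 39 + 30 = 96%);
the machine-readable table values are used everywhere.
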