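---
title: "Methods: emulating a target trial of post-acute outcome risks and burdens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: emulating a target trial of post-acute outcome risks and burdens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(postacute)
```

## The design

`postacute` implements the observational design used by large
electronic-health-record studies of post-acute sequelae: an exposed cohort
(people with a positive test during an enrollment window), a contemporary
control cohort from the same calendar era, and a historical control cohort
observed two years earlier. Follow-up for everyone starts 30 days after an
index date T0 (a *landmark* analysis: only people alive strictly beyond
day 30 enter, and the clock starts there), and each outcome is analyzed in
an *incident* subcohort of people with no occurrence of that outcome in
the year before T0.

The stages, each a separate module with its own functions:

1. **Index dates.** The exposed group's T0 is its test date. Controls
   receive T0 drawn i.i.d. from the empirical distribution of exposed T0
   dates (`assign_control_t0()`), shifted back 730 exact calendar days for
   the historical group, so all groups share the same follow-up-time
   distribution. We use exact day arithmetic, not calendar-year
   arithmetic: 2020-03-15 minus 730 days is 2018-03-16.
2. **Incident subcohorts.** `build_subcohort()` excludes people with the
   outcome in the lookback year, takes the first occurrence strictly after
   the day-30 origin as the event, censors at death (the competing risk),
   the group-specific administrative end of follow-up, and optionally an
   external event such as first vaccine dose. Composite outcomes take the
   earliest component event; MACE (all-cause mortality, myocardial
   infarction, stroke) includes death as an *event*, so it has no
   competing-risk channel.
3. **Covariates.** Pre-defined covariates are imputed by conditional mean
   within exposure group and continuous ones expanded to restricted cubic
   splines. High-dimensional codes from three domains (diagnoses,
   medications, laboratory abnormalities) are screened: codes occurring in
   at least `min_count` (default 100) people *per group* are ranked by
   univariate relative risk against exposure and the top `k` (default 100;
   300 in a sensitivity variant) are kept (`rank_high_dim()`).
4. **Weighting.** Each comparison group is standardized to a target
   population by inverse-odds weights `w = p/(1-p)`, `p` the modeled
   probability of target membership, and balance is checked by
   standardized mean differences (adequate below 0.1 by convention).
5. **Estimation.** Weighted cause-specific Cox models (Efron ties, robust
   sandwich variance clustered on persons) give hazard ratios; weighted
   Aalen–Johansen curves give 12-month burdens per 1,000 persons and the
   excess burden; a difference-in-differences analysis contrasts
   exposed-vs-control incident rate ratios after T0 with those in a
   matched pre-exposure period.
6. **Controls.** Negative-outcome, positive-outcome, and negative-exposure
   (calendar-day parity) control batteries rerun the identical pipeline
   with only the outcome or exposure substituted.

## The synthetic cohort generator

No individual-level data from studies of this design are publicly
available, so the package ships a generator (`sim_config()`,
`generate_cohort()`) whose output has the statistical structure the
analysis assumes, with known ground truth:

* **Event times** follow piecewise-constant (exponential) cause-specific
  hazards. Every person's event clock runs on *calendar time* from a fixed
  origin `history_days` (default 1,095 d) before the enrollment window;
  exposed people switch to exposure-multiplied rates at T0. Because the
  exponential is memoryless, the residual time from any later origin —
  the assigned control T0, the day-30 landmark — remains exponential at
  the same rate, which keeps closed-form oracles exact and produces
  pre-T0 history organically.
* **Confounding** enters through shared linear predictors: standard-normal
  confounders shift the exposure logit (rejection sampling from the
  tilted conditional laws) and multiply every cause-specific hazard. The
  crude hazard ratio is therefore biased by construction and the
  weighting has something real to correct.
* **Codes** are sparse per-domain binaries (defaults 540/543/62, matching
  the size of a realistic three-domain screen); a handful per domain ride
  on the confounders so the high-dimensional screen has signal, the rest
  are noise.
* **Care settings** (non-hospitalized / hospitalized / ICU, default
  probabilities 0.856/0.109/0.035) can carry graded exposure effects.
* **Missingness** is completely at random; the imputation rule under test
  says nothing about the missingness mechanism, so MCAR is the cleanest
  stress for it.

Default baseline rates (2×10⁻⁵–2×10⁻⁴ per day, death 8×10⁻⁵) are
*arbitrary desk-scale choices* — no published per-outcome baseline rates
exist for this design's cohorts — and are documented as such in
`?sim_config`. The validation studies in the test suite use rates near
2–3×10⁻⁴ per day (≈7–10% annual incidence) so that replicate studies have
event counts commensurate with their stated Monte-Carlo precision.

What the generator does **not** emulate: real code semantics, informative
censoring, time-varying hazards beyond the piecewise-constant switch at
T0, recurrent events (only first occurrences exist), or calendar trends in
incidence. Passing tests therefore demonstrate the estimators do what
they claim under the design's assumptions — not that those assumptions
hold in any particular real data set.

## Estimands, weighting, and a non-collapsibility caveat

The target population defaults to the union of the exposed and
contemporary groups (standing in for "all health-system users of the
pre-exposure year"). For a comparison side that is itself a constituent
of that union, the density-ratio weight to the target has the closed form
`π/e(x)` (exposed side) or `(1−π)/(1−e(x))` (the other constituent),
where `e(x)` is the exposure propensity *within the union* and `π` the
union's exposed fraction. We estimate `e(x)` by main-effects logistic
regression, which is exactly specified when group membership follows a
logistic selection model — whereas regressing "target membership" on the
stacked group-plus-target rows has an intrinsically non-linear log-odds
(the target is a mixture), and a main-effects fit there leaves residual
bias. Sides from outside the target (the historical group, whose density
the union does not contain) use the direct stacked propensity; its
misspecification is second-order at the effect sizes simulated here.
`weight_to_target()` exposes the generic stack; `pipeline_weights()`
applies the decomposition automatically.

The weighted Cox coefficient estimates a *marginal* hazard ratio in the
target population. With multiplicative frailty (the confounder effect on
hazards) and a shared competing death process, the marginal cause-specific
HR is attenuated relative to the conditional one as susceptibles deplete —
a non-collapsibility effect of order the cumulative incidence times the
frailty variance, about −0.01 on the log scale at the simulated event
rates. The parameter-recovery study measures total bias (estimation plus
estimand gap) against the conditional truth and finds it within ±0.02,
which is the package's accuracy claim; users comparing against conditional
effects at much higher event rates should expect visible attenuation.

Robust sandwich variances treat each person as an independent cluster.
They account for the weights being random but not for the efficiency gain
from estimating them; coverage in the validation study sits slightly above
95%, the usual mildly conservative behavior of IPTW sandwich intervals.

## Numerical and design choices

* **Ties**: Efron approximation; fixtures used for exact oracles are
  tie-free.
* **Acute-window events** (T0 to T0+30): excluded from that outcome's
  subcohort by default — they make the person non-incident at the origin.
  `cohort_spec(acute_events = "ignore")` instead retains such people
  event-free, the other defensible reading; the choice moves subcohort
  sizes by about 1% at simulated rates.
* **"Alive 30 d after"**: survival strictly beyond day 30; death on day
  30 exactly excludes.
* **RR ranking**: "strongest relative risk" is read as largest |log RR|,
  so protective and risk codes both qualify; `ranking = "raw"` gives the
  literal reading. Zero cells get a 0.5 continuity correction. Ties break
  lexicographically by (domain, code), making selection order-invariant.
* **Spline knots**: 4 knots at quantiles 0.05/0.35/0.65/0.95; skewed
  count covariates whose quantile knots collapse fall back to linear
  terms.
* **Weight truncation**: off by default (mirroring the primary analysis
  this design describes); a quantile cap is available for stability.
* **Burden CIs**: person-level nonparametric bootstrap (500 resamples by
  default), weights travelling with their persons; the method under
  emulation does not state how burden CIs were formed.
* **DiD variance**: the pre- and post-period IRRs share persons, so the
  independent-period variance of `did_ratio()` understates their
  correlation. `did_estimate()` bootstraps persons jointly across both
  periods and is what the validation study uses.
* **Pre-period construction**: each person's pre-exposure window has
  exactly their post-exposure *potential* follow-up length (to death or
  administrative end, not truncated at the outcome), ending at T0; people
  whose window plus lookback year precedes the start of observable data
  are dropped with a reported count.
* **Degenerate inputs**: a group with no events, zero-follow-up persons,
  propensity separation, and empty subgroups all raise or flag rather
  than silently proceeding; a time-varying term that never varies is
  reported as aliased.

## Validation studies and their sizes

The acceptance suite (`tests/testthat/test-acceptance.R`) runs, at sizes
chosen to keep the full suite within a routine CI budget while giving
each check the precision it needs:

* parameter recovery: 25 cohorts of 50,000 exposed / 50,000 controls,
  true HRs 1.7 and 1.0 with active competing death — mean weighted
  log-HR bias below 0.02, crude bias above 0.05;
* CI coverage: 200 cohorts of 5,000/group — 92–98% coverage for the
  weighted HR and the DiD ratio (joint bootstrap, 400 resamples);
* closed-form burden oracle at n = 100,000 within 3 binomial SEs;
* balance: max |SMD| < 0.1 after weighting at 10,000/group;
* graded severity 1.2/1.8/2.5 ordered correctly in ≥95% of 50 replicates
  at 20,000 exposed;
* control batteries (7 negative outcomes × 20 replicates at 10,000/group,
  positive control HR 1.5 at 20,000/group, parity split in a null world);
* exact small-fixture oracles (partial-likelihood score root,
  Aalen–Johansen hand recursion, RR ranking, SMD, IRR, calendar
  arithmetic) and byte-identical reruns.

`scripts/acceptance.R` re-runs condensed versions of the same studies
from the installed package and writes the measured quantities as JSON.

## Known limitations

Only first occurrences are modeled, so recurrent-event burdens are out of
reach. The pre-period of the DiD reuses covariates measured in the T0
lookback (all simulated covariates are time-invariant). Fine–Gray
subdistribution hazards, frailty models, multiplicity adjustment, and
empirical negative-control calibration are deliberately absent. The
historical-side propensity uses the direct stack and inherits its mild
misspecification. Burdens are weighted nonparametric Aalen–Johansen
estimates, not model-standardized curves — the emulated design does not
say which it used, and the nonparametric choice needs no additional
modeling assumptions.
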