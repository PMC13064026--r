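---
title: "Methods: validating PREDICT-style prognostic models under competing risks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating PREDICT-style prognostic models under competing risks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What this package does

`predictval` implements the full machinery of an external-validation
study for the PREDICT breast-cancer prognostic model: the risk engine
itself (v2.2 and v3.0), preparation of a registry-style cohort
(eligibility, biomarker and treatment mapping, horizon restriction,
subgrouping), a synthetic cohort generator with known ground-truth risk
structure, and the two performance statistics such studies report —
smooth model-based calibration (with the integrated calibration index,
ICI) and time-dependent discrimination (tdAUC) — with percentile
bootstrap inference including paired version differences.

## The risk engine

PREDICT is a pair of cause-specific proportional-hazards models, one
for breast-cancer death (stratified by ER status) and one for
other-cause death. For patient $i$ and cause $c$ the cumulative hazard
at year $t$ is

$$H_{c,i}(t) = H_{0,c}(t)\,\exp\{\eta_{c,i} + \tau_{c,i}\},$$

where $H_{0,c}$ is a parametric baseline cumulative hazard,
$\eta_{c,i}$ the covariate prognostic index (fractional-polynomial age
terms for ER-positive disease, log-transformed size and node count,
grade, detection mode, HER2/Ki67/PR level offsets) and $\tau_{c,i}$ the
sum of adjuvant-treatment log hazard ratios (endocrine therapy,
chemotherapy by generation, trastuzumab, bisphosphonates; v3.0 adds a
radiotherapy benefit and per-Gray mean-heart-dose harm that doubles for
smokers). The engine accumulates hazards on a yearly grid (years 1–15)
and apportions each year's deaths to causes in proportion to the
cause-specific hazard increments, which makes
`bc + other + survival = 1` hold to machine precision by construction.

All numeric content lives in versioned JSON coefficient files
(`inst/extdata/`). The v2.2 file transcribes the published algorithm.
The v3.0 file is a **synthetic stand-in**: it has the documented v3.0
structure (PR terms, smoking, radiotherapy benefit/harm, recalibrated
baselines) with literature-scale placeholder values, because the
released v3.0 numerics are distributed as source code on request rather
than in print. Every statistical property this package is tested on is
invariant to the exact values; users validating against the real tool
should drop a transcription of the released algorithm into the same
schema (the loader validates it: version tag, required term resolution,
nonnegative nondecreasing baselines).

The ten-year endocrine option — the only difference between v2.1 and
v2.2 — is encoded as an extra log hazard ratio that applies after year
10, so it exists in the interface but cannot alter the 5- and 10-year
outputs this package validates.

### "Unknown" levels

HER2, Ki67, PR, detection and micrometastasis status keep the tool's
explicit *unknown* levels as distinct coefficients; nothing is imputed.
Smoking, absent from registries, is set uniformly: all never/ex-smokers
in the primary analysis, all smokers as a sensitivity mode (a v3.0-only
variable, so v2.2 results are invariant to it — this invariance is
tested).

## Cohort preparation

Eligibility (female, age 25–40 inclusive, invasive stage I–III disease,
surgery, ER percentage and grade recorded, positive follow-up) is
applied in a fixed order with a first-failing-rule exclusion ledger.
Biomarker thresholds follow Swedish practice: ER/PR positive at ≥ 10%
stained cells, Ki67 positive strictly above 10%, HER2 positive for IHC
3+ or IHC 2+ with ISH amplification. Chemotherapy regimen text is
token-matched (taxane tokens → third generation, anthracycline tokens →
second); unrecognized tokens are an error, never a silent default.
Mean heart dose is coded 2 Gy for irradiated left-sided disease and
0 Gy otherwise. Follow-up is `(event date − diagnosis date)/365.25`;
calendar-year arithmetic clamps Feb 29 to Feb 28 in non-leap years.
Horizon restriction keeps patients whose diagnosis date lies at least
5 (or 10) calendar years before the registry cut-off and recodes later
events to censored-at-horizon (events exactly at the horizon remain
events).

Subtype uses ER/PR/HER2: HER2+ whenever HER2 is positive; TNBC when all
three are negative; Luminal for ER+/HER2-non-positive. HER2-unknown
with ER− lands in an explicit *unclassifiable* bucket that is excluded
from subtype analyses only — the subgroups therefore always partition
the cohort, which the tests assert.

## Synthetic cohorts with known truth

The generator draws covariates from marginals chosen to resemble a
young (≤ 40) breast-cancer registry population: subtype mix
59/21/20% (Luminal/HER2+/TNBC), ER+ ≈ 74%, grade 3 ≈ 55%,
node-negative ≈ 60%, log-normal tumour size with 20 mm median, ages
concentrated in the late 30s, diagnoses uniform over 2008–2019 and an
administrative cut-off of 2021-03-09. Treatment assignment respects
clinical coherence (trastuzumab only for HER2+, endocrine therapy
predominantly for ER+). The dependence structure beyond these
conditionals is deliberately simple; it is plausible rather than a
joint-distribution match, which no statistical property here requires.

Outcomes are simulated so that the *true* breast-cancer risk is a known
transform $g$ of the engine's prediction: identity (perfect
calibration), proportional $g(p) = kp$, or a constant shift on the
cloglog scale (proportional-hazards miscalibration). A two-piece
constant hazard on $[0,5)$ and $[5,\infty)$ is solved in closed form so
the cumulative risks at 5 and 10 years equal $g(p_5)$ and $g(p_{10})$.
Other-cause death and emigration are exponential with configurable
rates (defaults 0.001 and 0.002 per year, matching the order of
magnitude seen in young cohorts), and administrative censoring follows
from the diagnosis date. The stored truth table lets tests compare any
estimate against a brute-force answer.

One global seed drives everything through fixed substreams (covariates,
outcomes, bootstrap replicates), so each stage is reproducible in
isolation.

What the generator does *not* emulate: treatment selection bias,
screening programme dynamics, calendar trends, or measurement error in
biomarkers. Passing tests therefore demonstrate correctness of the
statistical machinery under a known data-generating process, not
real-world performance of PREDICT.

## Calibration: piecewise-exponential Poisson GAM

Follow-up is split at event-time deciles (union the horizon; yearly
grid as fallback) into person-time intervals; interval event counts are
modelled as Poisson with a log link and log-exposure offset — the
piecewise-exponential likelihood. The linear predictor contains a cubic
regression spline in interval time (baseline hazard, 10 knots), a cubic
regression spline in $\operatorname{cloglog}(p)$ of the predicted risk
(10 knots), and a 5×5 tensor-product interaction with an additional
null-space shrinkage penalty so non-proportional hazards can be
expressed but shrink away when unsupported. With more than one event
cause, cause enters as a parametric factor plus shrinkage-penalized
cause-by-smooth difference terms; emigration is a third cause level
that contributes no mortality. Smoothing parameters are selected by
REML (`mgcv::gam`; `mgcv::bam` with covariate discretization beyond
50k stacked rows). One deliberate detail: the time covariate is the
midpoint of the *full* grid interval shared by every row in it — giving
event rows (truncated at their event time) their own time value lets
the time smooth chase individual event times and badly inflates the
early hazard.

The model-based *observed risk* at predicted risk $p$ is computed from
the fitted cause-specific hazards at $x = \operatorname{cloglog}(p)$:
all-cause as $1 - \exp\{-(H_{bc} + H_{oth})\}$, breast-cancer-specific
as the competing-risks cumulative incidence
$\int_0^h S(u)\,h_{bc}(u)\,du$. The integral is evaluated by treating
the fitted hazard as piecewise constant over a 512-point grid — a
product-integral that is *exact* whenever the fitted hazard is constant,
which is what makes the closed-form oracle tests hold to $10^{-8}$
rather than to quadrature error. The cumulative-incidence definition is
a choice (the cause-specific alternative $1 - e^{-H_{bc}}$ differs only
through competing mortality, negligible in young cohorts); the
integral form is the one consistent with observed event frequencies.

The ICI is the patient-average of $|{\rm observed}(p_i) - p_i|$
(reported ×100). For large cohorts the observed-risk functional is
evaluated on a 128-point grid in $x$ and linearly interpolated to the
patients — the direct evaluation at every distinct $p$ is available and
the two agree to $10^{-6}$ in tests. Predicted risks are clamped to
$[10^{-6}, 1-10^{-6}]$ before the cloglog. Calibration-curve confidence
bands come from 200 draws of the coefficient vector from its Gaussian
posterior (mean $\hat\beta$, covariance $V_p$) propagated through the
observed-risk functional.

## Discrimination: IPCW tdAUC

The cumulative/dynamic AUC at the horizon: cases are target-cause
events in $(0, h]$ (closed at the horizon); controls are subjects
event-free past the horizon plus, for the cause-specific outcome,
competing-cause deaths before it (the cumulative-incidence-consistent
convention); emigration before the horizon is censoring for this
estimator. Subjects are weighted by $1/G(\min(T, h)-)$, with $G$ the
Kaplan–Meier estimator of the administrative censoring distribution,
and score ties receive half credit. A brute-force pairwise enumeration
oracle (valid only without pre-horizon censoring) must agree with the
estimator to $10^{-12}$, and does so across 50 random fixtures in the
acceptance suite.

## Bootstrap inference

Percentile bootstrap over patient resamples, unstratified, B = 200 by
default, per-replicate substreams derived from (seed, replicate);
replicates are retained on the result so the CI endpoints are visibly
order statistics. Failed resamples are redrawn up to a 10% cap, then
the run aborts with diagnostics. Paired version differences recompute
both versions on the same resample; the `significant` flag is set iff
the CI excludes zero.

Two smoothing-parameter policies are exposed: re-estimation inside
every resample (default — it propagates selection uncertainty) and
freezing at the full-data fit. For the frozen policy there is a fast
path (`fast_ici_bootstrap`, `fast_paired_ici_diff`) exploiting the fact
that a patient resample is a multiplicity-weighted copy of the original
person-time: the expansion, design matrix, penalty and evaluation grid
are built once and each replicate is a penalized IRLS reweighting. The
refit is equivalence-tested against the weighted `mgcv` fit at
$10^{-5}$. The bootstrap-coverage experiment in the acceptance suite
uses this frozen-policy path; at its scale (50 outer replicates ×
B = 200 at n = 2000) coverage lands in the nominal band, suggesting
smoothing-parameter uncertainty is not a leading error term for the
ICI at these sizes.

## Problem sizes and numerical choices

The test suite runs its large calibration checks at n = 20,000 patients
(null calibration and known-distortion recovery), the constructed
version-comparison at n = 5,000 with B = 200, and the coverage smoke at
50 × B = 200 × n = 2,000 — sizes chosen so each property is measured
with comfortable Monte-Carlo margin. Penalized IRLS uses a relative
deviance tolerance of $10^{-8}$ (max 50 iterations); REML convergence
is delegated to `mgcv` and non-convergence is surfaced, never silently
accepted. Tied event/horizon times count as events; exposure-zero rows
are dropped in the expansion; `0/0` hazard shares apportion no deaths.

## Known limitations

* The v3.0 coefficient values are synthetic stand-ins (structure, not
  estimates); absolute risk outputs under v3.0 are illustrative.
* The tdAUC is the plain IPCW cumulative/dynamic estimator; kernel
  -smoothed variants are out of scope.
* The calibration GAM treats emigration as administratively
  ignorable given the model; informative emigration is not modelled.
* Under proportional-hazards truth the shrinkage tensor retains a
  couple of noise effective degrees of freedom at large n rather than
  vanishing; its effect on the observed-risk functional is negligible
  (tested), but the edf itself is not a clean test statistic.
* 15-year outputs exist on the risk-curve grid but are not a validated
  surface.
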