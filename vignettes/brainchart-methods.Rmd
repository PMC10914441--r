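---
title: "Lifespan brain charts and atrophy staging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lifespan brain charts and atrophy staging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainchart)
```

## The problem

Progressive supranuclear palsy, Richardson syndrome (PSP-RS) is a 4R
tauopathy whose atrophy cascade is well described post mortem but hard
to observe in vivo: patients are only imaged late (roughly ages 55-86),
years after neurodegeneration starts. This package implements a
brain-chart strategy for inferring the full atrophy timeline from
cross-sectional volumetry alone:

1. fit a *normative lifespan trajectory* (a "brain chart") of each
   brain structure's volume against age in healthy controls spanning
   roughly ages 1-100;
2. fit a matching *disease trajectory* constrained over the whole
   lifespan by pooling the patients with all controls strictly younger
   than the youngest patient (justified by the assumption that
   neurodegeneration is continuous and progressive, so pre-symptomatic
   subjects at young ages are indistinguishable from controls);
3. declare a structure significantly smaller in disease from the
   earliest age at which the two trajectories' 95% confidence bands no
   longer overlap, and stay separated;
4. order the divergence onsets chronologically and group them into
   anatomical stages — the staging timeline.

Everything operates on tabular inputs: one row per subject with age,
total intracranial volume (TIV) and raw structure volumes in mm³.
Image processing (segmentation, QC) is upstream and out of scope.

## Preprocessing model

Left and right volumes of symmetric structures are summed. Volumes are
normalized as a percentage of TIV, $v = 100 \cdot \text{raw}/\text{TIV}$,
removing head-size variability, and then z-scored against the control
sample of the same structure,
$z = (v - \bar v_{\text{ctl}})/s_{\text{ctl}}$, so structures of very
different sizes share one scale. The reference population is all
controls over the whole lifespan: this keeps the healthy chart centred
and makes patient z-scores read as deviations from normal; it is
configurable via `zscore()`. A one-sample Kolmogorov–Smirnov check of
each structure's normalized control volumes against a fitted normal law
is recorded at the 95% level; failures are flagged in the run report
but never excluded (no exclusion rule is defensible without inspecting
the data, and the marginal distribution pools all ages, so mild
rejections are expected). Note the test statistic uses estimated
moments, which makes the flag conservative. Subjects whose residual
from the final fitted trajectory exceeds 2 residual standard deviations
are likewise flagged for human review, never auto-removed.

## Trajectory model

For one structure and one group, with ages $a_i$ and z-scores $z_i$,
candidate models are polynomials fitted by ordinary least squares from
the simplest to the most complex:

$$ z = \beta_0 + \beta_1 a + \dots + \beta_k a^k + \varepsilon,
   \qquad k \in \{1, 2, 3\}, \quad \varepsilon \sim N(0, \sigma^2). $$

A candidate is *eligible* only if its F test against the constant model
is significant at $P < 0.05$ **and** every coefficient's two-sided
t test is significant at $P < 0.05$. Among eligible candidates, the one
with the lowest BIC is selected, with ties broken toward the lower
degree; if none is eligible the constant model is returned, flagged as
a fallback. Two decisions here were genuinely open:

* **Intercept gate.** "All coefficients significant" could include the
  intercept. On z-scored data the intercept is not a shape parameter —
  requiring its significance would spuriously reject well-centred
  trajectories — so the gate covers the non-intercept coefficients by
  default (`gate_intercept = TRUE` restores the stricter reading).
* **BIC variant.** BIC is computed as
  $n \ln(\mathrm{RSS}/n) + k \ln n$ with $k = \text{degree} + 2$
  (coefficients, intercept, residual variance). Any affine-equivalent
  variant gives the same ranking at fixed $n$; this one is used
  consistently everywhere.

Fits use the raw-age basis (years, untransformed) so reported
coefficients are directly interpretable; the QR decomposition keeps
this stable for ages up to 100, which the test suite verifies against
an independently coded normal-equations oracle to 1e-8 relative error.

Pointwise bands at level $1-\alpha$ are confidence bounds for the
*mean curve*: $\hat z(a) \pm t_{n-p,\,1-\alpha/2}\, \mathrm{se}(\hat z(a))$
with $p$ the number of coefficients and the standard error from the
coefficient covariance. Observation-level prediction bands
(`mode = "prediction"`) are provided but are not the default: with ~60
patients they are several z-units wide and would almost never separate,
while the divergence criterion is about the *models* differing.
Evaluation outside the training age range errors by default
(`extrapolate = 0` in `confidence_band()`); the staging pipeline
relaxes this only as far as the severity reference age requires (see
below).

## Divergence and staging

On a common age grid (0.5-year steps over the ages both models
support), a structure diverges, case-smaller, at onset $a^\*$ — the
smallest grid age such that the disease band's upper bound stays
strictly below the healthy band's lower bound from $a^\*$ through the
end of the grid. The *sustained* rule (rather than first instantaneous
non-overlap) ignores transient band crossings from fit wiggle; the
first-crossing variant is available (`rule = "first"`). Non-overlap of
two 95% confidence intervals is conservative relative to a two-sided
Welch comparison of the fitted means at the 5% level — the suite
verifies zero exceptions over 1000 random model pairs — which is the
multiplicity argument for scanning many structures and ages without a
formal correction. Divergence with the case trajectory *above* the
healthy one is reported as an anomaly and never staged.

Severity is the signed difference of the fitted means at a reference
age (default 90 years), in z-units. The reference age typically exceeds
the oldest patient, so the pipeline permits the models to be evaluated
up to `max(extrapolate, ref_age - oldest common age)` years beyond
their training range for this score (and only for it — non-overlap is
decided on supported ages).

Staging walks the diverged structures in onset order: an entry joins
the current stage when its onset lies within `gap_threshold` (default
2) years of the previous entry, or when it shares an anatomical group
(e.g. putamen/caudate/accumbens = striatum, per the bundled
Neuromorphometrics-style grouping map) with a member of the current
stage; otherwise it opens a new stage. Published staging schemes of
this kind involve expert judgment; the (`grouping_map`,
`gap_threshold`) parameterization is an explicit, reproducible stand-in
for it, and both are recorded in the output. Ties in onset are broken
by larger severity, then name; stage counts are monotone non-increasing
in the threshold, and row order never matters (both are tested).

## The synthetic cohort generator

`simulate_cohort()` emulates the multi-study cross-sectional design on
which such charts are estimated: several control cohorts with distinct
age windows jointly covering ages ~1-100, one patient cohort restricted
to ages 55-86, cohort-specific TIV distributions (truncated normal) so
normalization is genuinely exercised, and symmetric structures emitted
as left/right columns so summation is exercised. Per structure, the
generator takes a healthy polynomial in z-units (degree ≤ 3), and
cases deviate by a piecewise-linear hinge: nothing before
`onset_age`, then `deviation_rate` z-units lost per year — the
simplest trajectory consistent with continuous, progressive
neurodegeneration. Observation noise is homoscedastic Gaussian in
z-units (`noise_sd`, default 0.8 z — a free simulation parameter;
real residual noise is not characterized, and the normality gate
presumes approximate normality). Reference statistics (`ref_mean`,
`ref_sd`, in % of TIV) map z-units back to raw mm³; values implying a
negative volume are clamped at a 1 mm³ floor and counted. Ages are
uniform within each cohort window. Everything is a deterministic
function of `(specs, truths, seed)`.

What the generator does *not* emulate: scanner/site effects beyond TIV
differences, heteroscedastic or age-dependent noise, segmentation
failure modes, non-hinge (e.g. sigmoidal) deviation kinetics, and
left/right asymmetry of disease effects. Passing recovery tests
therefore demonstrate the statistical machinery under the stated
generative assumptions, not robustness to those real-data features.

The default truth table `psp_truths()` reproduces the canonical PSP-RS
cascade — ventral diencephalon first (onset ~40, before any patient is
observable), then pallidum, then brainstem/striatum/amygdala, a
severely affected thalamus, frontal and occipital cortex last, plus a
spared hippocampus and cerebellum — with deviation rates giving
reference-age distances of realistic magnitude (thalamus ~4 z,
pallidum ~2.9, brainstem ~2.4). `recovery_scenario()` is the
benchmarking configuration: 2000 controls (ages 1-100), 60 cases
(55-86), 8 structures with onsets 46, 50, …, 74 (4 years apart,
straddling the start of the observation window so pre-window
extrapolation is exercised) at a common 0.10 z/yr rate.

```{r, eval = FALSE}
sim <- simulate_cohort(psp_cohorts(2000, 60), psp_truths(), seed = 42)
run <- stage_cohort(sim$subjects, metadata = default_structure_metadata())
print(run)
plot(run$scheme)
```

## Numerical and degenerate-input choices

* Rank-deficient designs (all ages equal) and $n < \text{degree} + 2$
  are hard errors; all-NA pairs are dropped before fitting.
* A numerically perfect fit (RSS ≈ 0) drives BIC to $-\infty$;
  selection still works because eligible candidates are compared by
  value.
* Zero reference variance makes z-scoring error, and constant samples
  are "untested" by the KS check rather than tested against a
  degenerate law.
* Grid onset is reported at grid precision (0.5 years); no
  interpolation between grid points is attempted.
* CSV output renders doubles with 17 significant digits so written
  tables read back bit-identically; run outputs contain no timestamps,
  making reruns byte-identical.

## Known limitations

**Onset compression.** The divergence onset is the age at which
mean-curve bands separate, and with thousands of controls those bands
are a few hundredths of a z-unit wide. A global polynomial cannot
represent a hinge: its least-squares fit departs from the healthy curve
*before* the true onset (and the earlier departure grows with the
terminal deficit). The two effects together bias detected onsets — late
true onsets are detected up to a decade early, early ones slightly late
— compressing the recovered timeline. On the benchmark scenario the
median absolute onset error is ≈ 5.5 years and the recovered ordering
of 4-year-spaced onsets is only moderately reliable (Kendall tau
typically 0.5-0.8). The *presence* of divergence, the direction, the
severity ranking and the coarse stage structure are much more robust
than the individual onset ages; downstream interpretation should treat
the timeline as ordinal-with-uncertainty, not as calendar truth. In the
noiseless large-sample limit the detected onset converges to the
polynomial-approximation crossing, not the true hinge age — the test
suite checks the implementation against an independent refit oracle
rather than against unattainable exact recovery.

**Extrapolated severity.** The distance at the reference age usually
requires extrapolating the disease model a few years beyond the oldest
patient; cubic tails make this score overshoot by ~10-15% in
simulation. It is a ranking score, not an unbiased effect estimate.

**No covariates.** Sex is carried through but not modelled (the
trajectories are age-only); there is no site harmonization and no
mixed-effects or GAM machinery — the procedure is deliberately plain
polynomial OLS.

## Problem sizes used by the checks

The packaged statistical checks use: 100 random instances for oracle
equivalence; 1000 refits at $n = 200$ for band calibration; 200
replicates of the 2000+60-subject null for the false-positive rate;
20 seeds of the benchmark scenario for onset recovery; 1000 random
model pairs for conservativeness; and 200 replicates at $n = 500$ for
degree selection. A full simulate-fit-stage run at 2060 subjects and
11 structures takes well under a second.
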