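---
title: "White-matter FCS analysis: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{White-matter FCS analysis: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmfcs)
```

## The measure

Given cleaned region-mean BOLD time series, the package computes the
Pearson correlation between every pair of regions, Fisher-z transforms it
(`z = atanh(r)`, variance-stabilizing so z values can be averaged), and
summarizes each region by its mean z over a family of regions:

* **WW-FCS** — a white-matter region's mean z with the other white-matter
  regions (49 of them in the default 164-region scheme);
* **GW-FCS** — a gray-matter region's mean z with all 50 white-matter
  regions.

Raw signed z values are averaged, with no absolute value or threshold:
the FC matrix is defined on the z scale, and a mean of signed values is
the literal reading of "average connectivity". Negative correlations
therefore reduce FCS. Pairs with missing z (e.g. a region with no voxels)
are dropped from the mean and counted (`n_missing`), rather than
discarding the subject.

Degenerate correlations are clipped to `|r| <= 1 - 1e-7` before `atanh`
(giving z of about 8.41) with a warning; this keeps every statistic finite
and makes the behavior of duplicate or near-duplicate series testable
rather than infinite. Zero-variance regions yield NA rows/columns with a
warning.

## The parcellation

The default scheme concatenates 100 cortical regions (Schaefer-style
network names, 50 per hemisphere), 14 subcortical structures (7 per
hemisphere) and 50 white-matter tract labels (JHU-style: 6 midline
structures plus 22 left/right pairs), in that order, ids 1–164. The
gray-matter family is cortical + subcortical (114); the white-matter
family has 50. Non-default counts generate placeholder names so that
small simulation studies use the same code paths.

`combine_atlases()` re-indexes several label volumes into one contiguous
id space preserving (atlas, original-id) order. Voxels labeled by more
than one atlas go to the earlier-listed atlas, and the conflict count is
reported — overlap handling between cortical, subcortical and tract
atlases is genuinely underdetermined, so the precedence is simply the
order in which the user lists the atlases. Extraction is an unweighted
mean over each region's voxels, with empty regions reported as missing
rather than failing the subject.

## Frame-level cleaning

`clean_timeseries()` applies, in order:

1. **Initial-volume dropping** (default 5 frames; 240 acquired frames
   become 235) from both the series and the motion trace.
2. **Framewise displacement** on the dropped trace (Power's convention:
   sum of absolute backward differences of the three translations plus 50
   mm times the rotation differences; the 50 mm head radius is the
   metric's standard and rotations are expected in radians, with a
   degrees switch for other motion-correction dialects). The first frame
   has FD 0 so frame alignment stays trivial.
3. **Censoring**: frames with FD > 0.5 mm are replaced by linear
   interpolation between the nearest unflagged neighbors (edge frames
   take the nearest unflagged value). Unflagged frames are untouched bit
   for bit and re-censoring is a no-op. Censoring precedes the
   regression step so the nuisance model is fitted to spike-free data.
4. **Nuisance + drift + high-pass as one projection**: the Friston
   24-parameter motion model (6 parameters, their one-frame lags
   zero-padded at the first frame, and both sets squared), linear and
   quadratic trends over the centered frame index, and the
   discrete-cosine components with frequency `k/(2·n·TR)` below the 0.01
   Hz cutoff are assembled into a single design (plus intercept) and
   removed by one ordinary least-squares projection.

The joint projection deserves a note. Projecting out nuisance columns and
then, separately, low-frequency DCT columns is *not* the same as
projecting onto the orthogonal complement of their combined span: the two
subspaces are far from orthogonal (head-motion drifts are themselves
low-frequency), and sequential projections reintroduce part of what the
first one removed — differences of order 0.4 on unit-variance inputs in
our property checks. The joint projection is exact, idempotent, and
leaves residuals orthogonal to every nuisance and drift column
simultaneously, which is what the cleaning-linearity test asserts at
1e-8. The stepwise functions (`nuisance_regress()`, `highpass_filter()`)
remain exported for users who want the stages individually.

The DCT cutoff guard rejects cutoffs at or above the Nyquist frequency
`1/(2·TR)`; with TR = 2.4 s and 235 frames the default 0.01 Hz cutoff
removes the mean plus 11 cosine components. Rank-deficient designs are
handled by pivoting with a warning rather than failure, except in the
group-level model where collinearity is a user error and aborts with the
offending columns named.

## Subject-level quality control

Three rules, applied by `qc_subjects()`:

* Euler-number modified Z-score below −3.5 (median/MAD form
  `0.6745·(x − median)/MAD`, falling back to the scaled mean absolute
  deviation when the MAD is zero, and to all-zero scores when every value
  is equal);
* mean FD above 0.5 mm;
* motion-outlier ratio (flagged/total frames) above 0.3.

The two motion criteria are combined with OR by default — either alone
excludes — which is the conservative reading of "mean FD > 0.5 mm and
outlier ratio > 0.3" as a list of two criteria; `rule = "both_motion"`
gives the joint reading. The computed mean FD is written back into the
subject records because it is also a covariate of every downstream model.

## Group inference, dose associations, power

`region_group_test()` fits, per region, OLS of FCS on an intercept, a
group indicator (post-therapy = 1, so negative coefficients mean lower
FCS after therapy), age in years, sex (male = 1) and mean FD in mm, with
listwise deletion per region. The reported t and two-sided p belong to
the group coefficient. When the covariate set is empty the model reduces
exactly to the pooled two-sample t (a property test asserts agreement to
1e-10).

Benjamini–Hochberg correction is applied separately per family with
configurable family sizes (defaults WW = 50, GW = 114, the family sizes of
the default scheme). The implementation delegates to
`stats::p.adjust(method = "BH", n = m)`; allowing `m` to exceed the number
of supplied p-values supports adjusting a printed subset that is known to
contain the smallest members of its family. The test suite checks the
rejection set against an exhaustive step-up threshold search.

`partial_corr()` residualizes both variables on the covariates (plus
intercept) and correlates the residuals; the t statistic uses
`df = n − 2 − g` with `g` covariates, the convention of the commonly used
partial-correlation packages. `dose_association()` applies this to
dose-complete subjects of the post-therapy group only, reporting how many
subjects were excluded for missing dose.

`posthoc_power_two_sample()` evaluates the power of the two-sided
pooled-variance t test at the observed standardized difference
`d = |m1 − m2| / s_pooled` via the noncentral t distribution with
noncentrality `d·sqrt(n1·n2/(n1+n2))`. A Monte-Carlo cross-check (10^4
simulated t tests) agrees within sampling error in the test suite.

`demographics_table()` compares continuous variables by the pooled t,
sex by continuity-corrected chi-square, and clinical staging by
chi-square without continuity correction on available cases (missing
staging is counted and reported); an empty contingency cell switches to
Fisher's exact test with a warning.

## The synthetic-cohort generator

The generator exists so that every downstream stage is testable without
patient data. Its defaults emulate the study conditions the package
targets: 47 pre-therapy and 64 post-therapy subjects, 240 frames at
TR 2.4 s, the 164-region scheme, ages drawn at mean 46.7 (SD 9.6) and
43.4 (SD 9.9) years, roughly 3:1 male:female, Euler numbers at −50
(SD 15), staging frequencies with realistic missingness, and 37
post-therapy subjects carrying dose values.

Region time series are zero-mean multivariate normal with a
block-constant correlation matrix: 0.32 within white matter, 0.28 between
gray and white matter, 0.30 within gray matter. The gray–gray level is
not targeted by either FCS statistic but the joint matrix needs one; the
three defaults were chosen to satisfy positive definiteness (block
matrices of this form need roughly `gw² < gm·wm`; the chosen set has
minimum eigenvalue 0.124 with all default effects applied) while placing
the implied Fisher-z levels (0.33 within WM, 0.29 GM–WM) in the range of
reported pre-therapy FCS means. Group effects are expressed in z-space:
for each affected region, its correlations to its FCS family move as
`r' = tanh(atanh(r) − Δz)`, so a single region's family mean z drops by
exactly Δz (overlapping effects on multiple white-matter regions
additionally shift each other's means by Δz/49-scale amounts). The
default effect map reduces five white-matter and six gray-matter regions
by 0.06–0.08 z, matching reported group differences; these are
summary-matched simulation targets, not patient data. Every constructed
matrix is checked by Cholesky factorization and construction fails loudly
if the requested effects are geometrically infeasible.

Motion traces are small-increment random walks (translation increments
SD 0.008 mm, rotation increments SD 8×10⁻⁵ rad) whose FD stays far below
the 0.5 mm threshold; with probability `motion_spike_rate` per frame a
step displacement of 0.7–1.2 mm is injected, guaranteeing FD > 0.5 at
exactly the injected frames (returned for test oracles).

Dose variables are built from the model the analysis assumes, inverted:
the covariate-residualized FCS (standardized) enters with weight equal to
the target partial correlation and covariate-residualized independent
noise with weight `sqrt(1 − r²)`; the result is rescaled to a Gray-like
scale (mean 54, SD 6). The *population* partial correlation equals the
target, so sample estimates converge with n and show the usual
`(1 − r²)/√n`-scale spread across replicates — deliberately not an
exact-sample construction, which would have no sampling variability to
study. Each dose variable is constructed against the first target listed
for it; additional reported pairings emerge through inter-region
correlation rather than being enforced.

Determinism: a single cohort seed derives per-subject streams through an
integer congruential map, so cohorts are bit-reproducible and
per-subject components can be regenerated independently.

### What the generator does not emulate

Gaussian, temporally white signals with stationary correlation: there is
no BOLD autocorrelation, no physiological noise structure, no scanner
drift beyond what the cleaning removes, no lesions, and — importantly —
no between-subject variability in true connectivity. Subject-level FCS
varies only through estimation noise (SD about 0.04 at 235 frames),
whereas reported patient cohorts show between-subject SDs around 0.10.
Consequently group tests on synthetic cohorts at the default effect sizes
are much better powered than the emulated study, and the
power-consistency check instead simulates subject-level FCS directly at
the reported summary moments (mean 0.25 SD 0.11 vs 0.19 SD 0.10). Passing
tests demonstrate correctness of the computations and calibration of the
inference under the stated generative model, not performance on real
fMRI.

## Simulation sizes used by the checks

Chosen once for a single-CPU workflow; the properties they probe are
size-invariant:

* **Null calibration**: 500 cohorts of 20 regions (10 cortical, 2
  subcortical, 8 WM), 60 frames, 15 + 15 subjects; uncorrected rejection
  at p < 0.05 must sit within 0.05 ± 0.02, and each family must show zero
  FDR-significant regions in at least 92% of replicates (0.95 minus three
  binomial standard errors).
* **Effect recovery**: 10 cohorts of 24 regions, 120 frames, 300 + 300
  subjects, one WM region reduced by Δz = 0.06; the mean recovered group
  difference must lie within ±0.01.
* **Dose recovery**: n = 2000, target partial r = −0.46, estimate within
  ±0.04; plus a 400-replicate study at n = 37 checking that estimates
  bracket the target with spread on the `(1 − r²)/√n` scale.
* **Power consistency**: 500 replicates at the reported summary moments;
  detection rate within three Monte-Carlo standard errors of the
  noncentral-t power (≈ 0.84).
* **Demo determinism**: the full default configuration (164 regions,
  47 + 64 subjects, 240 frames) runs in a few seconds and reproduces
  every output file bit for bit under a fixed seed.

## Known limitations

* Upstream spatial processing (bias-field correction, segmentation,
  surface reconstruction, nonlinear template registration, slice timing)
  is out of scope: inputs are assumed already aligned, and the voxel
  renderer exists to exercise extraction, not to simulate acquisition.
* The pipeline computes no edgewise inference, no gray–gray statistics
  and no graph metrics beyond the two FCS definitions.
* FDR family sizes are conventions, not discoveries; when analyzing a
  subset of regions the user must decide whether the family is the subset
  or the full scheme (`fdr_m`).
* The `|z|`-averaging variant of FCS is deliberately not the default;
  signed averaging is the defined measure, and the two differ materially
  when anticorrelations are present.
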