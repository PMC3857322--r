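---
title: "Reliability-masked single-case analysis of task fMRI: methods"
author: "reliacase authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reliability-masked single-case analysis of task fMRI: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reliacase)
```

## The problem

Group-level fMRI contrasts are of limited diagnostic use for heterogeneous
developmental disorders: a condition such as developmental dyscalculia (DD)
may express itself in different brain regions in different children, so
group averages wash the signal out.  A single-case approach — comparing each
patient individually against a typically developing (TD) control sample —
can expose this heterogeneity, but it is only defensible at voxels whose
contrast estimates are reproducible across sessions.  `reliacase`
implements a complete pipeline built around that idea:

1. first-level block-design GLM betas per subject, task and session;
2. a voxelwise test-retest reliability map, and a mask restricting all
   later inference to reproducible voxels;
3. second-level one- and two-sample t maps with Monte-Carlo cluster-extent
   correction;
4. voxelwise Crawford tests for a deficit per patient, with
   frequency-of-deviation maps;
5. exhaustive power-set ROI classification with leave-one-out linear SVMs;
6. complete-linkage hierarchical clustering of subjects on Spearman
   correlations between activation patterns.

Because no clinical dataset ships with the package, a synthetic-data module
generates test-retest beta-map studies with known ground truth; every
stage is exercised and validated against that truth.

## First-level model

Each run is modelled as `Y = X b + e` per voxel, with regressors

* the task boxcar convolved with the canonical double-gamma HRF (peak 6 s,
  undershoot 16 s, undershoot ratio 6), scaled to unit peak so the task
  coefficient is in raw BOLD units ("activation minus baseline"; rest is
  the unmodelled baseline);
* six motion parameters (raw values, not derivatives; all-zero columns are
  dropped);
* discrete-cosine drift terms implementing a 2-cycles-per-run high-pass
  filter inside the model rather than as a pre-filtering step — the two
  formulations project out the same subspace, and keeping the drift in the
  design keeps the fit a single linear model;
* an intercept.

Serial correlation is handled by a single Cochrane-Orcutt pass: the AR(1)
coefficient is estimated from the pooled lag-1 autocorrelation of the OLS
residuals of all in-mask voxels (one scalar per run), rows of data and
design are prewhitened, and the model is refit.  Pooling stabilises the
estimate on short child runs (roughly 70 volumes for a self-paced
comparison run at TR 1.6 s); per-voxel estimation is available via
`rho_per_voxel = TRUE`.  Note that OLS residuals carry a small negative
autocorrelation bias of order p/T (about −0.14 with ~10 regressors and 70
volumes), so the pooled estimate is conservative; the estimator remains
unbiased for the betas themselves, which is what the downstream pipeline
consumes.  Session pairs are averaged voxelwise (`session_average()`)
before any second-level step, halving session noise variance.

## Reliability masking

For each task, `icc_2_1()` computes the Shrout–Fleiss two-way random
single-measure intraclass correlation from the two-way ANOVA decomposition

\[
\mathrm{ICC}(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + k(MS_C - MS_E)/n}
\]

across all `n = 32` children and `k = 2` sessions.  ICC(2,1) is implemented
as absolute agreement (the defined statistic; the name takes precedence
over looser verbal descriptions).  Negative estimates are kept as computed:
they simply fall below threshold.  The per-task maps are combined with
Fisher's z transform (equal task weights — same subjects, no reason to
weight), and the mask keeps voxels with combined ICC **strictly greater**
than 0.33.  The boundary choice follows the strict-inequality wording of
the rule; at a measure-zero boundary the choice cannot matter in practice.
Clipping at ±(1 − 10⁻⁷) before `atanh` guards the transform at ±1.

The default 0.33 threshold is a deliberately strict floor for child fMRI,
where reliabilities below 0.33 are the norm; 0.4–0.6 is conventionally
labelled "fair".  `tabulate_reliability_bins()` reports the distribution
over the conventional ranges (poor/fair/good/excellent), and
`dice_overlap()` gives the session-overlap view of reliability.

## Group maps and cluster-extent correction

Second-level maps are one-sample (each group against zero) or pooled
two-sample (DD − TD) t maps on session-averaged betas, two-sided at voxel
p < 0.01, computed only inside the reliability mask.  Multiplicity is
controlled at the cluster level: `monte_carlo_cluster_extent()` simulates
null fields (standard normal noise smoothed to the estimated residual
smoothness and renormalised inside the mask), thresholds them exactly as
the data, and returns the smallest extent `k*` whose null exceedance
probability is at most alpha = 0.05.  Defaults: 1000 iterations, seeded;
6-face connectivity (26 available) — the conservative choice where the
reference implementation is unspecified.

Smoothness is estimated from group residual maps (betas minus the group
mean) by the variance-of-first-differences estimator expressed in the
Gaussian-kernel convention, `FWHM = sqrt(2 ln 2) * voxel /
sqrt(var(diff) / (2 var))`.  On spatially independent fields this reads
about 1.18 voxel widths — the resolution floor of a sampled grid — which is
the desired behaviour: simulating the null at that kernel width slightly
over-smooths relative to truly independent voxels, making `k*` mildly
conservative, never anticonservative.  Positive and negative excursions are
clustered separately and the sign is carried into the cluster table.

## Single-case statistics

`crawford_t()` implements the test for a deficit,

\[ t = \frac{x - \bar{x}_c}{s_c\sqrt{(n+1)/n}}, \qquad df = n - 1, \]

the modified t that treats the control sample statistics as estimates
rather than population values; with 16 controls, `df = 15`.  (Published
behavioural tables sometimes refer such statistics to other df; the `df`
argument exists for that behavioural use, imaging analyses keep the
default.)  `single_case_maps()` applies the test voxelwise to a patient's
averaged betas against the 16 controls, splits significant voxels
(two-sided p < 0.01, direction by sign — one two-sided test, not two
one-sided ones) into over- and under-activation masks, and cluster-filters
each at the same `k*` calibration as the group maps, since the same
correction is applied to both analyses.  `frequency_map()` then counts, per
voxel and direction, the percentage of patients deviating — the pipeline's
picture of how (in)consistent patient deviations are.

## Classification

Features are voxelwise session-averaged betas inside ROI ∩ reliability
mask, in increasing linear voxel order (ROI means available via
`roi_mean = TRUE`); concatenated mode stacks the two tasks' vectors,
weighting tasks equally.  `loo_linear_svm()` uses a linear SVM at fixed
cost 1 — no kernel, no tuning — with features standardised by
*training-fold* statistics only, so no information from the left-out
subject leaks into the fold.  DD is the positive class; the identity
`CCR = (sens·n_DD + spec·n_TD)/(n_DD + n_TD)` holds exactly by
construction and is checked in the tests.

`powerset_search()` evaluates every nonempty ROI subset — the classic,
optimal, and expensive approach.  Per-ROI feature blocks are extracted
once; subsets are ordered by size then lexicographically; the winner is the
highest CCR with ties broken by smallest subset then name order, and all
ties are reported.  The default cap refuses more than 10 ROIs
(1,023 subsets) without `force = TRUE`: a 17-ROI search is 131,071 subsets
× 32 leave-one-out fits and runs for hours on one CPU.

## Clustering

Subjects are clustered on `d = 1 − ρ` with ρ the average-rank Spearman
correlation over all masked voxels: rank correlation is robust to outlying
betas and invariant to monotone transforms, and `1 − ρ` (rather than
`1 − |ρ|`) makes anticorrelated patterns maximally distant, which is the
meaningful geometry for activation profiles.  Complete linkage is the
strict agglomeration criterion — clusters exist only if *all* their members
are mutually similar.  The number of clusters is an explicit input; a
largest-merge-gap suggestion is reported but never applied silently.
Composition tables summarise per-cluster diagnosis, sex, age and IQ, with
Welch t tests between the two largest clusters.  Direct between-cluster
activation contrasts are refused by default: contrasting groups that were
homogenised by clustering the same data is circular, and the override flag
(`i_understand_circularity`) makes the decision auditable.

## The synthetic-data generator

Two entry points:

* `simulate_timeseries()` exists to test the GLM path: self-paced designs
  (comparison 4 blocks × 6 trials, calculation 6 blocks × 4 trials, 0.5 s
  inter-stimulus interval, 14 s baselines, TR 1.6 s; per-trial response
  times lognormal with medians ≈ 1.2 s and 4.1 s, `sdlog = 0.35`, so block
  durations and volume counts vary across subjects as self-paced designs
  make them), canonical-HRF signal, motion-coupled nuisance, and
  stationary AR(1) noise.
* `simulate_beta_dataset()` generates at the level the pipeline natively
  consumes: `beta(v, s, k) = μ_group(v) + b_s(v) + e_{sk}(v)` with
  `b ~ N(0, σ_b²)` and `e ~ N(0, σ_e²)`, so the planted voxelwise ICC(2,1)
  is `σ_b²/(σ_b² + σ_e²)` wherever the group offsets are constant within
  group.  Defaults `σ_b = σ_e = 1` put the planted ICC at 0.5, the "fair"
  level a careful child protocol attains.

Three kinds of structure can be planted: a group-constant DD−TD shift in
named ROIs (`effect_table`, in beta units) — the homogeneous effect that
two-sample maps and classifiers detect; per-patient heterogeneous
deviations (`heterogeneity = TRUE`: each DD child draws 1–3 affected ROIs,
shifted by `het_shift = 5` control standard deviations of the averaged
betas, i.e. units of `sqrt(σ_b² + σ_e²/2)`) — encoding the observation that
patient deviations overlap little; and group-specific distributed
activation profiles (`pattern_sd`), which create the
within-cluster-correlation ≫ between regime in which activation-pattern
clustering is informative.  The default grid is 30 × 36 × 30 voxels at
3 mm (the working resolution of resampled child EPI), with a
superellipsoid brain mask of ≈ 16.5k voxels and a synthetic 17-ROI atlas
carrying the frontoparietal labels conventional in this literature (THA,
vIPS, hIPS, aIPS, PCL, aPCL, aFOP, CINS, CING, vPMC with hemisphere
codes).  The atlas geometry is synthetic — disjoint spheres on a
deterministic interior lattice — and its names are labels, not anatomical
claims.

What the generator does *not* emulate: physiological noise, susceptibility
artefacts, realistic anatomy or spatial autocorrelation of the beta noise
(simulated betas are voxelwise independent, which the smoothness estimator
and the Monte-Carlo calibration handle as the white-noise limit), or
behavioural/psychometric structure beyond response-time medians.  Passing
tests therefore demonstrate the statistical machinery — calibration,
localisation, recovery — not performance on real child fMRI.

## Numerical choices and degenerate inputs

* Zero-variance voxels: second-level t is set to a sign-carrying capped
  value and QC-flagged; Crawford t with zero control sd raises an error;
  constant time series yield beta 0 plus a QC flag; constant subject
  feature vectors make the Spearman ρ undefined and raise an error naming
  the subject.
* ICC with zero total variance returns `NaN` with the voxel QC-flagged by
  exclusion from the mask.
* `k*` search: smallest extent whose exceedance proportion ≤ alpha; with
  `alpha × iterations < 5` a tail-instability warning is raised.
* Ties in complete linkage follow `stats::hclust`'s deterministic
  behaviour; power-set ties are all reported, with the smallest-then-
  lexicographic rule picking the headline winner.
* All randomness is seed-controlled; identical configuration and seed
  reproduce byte-identical datasets and results.

## Problem sizes used in tests and validation

The validation suite runs the study at its native size (16 + 16 subjects,
two tasks, two sessions, ≈ 15–16k reliability-masked voxels): planted-ICC
recovery at three levels over 1000-voxel fields; Crawford type-I
calibration over 10⁵ replicates; family-wise error of the cluster-extent
procedure over 200 null datasets on a 20³ grid with a 1000-iteration
calibration; a 255-subset power-set search over 8 ROIs; and
planted-partition recovery at k = 2.  The full 17-ROI power set is
enumerated by formula only (131,071 subsets) — evaluating it is an
explicitly flagged hours-scale run.  The ICC estimator is checked against
a brute-force two-way ANOVA oracle to 10⁻¹⁰ on 1000 random 32 × 2
matrices, and the connected-component labeller against a flood-fill
oracle.

## Known limitations

* The AR(1) correction is a single Cochrane-Orcutt pass with a pooled ρ;
  iterated or REML-based prewhitening would be marginally more efficient.
* The Monte-Carlo null assumes Gaussian fields at the estimated kernel
  smoothness; heavy-tailed residuals would make the extent threshold
  approximate (the two-sided voxel threshold itself uses the correct t
  reference).
* Session averaging assumes both sessions are on a common scale; no
  inter-session intensity normalisation is performed.
* The behavioural arm of the study (RT/accuracy group comparisons,
  psychometrics) is out of scope; only the Crawford machinery is shared
  with the imaging path.
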