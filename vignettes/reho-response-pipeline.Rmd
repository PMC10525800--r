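---
title: "Regional homogeneity mapping and treatment-response prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional homogeneity mapping and treatment-response prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, numerical choices and limitations behind
`rehopredict`, a pipeline for case-control regional homogeneity (ReHo)
studies of resting-state fMRI with a longitudinal treatment arm: voxelwise
Kendall's-W mapping, Gaussian-random-field (GRF) corrected group inference,
and support-vector-regression (SVR) prediction of clinical treatment
response.

## The measurement model

ReHo quantifies the local temporal synchrony of the BOLD signal.  For each
in-mask voxel we compute Kendall's coefficient of concordance over the
voxel's own time series and its 26 nearest neighbours (27 series in total;
19- and 7-voxel stencils are also available):

$$W = \frac{12 \sum_i (R_i - \bar R)^2}{K^2 (n^3 - n) - K \sum T_j},$$

where $R_i$ is the sum over the $K$ series of the within-series rank at time
$i$, $n$ the number of time points, and $\sum T_j$ an optional tie
correction.  $W = 1$ means perfect concordance and the null expectation is
exactly $1/K$.  By default the tie term is omitted — the classic form used
by the standard resting-state toolboxes — and midranks are always used for
tied values, so the two forms differ only in the denominator.  Both are
exposed because the uncorrected form is the reproducibility reference while
the corrected one is the statistically complete statistic; for continuous
BOLD data ties are absent and the two coincide.

Before mapping, each series is cleaned the standard way: the first 10
volumes are discarded, a least-squares linear trend is removed, and an ideal
(brick-wall, zero-phase) band-pass of 0.01–0.1 Hz is applied in the
frequency domain.  The ideal filter matches the behaviour of the classic
resting-state toolchains; it requires at least 32 volumes, and its pass band
must respect the Nyquist frequency $1/(2\,\mathrm{TR})$.  Raw W maps are
divided by their whole-brain (in-mask) mean — so every subject's map has
mean 1 — and then smoothed with a 4 mm FWHM Gaussian kernel, in that order
("smReHo").  Smoothing uses a mask-renormalized separable kernel: the map
and the mask are convolved with the same kernel and divided, so edge voxels
are not attenuated and out-of-mask zeros do not bleed in.  On the small
grids used for simulation this edge handling is material; it keeps the
in-mask mean within 1% of 1 after smoothing.

Two boundary policies are worth stating explicitly.  Mask-edge voxels are
computed over their available in-mask neighbours with the effective $K$
recorded in the returned object (rather than discarded), matching toolbox
behaviour; a voxel with no in-mask neighbour gets 0 with a warning.
Because the null mean of $W$ is $1/K_{\mathrm{eff}}$, mask-edge voxels run
slightly above $1/27$ under pure noise — on the default 24-cube fixture the
whole-mask null mean is about 0.042 against $1/27 \approx 0.037$, while
voxels with complete neighbourhoods sit at $1/27$ to Monte-Carlo precision.
Normalization is by the subject's own mask mean (not a template mask), the
natural choice when every image shares the same synthetic mask.

## Motion quality control

Head motion is consumed as 6-parameter realignment traces (translations in
mm, rotations in radians).  Subjects are excluded when any translation
exceeds 2 mm or any rotation exceeds 2 degrees; the thresholds are strict
("more than"), so boundary values are retained, and screening is applied to
the volumes that remain after initial-volume removal.  Framewise
displacement uses the Power convention — the sum of absolute backward
differences with rotations converted to arc length on a 50 mm sphere —
which is the dominant convention in the toolchain family this pipeline
mirrors; the Jenkinson alternative is not implemented, and the choice is
flagged here because published studies often leave it unstated.  Mean FD
enters the group model as a nuisance covariate.

## Group inference

Group differences are tested voxelwise with an ordinary-least-squares GLM:
intercept, group indicator, and nuisance covariates (age, sex, education,
mean FD).  The contrast estimates group 1 minus group 2, with
$t = c^\top\hat\beta / \sqrt{\hat\sigma^2\, c^\top (X^\top X)^{-1} c}$ and
$df = n - \mathrm{rank}(X)$.  Pre/post treatment change uses a one-sample t
on paired differences.  Voxels with zero residual variance (possible with
synthetic ties) are set to $t = 0$ with a warning rather than $\pm\infty$;
the zero-variance test uses a relative floor because exact ties leave only
round-off in the residuals.

Cluster-level correction follows the classic GRF cluster-extent result.
The t map is converted to z scores by tail-probability matching, each tail
is thresholded at half the voxel-level p (default 0.001, two-tailed), and
connected components are labelled with 26-connectivity (6/18 selectable).
Map smoothness is estimated from standardized GLM residuals via the
variance of spatial first differences: per axis,
$\hat\lambda = \mathrm{var}(\Delta r)/\mathrm{var}(r)$ and
$\mathrm{FWHM} = \sqrt{8\ln 2}\,\sqrt{1/(2\hat\lambda)}$ voxels, with the
resel count $V / \prod_a \mathrm{FWHM}_a$.  The corrected cluster p is

$$p = 1 - \exp\{-E[m]\,P(N \ge k)\},\qquad
  P(N \ge k) = \exp(-\beta k^{2/3}),$$

with $E[m]$ from the 3D Euler-characteristic density at the z threshold and
$\beta$ from the expected cluster size.  Positive and negative clusters are
reported separately, each tail at half the cluster alpha.  Peak effect
sizes use Cohen's d: $d = t\sqrt{1/n_1 + 1/n_2}$ for two-sample maps and
$d = t/\sqrt{n}$ for paired maps.  The paired conversion is kept explicit
and configurable because published tables sometimes use other paired
conversions (e.g. values consistent with neither $t/\sqrt{n}$ nor
$2t/\sqrt{df}$), and the package does not attempt to reconcile them.

Two properties of this machinery are checked empirically rather than
assumed.  First, calibration: over 200 null simulations (two groups of 20,
19-cube grid, Gaussian noise smoothed to 9 mm FWHM on 3 mm voxels) the
family-wise error at nominal cluster p 0.05 falls near 0.02–0.05.  The
9 mm choice is deliberate: GRF cluster theory assumes the field is smooth
relative to the lattice (about 3 voxels FWHM or more), and below that the
correction grows sharply conservative — at 2 voxels FWHM we observe
essentially zero false positives.  That regime is a documented limitation,
not a calibrated operating point.  Second, a permutation oracle: a
max-cluster-extent permutation test (group-label shuffling, or sign
flipping for paired designs, corrected p $=(1+\#\{M_{\mathrm{null}} \ge
k\})/(n_{\mathrm{perm}}+1)$) is provided as a distribution-free
cross-check, and on well-separated planted effects the two methods agree.

One phenomenon surfaced by the synthetic fixtures deserves a note: because
maps are normalized by the whole-brain mean, a strong focal increase in one
group depresses that group's normalized values everywhere else, which can
produce a genuine, broad opposite-signed cluster outside the planted region.
This is a real property of mean-normalized ReHo, not an artifact of the
implementation, and readers of group maps should keep it in mind.

Symptom correlations use Pearson when both variables pass a Shapiro-Wilk
normality check at 0.05 and Spearman otherwise, with Bonferroni control
(flag at $\alpha/n_{\mathrm{tests}}$).  A 2x2 chi-square utility (Pearson,
no continuity correction, with Cramer's V) covers group-matching tables.

## Predicting treatment response

The clinical target is the reduction rate
$RR = (\mathrm{score}_{\mathrm{baseline}} -
\mathrm{score}_{\mathrm{week4}})/\mathrm{score}_{\mathrm{baseline}}$ of the
HAMA and HAMD rating scales; negative values (worsening) are legal, and
subjects with a nonpositive baseline are rejected.  Features are the
per-cluster means of baseline smoothed-normalized ReHo within the
significant between-group clusters (voxelwise features are deliberately out
of scope).

Prediction uses epsilon-insensitive SVR with an RBF kernel (epsilon 0.1,
the libsvm default), 5-fold cross-validation, and a grid search over
$C, \gamma \in \{2^{-10},\dots,2^{10}\}$.  Folds are a seeded shuffle
followed by a contiguous split; no stratification.  Feature
standardization (on by default, since kernel methods are scale-sensitive)
always uses training-fold statistics applied to the held-out fold.  Two
grid-search modes are first-class:

* **paper** (default): one fixed fold assignment; every $(C,\gamma)$ pair is
  evaluated by its aggregated out-of-fold MSE and the best pair's
  out-of-fold predictions are reported.  This mirrors the common published
  procedure, but the selection sees all folds, so its performance estimate
  is optimistically biased under the null.
* **nested**: the grid search runs inside each training fold only, which is
  the statistically sound estimate for new data.

The test suite measures the paper-vs-nested gap on null data and reports it
rather than hiding it; with pure-noise targets the nested mean r stays
within 0.2 of zero.

Significance uses a label permutation: the targets are shuffled, the entire
procedure is re-run, and $p_r = \#\{r_{\mathrm{null}} \ge
r_{\mathrm{obs}}\}/N$ (analogously for MSE with smaller-is-better).  The
plain $k/N$ rule is the default for fidelity with common practice — note it
can yield exactly 0 for strong signals — and the add-one variant
$(k+1)/(N+1)$, which is never smaller and never exactly zero, is always
returned alongside.  The published Bonferroni threshold for this
correlation (0.05/36) is exposed as a configuration value, not derived,
because the divisor's provenance is not stated in the literature the
pipeline mirrors.

## The synthetic cohort

No patient scans ship with the package; every test runs on synthetic
cohorts with known ground truth.  The generator plants local temporal
coherence with a shared-latent-factor construction: within an ROI with
coherence $c$, each voxel's series is $\sqrt{1-c}\,\varepsilon_v +
\sqrt{c}\,\ell$ with a single latent series $\ell$ per ROI, so the pairwise
correlation of ROI voxels equals $c$ by construction and Kendall's W is
monotone in $c$ — an analytic handle that spatial smoothing would not give.
Group 2 uses $c + \delta$, planting a known group difference.  Motion
traces are bounded random walks (translations bounded by the amplitude in
mm, rotations by amplitude/50 rad), a deterministic low-amplitude linear
drift exercises the detrending stage, and clinical covariates come from
fixed ranges (age 18–60, education 6–19 years, HAMA 10–25, HAMD 7–21,
moderate baseline severity).  Treatment response is generated as a linear
model on the subject's ROI-mean normalized ReHo plus Gaussian noise; week-4
scores are rounded to integers and clipped at zero (rating scales are
integer-valued), and the exact pre-rounding reduction rate is stored in the
truth block so tests never fight rounding.  Note that normalized ReHo in a
strongly coherent ROI sits well above 1, so outcome coefficients should be
scaled to keep reduction rates inside a plausible range; the defaults do
this.

All randomness derives from one master seed through a fixed
linear-congruential expansion (`child_seed(seed, stage, index)`), so any
subject can be regenerated in isolation and identical configurations are
bit-reproducible.

The generator's defaults are a 24-cube grid with 120 volumes at TR 2 s
(240 volumes only in paper-scale runs), which keeps a full test cycle in
minutes while leaving every algorithmic property measurable.  What the
synthetic data deliberately omits: hemodynamic response structure,
physiological (cardiac/respiratory) noise, scanner drift fields,
susceptibility artifacts, spatial normalization error, and realistic
anatomical covariance.  Passing tests therefore demonstrate the
correctness and calibration of the algorithms under the stated noise
model, not the clinical replicability of any particular published effect.

## The pipeline

`run_end_to_end()` chains simulate (or ingest) → preprocess → ReHo → group
stats → predict.  Every stage writes plain artifacts (uncompressed NIfTI,
TSV, JSON) plus a manifest with parameter hashes and output content hashes;
a stage whose parameters and outputs are unchanged is skipped on re-run,
and two fresh runs with the same seed produce byte-identical artifacts.
Motion-excluded subjects are dropped before the design matrix is built and
never reach the feature tables or reports.  `validate_run_config()` returns
violations by key and never throws, and an invalid configuration aborts the
run before any computation.

## Known limitations

* GRF cluster correction is conservative below about 3 voxels of smoothness
  (see above); the permutation oracle is the fallback in that regime.
* The smoothness estimator carries a small positive bias at low smoothness
  (about +18% for white noise), inherited from the first-difference
  approximation to the field roughness.
* The paper-mode grid search is optimistically biased by construction; use
  nested mode for honest out-of-sample estimates.
* Anatomical labelling, TFCE, mixed-effects longitudinal models, scrubbing,
  nuisance-signal regression and BIDS ingestion are out of scope.
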