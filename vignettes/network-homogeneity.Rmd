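---
title: "Network homogeneity analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network homogeneity analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the science and the engineering decisions behind
`nhkit`: the network homogeneity (NH) model and its assumptions, what the
synthetic cohort does and does not emulate, every tunable parameter with its
default and rationale, and the numerical choices made where the design was
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The scientific problem

Melancholic depression is a putatively distinct subtype of major depressive
disorder (MDD), marked by pervasive anhedonia, nonreactive mood and
psychomotor disturbance. A question of clinical interest is whether the
default-mode network (DMN) — medial prefrontal cortex, posterior
cingulate/precuneus, angular gyri, lateral temporal cortex — shows
homogeneity alterations that are *specific* to the melancholic subtype, and
whether such alterations can discriminate melancholic from nonmelancholic
patients.

Network homogeneity operationalizes "how coherently a voxel participates in
its network": for voxel $v$ in mask $M$ ($m$ voxels),

$$\mathrm{NH}(v) = \frac{1}{m-1}\sum_{u \in M,\, u \neq v} r(x_v, x_u),$$

the mean Pearson correlation between $v$'s time series and every other
in-mask series. The package implements this in the $O(mT)$ standardized
matrix form (correlation matrix as a scaled cross-product of z-scored
series) and validates it in the test suite against the literal $O(m^2)$
pairwise loop to $10^{-10}$.

The full analysis chain is: temporal preprocessing → DMN mask (group ICA +
template match, or a supplied template) → per-subject NH maps → smoothing →
voxelwise ANCOVA and pairwise t contrasts with covariates → Gaussian random
field (GRF) cluster-extent correction → cluster-mean NH extraction →
clinical correlations with Benjamini–Hochberg (BH) adjustment → exhaustive
leave-one-out SVM over cluster-NH feature combinations.

## 2. The synthetic cohort: what it emulates

Real subject-level imaging data for this design are not publicly
distributable, so the package ships a generator whose defaults *are* the
study conditions the analysis is built for, with recoverable ground truth at
every stage.

**BOLD model.** Each network region follows a one-factor equicorrelated
model: in-region voxel $i$ has series
$\sqrt{\rho}\,\ell + \sqrt{1-\rho}\,\varepsilon_i$ with a shared latent
$\ell$ and i.i.d. Gaussian noise, so the population pairwise correlation
within the region is exactly $\rho$ and the population NH of a pure-region
mask equals $\rho$ — an analytic anchor used by the Monte-Carlo tests.
Out-of-region voxels are pure noise. Per subject, the region coupling is
drawn as $\rho_i \sim N(\rho_{\text{group}}, 0.06)$ truncated to
$[0.02, 0.9]$: between-subject heterogeneity is what gives group contrasts
finite effect sizes and the classifier a non-trivial problem (perfectly
homogeneous groups would classify at 100%).

**Group coupling defaults.** Six disjoint box regions (27–80 voxels, near
typical reported cluster extents) on a 24×28×22 grid of 3 mm voxels with an
MNI-style centered affine. The couplings plant the qualitative pattern the
pipeline must recover, with a deliberate left>right asymmetry in the
frontal effect mirroring the asymmetry such studies report:

| region | melancholic | nonmelancholic | control | planted contrast |
|---|---|---|---|---|
| left ITG | 0.16 | 0.36 | 0.36 | mel below both |
| right MTG | 0.22 | 0.25 | 0.48 | both patients below control |
| left SMFG | 0.46 | 0.18 | 0.30 | mel above both, strongest pair signal |
| right SMFG | 0.42 | 0.22 | 0.32 | mel above both, weaker than left |
| right PCC/precuneus | 0.42 | 0.42 | 0.30 | both patients above control |
| right angular | 0.40 | 0.40 | 0.27 | both patients above control |

These values are resting-state-plausible coupling levels chosen once so
that (i) every planted contrast is detectable at the study's sample sizes
under GRF correction, and (ii) single features do not saturate the
classifier, leaving the left-SMFG + left-ITG *pair* the best combination.

**Acquisition constants.** TR 2.5 s, 200 volumes (10 discarded), 3 mm
isotropic grid; group sizes 31/28/32.

**Motion.** Six rigid-body parameters as smooth sinusoidal drift (≤0.2 mm
translations, ≤0.002 rad rotations) plus Bernoulli single-frame spikes
(default probability 0.02 per frame, 0.5 mm): enough to make mean framewise
displacement (FD) a non-degenerate covariate without triggering exclusions.
Subjects flagged as high-motion receive 5 mm spikes at every frame, which
deterministically fails the 2 mm rule — used to reproduce the
scanned-versus-analyzed group-size pattern structurally.

**Clinical scales.** Per-group Gaussian draws matching the configured
means/SDs (age, education, illness duration, HRSD-17, BAI, SHAPS-C, five
TEPS scales; controls get no illness duration or TEPS, and scores are
truncated at zero). Sex is Bernoulli with the configured group proportions.

**NH–symptom coupling.** The generator targets r = −0.5 between right-MTG
NH and the TEPS total and contextual-anticipatory scores in the melancholic
group. Two design choices matter here and are deliberate:

1. *Exact in-sample calibration.* The score is built as an affine mix of the
   standardized realized NH and noise residualized against it, rescaled to
   the configured mean/SD, so the sample correlation equals the target
   exactly. A population-level calibration at n = 31 would make recovery a
   coin flip (raw power for r = 0.5 at n = 31 is ~83% even uncorrected);
   exact calibration turns the planted association into a controlled
   property whose recovery failure would indicate a pipeline defect rather
   than sampling luck.
2. *Coupling against the realized, preprocessed quantity.* The NH value used
   for calibration is the region-mean NH over the whole network mask,
   computed after the same discard/detrend/bandpass/nuisance chain the
   analysis applies (`coupling_preprocess` argument). Bandpassing to
   0.01–0.08 Hz keeps ~68 of 190 Fourier components and nuisance regression
   removes 26 more degrees of freedom, so correlations *recomputed* after
   preprocessing decorrelate noticeably from raw-series correlations;
   calibrating against the raw series would attenuate the planted r by
   ~10–25% through no fault of the analysis. The remaining attenuation
   (smoothing, cluster-vs-region mismatch) is small; the acceptance script
   reports the observed mean r across replicates.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: hemodynamic response convolution, 1/f and
physiological noise spectra, scanner drift fields, spatial autocorrelation
outside the coupled regions, EPI distortion, anatomical variability and
normalization error, non-Gaussian score distributions, and any true
motion–signal coupling (motion regressors are independent of the planted
signal, so nuisance regression can only cost degrees of freedom, never
rescue artifactual effects).

## 3. Preprocessing

Stage order is fixed: discard → motion-exclusion test → linear detrend →
bandpass → nuisance regression.

* **Discard** (default 10 volumes) drops frames from the run and the motion
  trace synchronously.
* **Exclusion rule**: strict `>` at 2 mm translation / 2° rotation,
  measured per axis as displacement from the first retained frame (the
  common batch-pipeline convention; frame-to-frame would be an FD-style
  criterion, which is kept separate). The decision names the offending axis
  and frame.
* **FD** is the Power-style sum of absolute frame-to-frame parameter
  changes, rotations converted to arc length on a 50 mm sphere; the first
  frame is 0. Mean FD is computed after discard and becomes a group-level
  covariate.
* **Detrend**: per-voxel least-squares line removal (idempotent;
  residuals orthogonal to the [1, t] basis).
* **Bandpass** (0.01–0.08 Hz): ideal hard-edged frequency-domain filter via
  the DFT, zero-phase by construction, DC removed. Hard edges match the
  behavior family of the batch resting-state toolboxes this mirrors; the
  ripple-free alternatives (FIR/Butterworth) introduce phase or edge
  trade-offs without changing any downstream statistic materially.
* **Nuisance regression**: OLS residuals against mean white-matter series,
  mean CSF series, and the Friston-24 motion expansion (6 parameters, their
  one-frame lag, and both sets squared) plus intercept. The global mean
  signal is *not* removed (global-signal preservation). Regressors are
  bandpassed identically to the data first, so regression cannot
  reintroduce removed frequencies. Collinear columns are dropped with a
  warning (the squared terms of smooth drifts often are). Tissue seeds are
  small boxes shipped with the generator; on grids too small to contain
  them they clamp to the grid and may be empty, in which case they are
  skipped.

## 4. DMN mask construction

Group spatial ICA follows the two-stage reduction convention: per-subject
PCA in time (default dimension `min(T-1, 2C+5)`), temporal concatenation,
group PCA to C components, whitening, symmetric fixed-point ICA, then
back-reconstruction of subject maps by dual regression (pseudo-inverse
based, rank-safe).

* **Component count C** defaults to 20 in the configuration surface but any
  small C works on synthetic data; tests use C = 2–4. The choice is
  acquisition-dependent and exposed.
* **Contrast function**: the default is the skewness contrast $g(x)=x^2$.
  Brain network spatial maps are sparse with positive skew, and on exactly
  such sources the symmetric contrasts (tanh, pow3) can converge to
  sign-symmetric mixtures — observed on the package's own known-source
  recovery test, where tanh plateaued at spatial correlation ≈ 0.6 with
  every source while the skew contrast exceeded 0.98. tanh and pow3 remain
  available. Initialization is deterministic from the seed; fixed-point
  tolerance 1e-6, at most 500 iterations; component sign is fixed so each
  map has positive skewness.
* **Template match**: components ranked by absolute spatial correlation with
  the template; all above 0.3 are selected, with an argmax fallback (plus
  warning) so at least one component is always returned.
* **Mask overlay**: per group, the mean back-reconstructed subject map is
  z-scored and thresholded at z > 1.0; the final mask is the union over
  selected components and groups. Union (not intersection) keeps every
  candidate network voxel for NH testing; the binarization threshold
  follows the common display convention. Mask construction is monotone in
  the threshold.

The pipeline can also take the network template directly as the mask
(`mask_method = "template"`), which is the configuration the recovery
studies use: mask construction is validated separately, and a fixed mask
makes replicate cohorts cheap because voxels outside it never reach any
downstream statistic (the generator then simulates region and tissue-seed
voxels only, `active = "regions"` — statistically identical downstream).

## 5. NH maps and smoothing

Zero-variance voxels get NH 0, are excluded from other voxels' means, and
are counted in a message. Smoothing uses a separable Gaussian kernel with
$\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ per axis (mm converted to
voxels), restricted to the mask with edge renormalization — the smoothed
map is the ratio of the smoothed masked values to the smoothed mask
indicator — so constants are preserved and nothing bleeds in from outside
the mask. FWHM 0 is the identity. Post-smoothing values may leave [−1, 1]
slightly near mask edges and are not clipped; the GLM does not require
boundedness.

## 6. Group inference and GRF correction

**Design.** Group indicators plus mean-centered covariates (age, education,
mean FD) and an intercept; education is included even though groups differ
on it, matching the analysis convention this mirrors. Collinear covariates
are pruned with a warning. The omnibus group effect is a partitioned F
(full vs covariates-only); pairwise contrasts refit on the two groups
involved and report the adjusted difference as a t (checked against the
closed-form pooled two-sample t in the no-covariate case, and F = t² in the
two-group case).

**Smoothness.** Residual maps are scaled per voxel to unit norm over the
stack (residuals are zero-mean by construction under a model with
intercept; per-voxel SD scaling with demeaning is badly biased for small
stacks). Along each axis the pooled variance $v$ of first differences
between in-mask neighbours is inverted under a Gaussian autocorrelation
model: $\rho(1) = 1 - v/2$,
$\mathrm{FWHM} = \sqrt{8\ln 2}\,\sqrt{-1/(4\ln\rho(1))}$ voxels, floored at
one voxel (white noise ⇒ independent voxels). RESELs = mask volume /
∏FWHM. The estimator is exact under a Gaussian ACF and recovers 6 mm
smoothness within a few percent in the test suite.

**Cluster correction.** t and F maps are Gaussianized by probit transform
of their p-values (log-scale for numerical stability), thresholded at the
one-sided z for voxel p (default 0.001), and connected components are
formed within the mask at 26-connectivity (6/18 available). Each cluster's
family-wise p combines the expected cluster count from the 3D
Euler-characteristic density,
$E[m] = R\,(4\ln 2)^{3/2}(2\pi)^{-2}(u^2-1)e^{-u^2/2}$, with the classic
exponential extent approximation $P(n \ge k) = e^{-\beta k^{2/3}}$,
$\beta = (\Gamma(5/2)/\bar n)^{2/3}$, $\bar n = E[N]/E[m]$:
$p_{\mathrm{corr}} = 1 - \exp(-E[m]\,P(n \ge k))$. Signed maps are
processed per tail, each thresholded one-sided at voxel p and corrected at
cluster p — the convention of the GRF lineage this package mirrors. On this
lattice the extent approximation runs conservative, and the package's own
Monte-Carlo calibration (500 smooth null fields at 6 mm FWHM, recomputed by
the acceptance script) shows the per-tail convention realizes a family-wise
rate near the nominal 0.05 where a Bonferroni split across tails would
halve it; `split_tails = TRUE` provides the strict variant. Lower-dimension
EC terms are omitted (negligible at these thresholds and mask sizes).
Anti-conservative behavior on unsmoothed maps is expected and documented:
GRF theory assumes smooth fields.

**Reporting.** Peaks map to mm through the affine (0-based voxel
convention); cluster locations take the modal ground-truth region label of
their member voxels when an atlas is attached; tables sort by extent.

## 7. Clinical statistics

`anova_from_summary`, `ttest_from_summary` and `chi_square_table`
reconstruct one-way ANOVA (+ Fisher LSD pairwise t on the pooled MSE),
pooled-variance two-sample t, and Pearson chi-square (no continuity
correction) from printed group means/SDs/sizes — the pooled (not Welch)
t is used because it is what the summary cells determine and what the
reference tables print. All are validated against `aov`, `t.test` and
`chisq.test` on raw data. `bh_adjust` implements the step-up
$\tilde p_{(i)} = \min_{j \ge i}(p_{(j)} m/j)$ with a floor at the raw p
(guarding a one-ulp rounding case) and is checked against `p.adjust` and an
exhaustive evaluation of the definition.

The BH family for the NH–symptom correlations is, per score, the set of
clusters abnormal in that group's versus-control comparison — the family
size that reproduces the worked adjusted values (0.005→0.045, 0.004→0.036
at m = 9). Missing scores (controls' TEPS) are dropped listwise per
variable, and per-variable n is always reported rather than assumed.

## 8. Classification

Leave-one-out cross-validation with an RBF SVM (cost 1, γ = 1/#features —
the wrapped library's long-standing defaults; linear kernel available).
Feature z-scoring is fit on each training fold only and applied to the
held-out subject, avoiding test-set leakage; the melancholic group is the
positive class. `enumerate_combinations` evaluates every nonempty feature
subset up to `max_size` (default 2, giving the six combinations of three
cluster features); the best is the accuracy argmax with ties broken toward
fewer features, then lexicographic feature id. No hyperparameter tuning is
performed (none is reported in the design this follows). A caveat stated
rather than hidden: LOOCV accuracy under label permutation sits slightly
*below* 50% at small n (the training majority anti-correlates with the
held-out label); the chance-band check therefore uses n = 60.

## 9. Problem sizes and runtime choices

The test suite and acceptance script choose problem sizes as a deliberate
trade-off between statistical resolution and a desk-scale run: Monte-Carlo
coupling checks use 200 replicate draws; the GRF calibration uses 500 null
fields on the full 24×28×22 grid with smoothness estimated once from a
30-field stack (the null process is stationary, so one estimate serves all
replicates); planted-effect recovery uses 20 replicate full-size cohorts
(91 subjects each) through the template-mask pipeline; ICA recovery tests
run on reduced grids. The complete suite runs in about two minutes on one
CPU; the acceptance script in about the same.

## 10. Known limitations

* GRF cluster p-values rely on continuum approximations; at smoothness
  below ~2 voxels FWHM, or with very small masks, they are approximate
  (here: conservative), and permutation inference — out of scope — would be
  the rigorous alternative.
* The equicorrelated one-factor BOLD model has no spatial autocorrelation
  within regions beyond the shared latent and none outside regions; the
  smoothness entering GRF correction on synthetic NH maps comes mostly from
  the 4 mm smoothing step.
* The exact-calibration coupling makes the planted correlation a controlled
  property, not a draw from the sampling distribution; recovery rates
  across replicates therefore isolate pipeline attenuation, and real-data
  power at n = 31 would be substantially lower.
* Group ICA here is a compact two-stage reduction + fixed-point unmixing;
  it does not reproduce any specific toolbox's numerical output, stability
  resampling, or dual-regression variants.
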