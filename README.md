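# nhkit

Network homogeneity (NH) analysis of resting-state fMRI for three-group
clinical designs — melancholic depression, nonmelancholic depression, and
healthy controls — from preprocessed BOLD series through default-mode-network
(DMN) mask construction, voxelwise group inference with Gaussian random field
(GRF) cluster correction, symptom correlations, and support-vector-machine
classification. A synthetic-cohort generator with known ground truth makes
every stage testable without access to patient data.

## The statistic

For a voxel *v* inside a network mask *M* with *m* voxels, network
homogeneity is the mean Pearson correlation between its time series and every
other in-mask series:

    NH(v) = 1/(m-1) * sum_{u in M, u != v} r(x_v, x_u)

Per subject, NH maps are computed on temporally preprocessed data (initial
volume discard, linear detrend, 0.01–0.08 Hz zero-phase bandpass, white
matter + CSF + Friston-24 nuisance regression with the global signal
preserved), smoothed with a 4 mm FWHM mask-restricted Gaussian kernel, and
entered into a voxelwise ANCOVA across groups — and pairwise post-hoc t
contrasts — adjusting for age, education and mean framewise displacement
(FD). Statistic maps are thresholded at voxel p < 0.001 and clusters are
retained at GRF-corrected cluster p < 0.05. Cluster-mean NH values feed
Pearson correlations with clinical scales (Benjamini–Hochberg adjusted) and a
leave-one-out SVM over all small feature combinations.

## Worked example

The default `cohort_spec()` encodes the study conditions the package is
built around: 31 melancholic, 28 nonmelancholic and 32 control subjects, TR
2.5 s, 200 volumes, six coupled DMN regions with group-specific within-region
coupling, and clinical scales whose group distributions match a
first-episode, drug-naive depression sample. One call runs the whole
analysis:

```r
library(nhkit)
res <- run_pipeline(pipeline_config(seed = 1))
res
#> <nh_pipeline>
#>   retained subjects: control=32, melancholic=31, nonmelancholic=28
#>   excluded for motion: 0
#>   melancholic_vs_control: 4 cluster(s)
#>   nonmelancholic_vs_control: 2 cluster(s)
#>   melancholic_vs_nonmelancholic: 3 cluster(s)
#>   best combination: left_itg+left_smfg (96.61% accuracy)
```

The melancholic-vs-nonmelancholic contrast recovers the planted effect
pattern — NH increased in bilateral superior medial frontal gyrus (SMFG),
decreased in left inferior temporal gyrus (ITG):

```r
res$contrasts$melancholic_vs_nonmelancholic$report
#> # A tibble: 3 × 8
#>   location       x     y     z n_voxels peak_stat sign     p_corrected
#> 1 left_itg   -16.5 -16.5 -16.5       80     -8.82 negative 0.000000975
#> 2 left_smfg  -10.5  25.5   4.5       44      5.56 positive 0.0000449
#> 3 right_smfg   1.5  22.5  -1.5       42      5.60 positive 0.0000570
```

`n_voxels` is the cluster extent, `peak_stat` the signed t value at the
cluster peak, and `x, y, z` the peak position in mm under the cohort's
MNI-style affine. In the melancholic group, NH extracted from the right
middle temporal gyrus cluster is negatively correlated with the
pleasure-experience (TEPS) scores, as planted by the generator
(target r = -0.5):

```r
res$correlations$melancholic
#>   cluster score                            n      r   p_raw    p_bh
#> 1 c2      teps_total                      31 -0.502 0.00403 0.0161
#> 2 c2      teps_contextual_anticipatory    31 -0.503 0.00389 0.00778
```

`autoplot(res$classification)` draws the Fig.-style accuracy bar chart of
all feature combinations; `tidy()` and `glance()` methods return tibbles for
every fitted object.

Summary-statistic helpers reproduce group-comparison tables directly from
printed cells:

```r
anova_from_summary(tibble::tibble(
  group = c("melancholic", "nonmelancholic", "control"),
  mean = c(28.65, 32.04, 29.59), sd = c(5.30, 8.18, 5.00),
  n = c(31, 28, 32)))$statistic
#> [1] 2.291666
```

## Scope

The package starts from motion-corrected, spatially normalized BOLD series
(simulated directly in a common space); slice-timing correction, realignment
estimation and nonlinear spatial normalization are out of scope, as is
hemodynamic-response modeling in the generator. See
`vignettes/network-homogeneity.Rmd` for the model, parameter and calibration
details.
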