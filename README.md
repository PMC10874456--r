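# fibrofractal

Observer-independent quantification of tissue fibrosis from
Masson-trichrome-stained histological sections, for researchers
validating structural readouts of intestinal (or other organ) fibrosis
against pathologist grading.

Semiquantitative fibrosis scores are observer-dependent, and plain
matrix-quantity measures (collagen proportionate area) are confounded by
features such as smooth-muscle hyperplasia. During fibrotic remodeling
the extracellular matrix (ECM) network also becomes structurally more
complex, and that structure can be measured. `fibrofractal` implements
the full measurement chain and the statistics used to validate it:

* **Binarization chain** — cyan-channel extraction (aniline blue stains
  the ECM), rolling-ball background subtraction (radius 20 px), contrast
  normalization (0.1 % saturation), unsharp mask (sigma 2, weight 0.6),
  median filter (radius 1), Tsai's moment-preserving threshold,
  despeckle; yields the binary ECM pattern.
* **Box-counting fractal dimension** — `D` is the OLS slope of
  `ln N(eps)` vs `ln(1/eps)`, where `N(eps)` counts occupied `eps x eps`
  boxes; averaged over 12 lattice origins, with a dyadic size series
  capped at 45 % of the image side. `D = 1` for a line, `2` for a filled
  square; ECM networks land in between, higher with complexity.
* **Sliding-box lacunarity** — `lambda = mean_eps (sigma/mu)^2` of the
  foreground mass over sliding windows: the gappiness of the pattern.
* **ECM fraction** — blue-stained area over total tissue area by HSV
  colour thresholding (matrix quantity, independent of the chain above).
* **Cohort statistics** — Spearman correlations against fibrosis grade,
  grade-wise comparisons routed by Shapiro-Wilk normality (ANOVA + Tukey
  or Kruskal-Wallis + Dunn/Bonferroni), margin-vs-focus comparisons with
  per-patient `delta = focus - margin` discrimination, and qPCR
  relative expression `2^-(CT_target - CT_reference)` with the
  COL1A1/COL3A1 ratio.
* **Synthetic data** — analytic fractal fixtures, von-Mises-oriented
  fiber networks with ground-truth masks, trichrome-like renders, and
  simulated paired margin/focus cohorts with configurable per-grade
  effect structure.

## Worked example

```r
library(fibrofractal)

# a synthetic fiber network rendered as a trichrome-like image,
# measured by the full pipeline
fib <- fiber_network(256, target_fraction = 0.3, seed = 7)
img <- render_trichrome(fib)
analyze_image(img, analysis_config(downsample_factor = 1))
#>   ecm_fraction fractal_dimension lacunarity fd_r2_mean degenerate
#> 1       0.3013             1.677     0.7245      0.998      FALSE
```

The ECM fraction recovers the constructed density (0.30); the binarized
pattern has dimension 1.68 — between a line and a plane, as expected for
a partial fiber covering — and lacunarity 0.72. Direct pattern analysis
shows the underlying detail:

```r
analyze_pattern(fib)
#> Fractal analysis of binary pattern
#>   fractal dimension D: 1.677 (mean of 12 grids, r2 0.998)
#>   lacunarity lambda:   0.7091 (mean over 6 box sizes)
#>   box sizes: 2, 4, 8, 16, 32, 64
```

On a simulated 28-patient margin/focus cohort the validation statistics
reproduce the expected effect structure — fractal dimension correlates
positively with fibrosis grade and discriminates the fibrotic focus from
the resection margin in every patient:

```r
tb <- simulate_cohort(n_patients = 28, seed = 1)
rep <- stats_report(tb)
rep$correlations$fibrosis_score_vs_fractal_dimension$rho
#> [1] 0.7074045
loc <- rep$location_comparisons$fractal_dimension
c(margin = loc$mean_margin, focus = loc$mean_focus)
#>   margin    focus
#> 1.694291 1.777834
loc$discriminates
#> [1] TRUE
```

## Analysis workflow

The `analysis/` scripts run the complete validation study over synthetic
data and write their tables under `results/`:

1. `01_fractal_validation.R` — estimator anchors: filled square, line,
   Sierpinski carpet (D within 0.05 of 2, 1 and ln8/ln3), exact carpet
   box counts, closed-form lacunarity cases.
2. `02_segmentation_validation.R` — binarization round-trip (Jaccard
   0.94 against ground-truth masks) and ECM-fraction recovery across
   densities 0.1-0.9.
3. `03_density_alignment_sweep.R` — fractal dimension rises
   monotonically with fiber density (the structural premise) and stays
   within [0, 2] across alignment concentrations.
4. `04_cohort_analysis.R` — cohort statistics on the simulated default
   cohort plus 200-seed parameter recovery.

```sh
Rscript analysis/01_fractal_validation.R   # and so on
```

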