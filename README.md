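# ccshape — two-group landmark-based statistical shape analysis

`ccshape` implements a complete two-group geometric-morphometrics pipeline
for 2-D landmark data, built around the comparison of the mid-sagittal
corpus callosum outline (16 landmarks per subject) between a patient and a
control group. It is aimed at researchers who have digitized homologous
landmarks on two cohorts (e.g. with tpsDig) and want the standard
shape-statistics battery with a reproducible, scriptable interface.

## What it computes

Given two samples of $k \times 2$ landmark configurations:

- **Superimposition** — generalized Procrustes analysis (GPA) in the
  complex representation: translation, scale (centroid size
  $\mathrm{CS} = \sqrt{\sum_j \lVert x_j-\bar x\rVert^2}$) and rotation
  removed; pooled across groups so coordinates are commensurate.
- **Shape-space geometry** — Kendall's Riemann distance
  $\rho = \arccos\lvert\langle z_1,z_2\rangle\rvert$, per-group and pooled
  RMS-$\rho$ dispersion summaries, tangent-space projection at the pooled
  mean with principal-component reduction to the $2k-4$ informative
  dimensions.
- **Mean-shape testing with a homogeneity gate** — Box-M (Box's 1949 F
  approximation) tests equality of group covariances; if it rejects, the
  unequal-covariance James statistic
  $T^2 = d'(S_1/n_1+S_2/n_2)^{-1}d$ with a seeded within-group bootstrap
  null; otherwise classical Hotelling $T^2$.
- **Deformation mapping** — thin-plate spline ($U(r)=r^2\ln r$) between
  the group mean shapes, bending energy, and an analytic-Jacobian
  expansion-factor grid (local area ratio, the classic transformation-grid
  figure); per-landmark dissimilarity and contribution ranking.
- **Allometry** — multivariate regression of reduced tangent scores on
  centroid size with Wilks' $\Lambda$, exact F, $R^2$ and MSE, plus shape
  prediction at arbitrary size.
- **Synthetic data** — a seeded generator (`shape_population_spec()`,
  `simulate_sample()`) reproducing the assumed data structure (Gaussian
  shape variation calibrated to RMS-$\rho \approx 0.08$, localized
  mean-shape offsets, covariance inhomogeneity, lognormal sizes,
  allometric coupling), so the whole pipeline is testable end to end
  without clinical data.

File formats: the tpsDig `TPS` text dialect (`LM=`, coordinate lines,
`IMAGE=`/`ID=`/`SCALE=`) and long-format CSV
(`specimen_id,landmark_index,x,y`).

## Worked example

Simulate two groups of 41 specimens with a localized mean-shape offset at
landmarks 5, 1, 3 (magnitudes 3:2:1 coordinate-sigmas) and mildly
inhomogeneous covariances, then run the full analysis:

```r
library(ccshape)
spec <- shape_population_spec(seed = 42,
                              group_delta = landmark_delta(c(5, 1, 3),
                                                           c(3, 2, 1) * 0.0151),
                              covariance_scale = 1.5)
a <- simulate_sample(spec, 1)
b <- simulate_sample(spec, 2)
report <- run_two_group_analysis(a, b, analysis_config(seed = 42))
print(report)
```

```
Two-group shape analysis: group1 (n = 41 ) vs group2 (n = 41 ), k = 16
Box-M test: M = 742.2466, F = 1.1394 (df = 406.0, 19383.2), p = 0.02861
Mean-shape test (james_resampling): T2 = 364.0577, p = 0.001
RMS rho vs pooled mean: group1 0.088399 | group2 0.123079 | pooled 0.107152
Allometric regression (CS): Wilks' lambda = 0.6668, F = 0.9460 (df = 28, 53), p = 0.5527
  R^2 = 0.01256, MSE = 0.0003977
Top-ranked dissimilarity landmarks: 5, 3, 1, 12, 9
```

Reading this: Box-M rejects covariance homogeneity (p = 0.029), so the
gate selected the resampling James test, which rejects equal mean shapes
(T² = 364.1, bootstrap p = 0.001 with 999 resamples). The dissimilarity
ranking recovers the three landmarks where the offset was injected as the
top three:

```r
head(report$dissimilarity, 3)
#>  rank landmark_index dissimilarity contribution
#>     1              5     0.0522156     0.303527
#>     2              3     0.0234079     0.136069
#>     3              1     0.0231198     0.134395
```

Group 2's larger RMS-rho (0.123 vs 0.088) reflects its inflated covariance.
The allometry block is null here because the generator used no size–shape
coupling (p = 0.55). `write_report(report, "report.json")` serializes
everything (test statistics, dissimilarity table, TPS warp and expansion
grid, per-landmark 95% ellipses and hulls, provenance) as stable JSON;
`format = "text"` renders a human-readable summary.

A demographics check from published summary statistics:

```r
t_test_from_summary(41, 34.17, 10.14, 41, 35.10, 9.92)
#> $t [1] -0.4196836   $df [1] 80   $p [1] 0.6757636
```

## Command line

```sh
Rscript inst/cli/ssa.R simulate --n 41 --sigma 0.0151 --delta-landmarks 5,1,3 \
    --delta-scale 0.045 --cov-scale 1.5 --seed 42 --out-a a.tps --out-b b.tps
Rscript inst/cli/ssa.R run --group-a a.tps --group-b b.tps --seed 42 \
    --resamples 999 --grid 24 --direction b_to_a --out report.json
Rscript inst/cli/ssa.R ttest-summary --n1 41 --mean1 34.17 --sd1 10.14 \
    --n2 41 --mean2 35.10 --sd2 9.92
```

## Further reading

`vignettes/shape-analysis-methods.Rmd` documents the statistical model,
every tunable parameter with units and defaults, what the synthetic
generator does and does not emulate, numerical choices, and known
limitations.
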