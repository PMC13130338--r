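---
title: "Two-group landmark shape analysis: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-group landmark shape analysis: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccshape)
```

## The problem

`ccshape` compares the *shape* of an anatomical structure between two groups
of subjects, using labeled 2-D landmarks digitized on each specimen — the
motivating application being the mid-sagittal outline of the corpus callosum
(16 landmarks per subject, two clinical groups of 41). "Shape" is what
remains of a landmark configuration after position, orientation and size are
discarded. The pipeline answers four questions:

1. Do the two groups differ in mean shape, and with what confidence?
2. *Where* on the structure is the difference concentrated (per-landmark
   ranking, thin-plate-spline deformation grid)?
3. How dispersed is each group about its mean shape (RMS Riemann distance)?
4. Does shape depend on size (allometry), and how strongly?

## Shape space and superimposition

A configuration is a $k \times 2$ matrix, handled internally as a complex
$k$-vector $z$ ($z_j = x_j + i y_j$), because a rotation by $\theta$ plus
rescaling by $b$ is multiplication by $b e^{i\theta}$. Centroid size is
$\mathrm{CS}(X) = \sqrt{\sum_j \lVert x_j - \bar x \rVert^2}$. Centering and
dividing by CS gives the *preshape*; the Riemann (Procrustes geodesic)
distance between two shapes is
$\rho = \arccos \lvert \langle z_1, z_2 \rangle \rvert \in [0, \pi/2]$.

Numerically, $\arccos$ near 1 cannot resolve distances below about
$1.5\times 10^{-8}$, so the package evaluates $\rho$ through the
rotation-aligned chordal norm, $\rho = 2 \arcsin( \lVert z_1 - z_2
\hat\beta \rVert / 2)$ with $\hat\beta$ the optimal unit rotation — the same
quantity, accurate to machine precision. This matters because the
generalized Procrustes iteration (`gpa()`) is declared converged when
successive means are closer than `tol = 1e-10`, below the arccos floor.

`gpa()` performs the standard full-Procrustes iteration: preshapes are
aligned to a provisional mean with the closed-form complex similarity
(`opa_align()`, rotations restricted to determinant $+1$ — a mid-sagittal
structure has a fixed orientation, and allowing reflection would silently
collapse flipped digitizations), the mean is the renormalized average of the
aligned configurations, and the loop stops when the mean moves less than
`tol`. Both study groups are superimposed **together** (pooled GPA), so
every downstream statistic sees commensurate coordinates.

## Tangent coordinates and dimension reduction

Statistics are computed in the tangent space at the pooled Procrustes mean
$\mu$: each aligned preshape is projected by $I - \mu\mu^*$. The package
uses the *full*-Procrustes residuals ($v_i = (I-\mu\mu^*)\, z_i \langle z_i,
\mu\rangle$), whose column means about the sample's own mean are exactly
zero; their norm is $\sin\rho\cos\rho$, indistinguishable from $\sin\rho$ at
the dispersions this analysis targets ($\rho \approx 0.04$–$0.09$).

Planar tangent coordinates occupy only $2k-4$ of $2k$ dimensions
(translation ×2, rotation, scale are gone), so covariance-based tests would
face singular matrices. `reduce_dimension()` projects both groups onto the
principal-component basis of the pooled, *group-mean-centered* data
(centering per group keeps a mean difference from inflating the basis), and
refuses to retain more dimensions than the smaller group can support
($d < \min n_i - 1$). For $k=16$, $n=41+41$, the retained dimension is 28.

## The two-sample tests and the homogeneity gate

Equality of group covariance matrices is tested with Box's M,
$M = (N-g)\ln\lvert S_p \rvert - \sum_i (n_i-1)\ln\lvert S_i\rvert$, using
Box's 1949 F approximation (the F form, not the chi-square form, because the
motivating study reports an F). The pipeline then applies the gate rule:
Box-M $p < \alpha$ (default 0.05) selects the unequal-covariance **James**
statistic $T^2 = d'(S_1/n_1 + S_2/n_2)^{-1} d$ with a resampling null;
otherwise the classical pooled-covariance **Hotelling** $T^2$ with its exact
F transform.

The James null is a *within-group centered bootstrap*: each group is
centered at its own mean (imposing the null while preserving each group's
covariance), specimens are resampled with replacement within group, and
$p = (1 + \#\{T^{2*} \ge T^2_{\mathrm{obs}}\})/(1 + B)$ (add-one form, so a
finite bootstrap never reports $p = 0$). A permutation scheme would be wrong
here: exchanging specimens across groups with unequal covariances breaks
exactly the null the test is designed for. Resample index streams are
attached to the two groups in a canonical, label-independent order, so
swapping the group arguments reproduces the p-value bit-for-bit.

## Deformation mapping and the dissimilarity ranking

The thin-plate spline between the two group means (default direction: group
B's mean warped onto group A's) uses the kernel $U(r) = r^2\ln r$; the
convention is fixed so bending energies ($\mathrm{tr}\, w'Kw$, zero exactly
for affine maps) are comparable across implementations. `expansion_grid()`
evaluates the *analytic* Jacobian determinant of the warp on a lattice —
the local area expansion factor of Fig.-4-style transformation grids — with
$\mathrm{d}U/\mathrm{d}r$ derived in closed form and verified against
finite differences in the tests; `log2` expansion is also reported for
symmetric color scales.

"Dissimilarity" of landmark $j$ is defined here as the Euclidean distance
between the two Procrustes-aligned group means at $j$ (unit-CS frame;
ranking is scale-invariant either way), with contribution = dissimilarity /
total, ties broken by ascending index. A per-specimen averaged variant
(mean distance of each group's specimens to the other group's mean
landmark) is reported alongside when the aligned arrays are supplied. If
the means coincide, contributions degenerate to the uniform $1/k$ and the
table carries an explicit zero-difference flag rather than NaNs.

## Allometry

`allometric_regression()` fits the multivariate linear model
$V = \mathbf{1}\alpha' + s\beta' + E$ of reduced tangent scores on centroid
size (raw CS by default — log CS behind a flag, as morphometric practice
varies), pooled across groups. Significance uses Wilks'
$\Lambda = \lvert E'E \rvert / \lvert E'E + H \rvert$ with the exact
single-predictor F transform $F = \frac{1-\Lambda}{\Lambda}\,
\frac{n-d-1}{d}$; fit quality by $R^2 = 1 - \mathrm{tr}(E'E)/
\mathrm{tr}(T'T)$ and $\mathrm{MSE} = \mathrm{tr}(E'E)/(nd)$ (mean over all
residual cells — the most common convention; stated here because
conventions differ). The regression runs on reduced scores because the raw
tangent SSCP is identically singular. An exactly rank-deficient response
(e.g. noiseless synthetic data) makes $\lvert E'E + H\rvert = 0$; the
implementation returns the limiting $\Lambda = 0$ when the residual energy
is negligible and errors otherwise.

## The synthetic generator: what it emulates, and what it does not

No landmark data were published for the motivating study, so the package
ships a generative stand-in (`shape_population_spec()`,
`simulate_sample()`) that reproduces the *statistical structure* the
analysis assumes:

- **Template**: a deterministic 16-landmark C-shaped arch (8 upper, 8 lower
  contour points), unit CS, minimum landmark spacing 0.02 — qualitatively a
  corpus callosum outline, not an anatomical tracing.
- **Within-group variation**: i.i.d. Gaussian perturbations of each
  coordinate, scale `sigma`, applied in the template's unit-CS frame
  *before* the random similarity transform, so `sigma` lives in shape units
  and is calibratable: `calibrate_sigma(0.08, ...)` bisects to the sigma
  whose large-sample RMS Riemann dispersion matches 0.08, the order
  reported for mid-sagittal corpus callosum data. The default
  `sigma = 0.0151` is that calibrated value, frozen.
- **Group difference**: `landmark_delta()` builds a localized mean offset.
  Because a configuration-space offset is partly a similarity transform —
  which superimposition removes and smears over all landmarks — the
  constructor chooses the offset *directions* (deterministically, from the
  template geometry alone) to minimize the similarity-group component, and
  projects out the remainder. The result is a genuine mean-*shape* offset
  whose named landmarks dominate in the stated magnitude order; the small
  compensating displacements on the other landmarks are unavoidable
  (Procrustes shape differences cannot be exactly localized).
- **Covariance inhomogeneity**: `covariance_scale` multiplies group 2's
  sigma, reproducing the Box-M-rejecting regime.
- **Size and allometry**: centroid sizes are lognormal (default meanlog
  $\log 50$ mm, sdlog 0.07 — roughly a 50 mm structure with the ~7% size
  CV typical of adult neuroanatomy); `allometry_beta` couples centered log
  CS to a shape displacement. Raw outputs carry random rotation, the drawn
  size, and a uniform translation in $\pm 100$ mm, so file-level inputs
  exercise the full superimposition path.
- **Seeding**: groups 1 and 2 draw from disjoint substreams of one seed, so
  a single integer reproduces the entire experiment regardless of the
  order in which groups are generated.

What the generator does **not** model: digitization (rater) error as a
separate variance component, correlated anatomical variation along the
contour, non-Gaussian tails, or any image-level process. A green recovery
test therefore establishes that the pipeline detects and localizes the kind
of difference the analysis assumes — not that the clinical findings of any
particular study are correct.

## Numerical choices and degenerate inputs

- Riemann distances via the chordal form (see above); GPA `tol = 1e-10`,
  `max_iter = 100`, non-convergence warns and is flagged, never silent.
- All-coincident configurations: `centroid_size()` returns 0 with a
  degeneracy attribute; every downstream operation rejects CS = 0.
- TPS requires pairwise-distinct, non-collinear source landmarks and
  reports which pair/condition failed.
- Dissimilarity ties: descending dissimilarity, ascending landmark index.
- `t_test_from_summary()` is the classical pooled-variance two-sample
  t-test reconstructed from summary statistics, for demographic covariates
  reported only as mean ± SD.

## A worked run

```{r example, eval = FALSE}
spec_a <- shape_population_spec(seed = 42,
                                group_delta = landmark_delta(c(5, 1, 3),
                                                             c(3, 2, 1) * 0.0151))
sample_a <- simulate_sample(spec_a, 1)
sample_b <- simulate_sample(spec_a, 2)
report <- run_two_group_analysis(sample_a, sample_b,
                                 analysis_config(seed = 42))
print(report)
write_report(report, "report.json")
```

## Known limitations

- Two groups only; no covariate adjustment, no >2-group MANOVA, no
  semilandmarks or 3-D support.
- The Box-M gate is a hard threshold; borderline homogeneity flips the test
  choice discontinuously (mitigated by reporting both the gate p-value and
  the chosen method in the report).
- Box's F approximation is known to be slightly liberal when the retained
  dimension approaches the group size; the pipeline's precondition
  ($n_i > d+1$) prevents the worst regime but small-sample Box-M p-values
  should be read qualitatively.
- The per-landmark dissimilarity ranking is a descriptive ordering of mean
  differences, not a set of per-landmark hypothesis tests.
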