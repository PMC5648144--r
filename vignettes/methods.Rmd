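---
title: "Comparing climatic and edaphic predictor sets across niche-modeling algorithms: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question and the experiment

Plant distributions respond to soil as well as climate, but global
edaphic grids behave very differently from bioclimatic ones: soil
properties vary over short distances and with great spatial complexity,
while interpolated climate surfaces are smooth over hundreds of
kilometres. `nichefactor` implements a factorial experiment that makes
this contrast measurable. Two within-subject factors are crossed over a
set of species: the **Predictor** factor (climate-only `C`, edaphic-only
`E`, or combined `CE` variable sets, each reduced to principal-component
scores) and the **Algorithm** factor (binomial GAM, maximum entropy with
linear and quadratic features `MElq`, random forest `RF`, and an RBF
support vector machine `SVM`). Every species x predictor x algorithm
treatment is scored by spatially blocked 2-fold cross-validation (TSS,
TPR, AUC), and the geometry of its binary prediction is summarized by a
landscape shape index (SI). A repeated-measures ANOVA compares factor
levels across species, and whole-map Kendall correlations quantify how
much the predicted suitability surfaces actually agree.

The pipeline is driven entirely by a synthetic-world generator, so the
full analysis runs from a clean session with no downloads, and -- more
importantly -- against *known* ground truth: each virtual species has an
explicit suitability function, so directional claims ("edaphic niches
are invisible to climate-only predictors") become testable properties
rather than interpretations.

## The synthetic world

`gen_gaussian_field()` filters seeded white noise with an isotropic
Gaussian kernel by circular FFT convolution and standardizes the result
to mean 0, SD 1. The kernel scale (in cells) is the single knob that
separates the two families: the demo world uses a range of 40 cells
(24 degrees) for the 6 climate-like layers and 4 cells (2.4 degrees) for
the 8 edaphic-like layers. Circular convolution keeps the field
stationary to the edge; the alternative (zero-padded convolution) fades
toward the borders and would confound the checkerboard partition with
position. Within-family collinearity is produced by mixing a shared
latent field into each layer (`layer = sqrt(rho) shared +
sqrt(1-rho) independent`, restandardized), with `rho = 0.6` by default so
that a few leading components carry most of each family's variance, as
strongly intercorrelated bioclim and soil grids do. A configurable
fraction (2% by default) of edaphic cells is set invalid to emulate grid
cells that carry climate but no soil data; all statistics and sampling
respect the joint validity mask.

Virtual species have product-Gaussian niches:
`suitability(x) = prod_j exp(-(x_j - opt_j)^2 / (2 breadth_j^2))` on two
response layers drawn from the requested family. The product form keeps
suitability in [0, 1], equal to 1 exactly at the joint optimum and
monotonically decreasing away from it -- the unimodal smooth-niche
concept that underlies correlative niche modeling. Optima are drawn from
the 10-90% quantiles of the realized layer so the niche sits inside the
sampled environment; breadths (0.5-1.25 SD units) control range size.
Occurrence counts are log-uniform between 20 and 1227 records, the span
of cleaned record counts the design anticipates, and records carry
collection years uniform on 1979-2013 so the temporal cleaning stage has
work to do.

What the generator does *not* emulate: sampling bias along roads and
cities (a bias layer exists as a knob but is off by default), spatial
aggregation of records beyond what suitability induces, dispersal
limitation (species occupy all suitable cells), and any real covariance
structure between the climate and soil families. Passing tests therefore
demonstrate that the machinery recovers known structure under these
idealized conditions, not that any real flora behaves this way.

## Stage-by-stage choices

**Grids.** Rasters are square-celled, north-up lon/lat grids; cell
membership uses half-open intervals (left/top edge inclusive) so every
point belongs to exactly one cell. Mean aggregation averages valid cells
per block and keeps partial trailing blocks (averaged over the cells
present) rather than silently trimming the study area. Grids serialize
as ESRI ASCII (`.asc`) files -- a plain-text raster format whose header
carries the full geotransform and nodata sentinel -- and round-trip
exactly at 17 significant digits.

**Occurrence preparation.** Cleaning removes records outside the study
window, collapses exact duplicate coordinates, and applies the
1979-2013 window to dated records; undated records are kept unless the
strict flag is set, since specimen databases rarely date everything and
silently dropping them would bias record counts. Systematic thinning
overlays a grid of twice the model cell size (mirroring thinning a
5-arc-minute modeling grid at 10 arc-minutes) and keeps one record per
cell, uniformly at random under a seed; the operation is idempotent.
Geographic extent (GE) counts model-grid cell centers inside or on the
convex hull of the records (inclusive boundary); hulls of fewer than
three distinct or collinear records fall back to the count of occupied
cells, which also floors GE at 1 so the record density DR = NR/GE is
always defined.

**Predictors.** Each variable set is standardized per variable over the
jointly valid cells and eigendecomposed via its correlation matrix. The
correlation (not covariance) matrix is the only defensible choice when
temperatures, millimetres, percentages and cmolc/kg share a stack;
unscaled PCA would be unit-dominated. The PCA is fitted over all valid
cells of the study area, not just occurrence cells, since the same score
layers must serve every species. Retention is the minimal k whose
cumulative variance proportion *strictly exceeds* 0.95. Component signs
are arbitrary in any eigendecomposition, so each component's
largest-magnitude loading is made positive; without this, re-runs on
other BLAS builds could flip score layers.

**Spatial design.** Pseudo-absences are drawn at prevalence 1 (one per
presence) without replacement from the centers of valid, non-presence
cells of a soil mask layer. The 2-fold partition assigns each point the
parity of its checkerboard block; block size is chosen by sweeping 30
candidate resolutions (0.5 to 15 degrees in 0.5 steps), keeping the
feasible candidates (both folds hold presences) and minimizing the
presence imbalance between folds. Ties go to the *smallest* resolution:
finer blocks give more, smaller alternating regions and hence the more
conservative spatial separation. The checkerboard anchor is the study
window's top-left corner and is exposed as a parameter. Pseudo-absence
fold allocation is spatial-first -- each pseudo-absence keeps its own
block's parity -- and only the surplus needed to restore per-fold
prevalence 1 is re-sampled into the deficient fold's blocks; a pure
relabeling variant is available behind a switch for sensitivity checks.

**Algorithms.** GAM: one univariate thin-plate smooth per score layer,
binomial likelihood, smoothing parameters optimized by outer Newton
iteration; no interactions or term selection. The basis dimension is
capped at 10 per smooth and, jointly, so the model never carries more
coefficients than training points (`floor((n-1)/p) + 1` per smooth,
minimum 3, degrading to linear terms below that): small spatial folds
crossed with the wide CE score set would otherwise give absurdly
over-parameterized smooths. RF: classification forest, 500 trees, `mtry` swept from the
`floor(sqrt(p))` default by factor-2 steps and chosen by minimum
out-of-bag error, then refit. SVM: RBF kernel at fixed cost C = 1 with
Platt-sigmoid probabilities; the kernel width defaults to the inverse
median squared pairwise training distance and is recorded in the model
metadata. The maximum-entropy model is implemented natively: features
are each predictor and its square, affinely scaled to [0, 1] over the
background (new points clamped); the model is the Gibbs density
maximizing presence likelihood with per-feature L1 bounds
`beta_j = b(m) * sd_j / sqrt(m)`, where `b(m)` interpolates the
published linear+quadratic default schedule (0.22 at 10 presences down
to 0.10 at 100) on the presence count m. The convex objective is
minimized by monotone proximal-gradient descent with backtracking
(objective provably non-increasing; 1000-iteration cap, relative
tolerance 1e-8), and the fitted entropy H over the background drives the
logistic output `p = e^H q / (1 + e^H q)`, which equals 0.5 everywhere
for the null (all-weights-zero) model. Background is every jointly
valid cell up to a 10000-cell cap, beyond which a seeded uniform sample
is taken.

**Evaluation.** The binarization threshold maximizes sensitivity +
specificity over the unique predicted values *on the training fold*
(selecting on the test fold would leak), with the `>=` rule and
smallest-candidate tie-break pinned for reproducibility. AUC is the
rank-based (Mann-Whitney) estimator with midrank ties. SI is computed on
the full-extent binary map with rook (4-neighbour) patch connectivity by
default -- queen connectivity is a flag -- as
`sum(0.25 p_i / sqrt(a_i))` over patches; any square patch contributes
exactly 1. Fold metrics are arithmetic means of the two fold
assignments, making records invariant to fold order; the per-treatment
suitability map used for Kendall comparisons is the cell-wise mean of
the two fold predictions. Kendall tau-b is computed by an O(n log n)
merge-sort algorithm (in C++) because whole-map comparisons multiply
out to millions of cell pairs per species.

**Statistics.** The repeated-measures ANOVA treats species as subjects
and both factors as within-subject; sums of squares come from cell and
marginal means (Type I and Type III coincide on this complete balanced
design, which the tests assert), and each effect is tested against its
own subject-interaction stratum. Sphericity is checked per effect by
Mauchly's W on the covariance of orthonormal contrast scores (chi-square
approximation with the small-sample factor); when rejected at 5%, the
reported degrees of freedom are Greenhouse-Geisser shrunk with
`eps = (sum lambda)^2 / (q sum lambda^2)`. TSS enters the ANOVA as
`asin(TSS)`: TSS is signed, so the proportion-style `asin(sqrt(x))`
transform is undefined on half its range; that variant is available
behind a flag with negative clipping. The downstream mixed-effect
models, least-squares-means contrasts and FDR corrections that a full
report would add are deliberately not re-implemented -- the exported
long-format evaluation table is exactly what any established
mixed-model routine consumes.

## Numerical and degenerate-input policy

Seeded stages never disturb the caller's RNG (each derives a 31-bit
stream from the global seed and a stage key, so any single treatment is
reproducible in isolation, and serial re-runs are bit-identical).
Degenerate cases fail loudly rather than silently: single-class labels,
constant layers, empty crops, infeasible pseudo-absence or partition
problems, and zero-weight occurrence sampling all raise errors naming
the species or stage. Perfect separation in the GAM is the one
tolerated warning (the capped fit is returned), and treatment-level
failures inside `run_experiment()` become NA rows so one degenerate
species cannot sink a 288-treatment run; the run aborts only past 50%
failures.

## Problem sizes

The demo configuration (`experiment_config()` defaults) is a 150 x 150
world with 24 species -- 288 treatments, sized to complete in minutes on
one CPU. The direction-of-effect study (`edaphic_study_config()`) keeps
the same 90 x 90 degree window and physical autocorrelation ranges at a
coarser 1.5-degree cell (60 x 60), with 20 edaphic-niche species per
replicate and three replicate seeds; this is the configuration behind
the package's headline property that TSS(E) > TSS(C) and
SI(E) > SI(CE) > SI(C) for soil-driven species. Unit and property tests
use 20-60 cell grids so the full suite stays fast; the Monte-Carlo null
calibration of the ANOVA uses 500 simulated 15-subject tables.

## Known limitations

The generator's stationary, isotropic fields have no latitudinal
gradients, coastlines or elevation structure, so checkerboard
feasibility is easier than on real coastal ranges. Virtual species
respond to exactly two raw layers; real niches load diffusely on many
correlated variables, which flattens the C-versus-E contrast. SI
depends on the rook/queen convention and on resolution, so only
within-run orderings are meaningful. The maximum-entropy default
regularization schedule is a documented parameter, not a constant
imported from any particular implementation, and the entropy-based
logistic transform assumes the conventional 0.5 prevalence at typical
conditions. Finally, prevalence-1 pseudo-absence designs are known to
favour discriminative learners (RF, SVM) over the GAM, and that
asymmetry is visible in the demo results.
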