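---
title: "Seed shape morphometrics with average contours, the J-index and Bezier curvature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed shape morphometrics with average contours, the J-index and Bezier curvature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(seedmorph)
```

## The analysis in one paragraph

Grape seeds (and seeds generally) carry taxonomic and historical signal in
their lateral-view outline: wild-type seeds are short and round, cultivated
morphotypes are elongated with a pronounced basal beak, and related
cultivars share recognizably similar silhouettes. `seedmorph` quantifies
that signal. Seed silhouettes are reduced to closed contours; each contour
is described by eight classical measurements and by an elliptic Fourier
series truncated at 8 harmonics; normalized Fourier coefficients are
averaged into a per-population *average contour* (Ac) and pairs of Acs into
reference *shape models*; every population is then scored against each
model with the *J-index* — percent shared area after a registration that
maximizes overlap — and assigned to a morphotype group by threshold rules;
finally, the curvature signature of the lower seed profile (a Bezier fit)
and population-level statistics (Mann-Whitney comparisons, PCA on the
coefficient table) characterize the groups.

## Contours and measurements

Contours come from three sources: binary silhouette images (traced at the
0.5 isolevel with marching squares, so vertices sit at sub-pixel positions;
pixel-chain outlines would bias perimeter-dependent quantities like
circularity), TPS outline files, or the synthetic generator described
below. All contours are stored in mm, counterclockwise, y increasing
upward; image input is y-flipped once at extraction and nowhere else.
Components touching the image border are excluded: a partial seed has
meaningless shape.

The eight measurements follow the conventions of standard image-analysis
software: area $A$, perimeter $P$, length $L$ and width $W$ from the
best-fit (moment) ellipse, circularity $C = 4\pi A/P^2$, aspect ratio
$AR = L/W$, roundness $R = 4A/(\pi L^2)$, and solidity
$S = 1000\,A/A_{hull}$ on the conventional integer $\times 1000$ scale.
Two choices deserve a note:

* **Ellipse axes, not Feret lengths.** Whether $L$ and $W$ should be
  caliper (Feret) lengths or fitted-ellipse axes is genuinely open; the
  common image-analysis aspect-ratio and roundness definitions use the
  fitted ellipse, so that is the default here, with
  `measure(..., length_method = "feret")` available for sensitivity
  checks. For an exact ellipse the two agree.
* **Exact convex hull.** Solidity uses the hull of the polygon vertices,
  not a raster approximation, so it does not depend on image resolution.

## Elliptic Fourier descriptors

The Kuhl-Giardina transform treats the outline as periodic functions
$x(t), y(t)$ of cumulative chord length; harmonic $k$ contributes
coefficients $A_k, B_k$ (cosine/sine, x) and $C_k, D_k$ (y). Eight
harmonics reproduce smooth pyriform seed outlines to well below measurement
noise while keeping the coefficient space small ($8 \times 4 = 32$).

Normalization uses the standard first-harmonic procedure: start point
moved to the harmonic-1 major-axis crossing, shape rotated so that axis is
horizontal, translation dropped, size divided out (and kept in `size_mm`,
so mm-scale quantities such as curvature remain available). The
180-degree ambiguity of the major axis is resolved by requiring
non-negative x-skewness of the outline — in practice the beak always
points the same way. Reflection is *not* normalized away: seeds are
photographed in a consistent lateral view, so chirality is signal, not
nuisance.

One numerical subtlety is worth recording. Under chord-length
parameterization an ellipse is *not* a pure first-harmonic curve (its
constant-speed traversal has genuine higher harmonics). The transform
therefore accepts `parameterization = "uniform"`, which treats the input
vertices as equally spaced in the curve parameter and is exact on
analytically parameterized single-harmonic shapes; the two conventions
coincide on contours resampled to uniform arc length, which is the
package's standard preprocessing before any fit. The frozen morphotype
templates (below) are stored at the fixed point of
reconstruct → arc-length EFD → normalize, i.e. in (approximately)
constant-speed form, so reconstructing and re-fitting them is the
identity up to numerical tolerance.

Averaging is plain arithmetic: an Ac is the element-wise mean of its
members' normalized coefficients (exactly linear, so the Ac of two seeds
is their coefficient midpoint), and a model is the mean of two or more
Acs.

## The J-index

The J-index of a shape against a model is
$J = 100 \cdot \mathrm{area}(\mathrm{intersection}) /
\mathrm{area}(\mathrm{union})$ — an area Jaccard index — after a
superposition chosen to maximize overlap, replacing the manual
overlay-and-pixel-count procedure with an algorithmic one:

1. initialize by aligning centroids, equalizing areas, and scanning
   rotations on a grid (1 degree by default);
2. refine (dx, dy, rotation, log scale) with Nelder-Mead;
3. return the best pose evaluated anywhere — never worse than the
   initialization (a property asserted in the tests).

Scale *is* optimized by default, since a manual overlay implicitly
resizes the model; `fixed_scale = TRUE` gives the strict same-scale
comparison. Ties between equal-J rotations keep the smaller |rotation|.

Overlap areas are computed by a scanline strip integrator (compiled C++):
within each of `n_strips` horizontal strips the polygon cross-sections are
exact x-intervals, and intersection and union are integrated from the
*same* strips, so identical shapes score exactly 100 and disjoint shapes
exactly 0; analytic cases (half-overlapping unit squares, 33.33) agree to
well under 0.1 J points at the default 400 strips. This is deliberately
close in spirit to the pixel-count procedure used with overlay images,
while being resolution-controlled and deterministic. The population
J-index is the mean per-seed J, reported with its CV.

## Classification

Population aspect ratios split into a high class (boundary 1.575, i.e.
values printing as 1.58 and above) and a low class; within each class
cultivars are ranked by descending solidity, ties alphabetical. Groups are
assigned from the J-index of a population against the two reference
models: Group 1 if both values are below 90 (strict); Group 2 (or 3) if J
against the first (second) model exceeds 94 (strict); everything else is
Group 4, split into 4a/4b by which model scores higher. Values exactly at
a threshold fall toward Group 4, matching the strict wording of the rules.
The rules do not say what happens when *both* models exceed 94; the
package resolves that corner to the larger J (ties to Group 2) and
records the choice here. An exhaustive grid test asserts the partition.

## Curvature of the lower profile

The open sub-path along the lower side of a standard-oriented seed (from
leftmost to rightmost point) is fitted with a single least-squares Bezier
curve — degree 10 by default, chord-length parameterization, endpoints
interpolated. Signed curvature
$\kappa = (x'y'' - y'x'')/(x'^2+y'^2)^{3/2}$ is evaluated on a 601-point
grid over $t \in [0.2, 0.8]$; the extremes of the fitted curve are
excluded because endpoint behavior of a global polynomial fit is
unstable. Reported statistics are max, min, mean (all mm$^{-1}$;
a radius-1 mm circle has curvature 1, radius 0.1 mm curvature 10, a line
0) and the max/mean ratio. The mean is taken uniformly in $t$ (the
arc-length-weighted variant differs negligibly for these profiles and is
not exposed). Positive curvature is convex; negative values flag the
non-convex beak flanks, and deeper minima plus larger max/mean ratios are
exactly what distinguishes the straight-beaked, low-solidity morphotype
from the high-solidity one. The Bezier degree is a visible parameter and
is reported in outputs; degree 10 resolves one beak concavity per profile
without oscillation.

## Statistics

Group comparisons use two-sided Mann-Whitney U tests (seed-shape metrics
are not normal), exact when the smaller group has at most 8 observations
and no ties, normal approximation with continuity correction otherwise,
with a greedy compact-letter display at $\alpha = 0.05$ and no
multiple-testing correction. The test is a thin wrapper over
`stats::wilcox.test`; the test suite checks it against exhaustive
permutation enumeration for all sample sizes up to 7.

PCA runs on the centered, *unscaled* coefficient table (columns
`A1..A8, B1..B8, C1..C8, D1..D8`): after normalization all coefficients
share one dimensionless scale, and variance-scaling would inflate
small-amplitude harmonics; `scale. = TRUE` gives the correlation variant.
Confidence ellipses are 95% regions for the *group mean*
(chi-square quantile on the covariance of the mean), not data ellipses —
they shrink as $1/\sqrt{n}$ and need not contain any individual
observation.

## The synthetic generator

Because the real seed-image collection is an external download, the
package ships a generator whose templates stand in for the reference
morphotypes, with targets taken from the reference models' published
shape descriptors:

| template | target AR | target solidity | length (mm) | beak |
|---|---|---|---|---|
| `heben_like` | 1.62 | 975 | 6.5 | rounded |
| `chenin_like` | 1.68 | 955 | 6.8 | straighter, deeper flanks |
| `sylvestris_like` | 1.30 | 1000 | 5.5 | vestigial |

Each template began as a parametric pyriform outline (egg-shaped body plus
a Gaussian radial bump for the beak, deflected slightly off-axis so the
outline has the mild top-bottom asymmetry of real seeds); body parameters
were tuned once so the 8-harmonic reconstruction meets the AR/solidity
targets, and the resulting coefficients are frozen constants
(`scripts/tune_templates.R` regenerates them). The sylvestris template's
length (5.5 mm) and the noise defaults are the package's own choices of a
realistic regime, not published values: per-seed variation multiplies
every harmonic-2+ coefficient by $1 + 0.05\,z$ ($z \sim N(0,1)$) and the
size by $1 + 0.03\,z$, giving within-population CVs of the same order as
published per-cultivar tables. Draws whose reconstruction self-intersects
are redrawn (at most 100 times). Zero noise reproduces the template
exactly, which makes end-to-end pipeline identities testable.

What the generator does *not* emulate: segmentation artifacts, touching
seeds, lighting gradients, digitizing noise on the contour itself, and
between-image calibration error. Green tests on synthetic data therefore
validate the computational chain, not the imaging protocol.

## The pipeline and the problem sizes used

`run_pipeline()` executes the whole chain on synthetic data: two reference
populations per model morphotype are averaged into Acs and then into the
two models (mirroring how the reference models are built from two Acs
each); test populations of 25 seeds per morphotype are measured, scored,
classified and profiled; comparisons and PCA close the run. Defaults were
chosen so a full replicate is a desk-scale computation (about half a
minute): 25 seeds per population, 150-point contours, 150 strips, a
6-degree rotation grid with 80 refinement iterations. At these settings
the three morphotypes classify into Groups 2, 3 and 1 respectively, and
the low-solidity morphotype shows the deeper curvature minimum and larger
max/mean ratio, with Mann-Whitney separation far below $\alpha$. The
acceptance suite repeats that over 10 independently seeded replicates.

```{r pipeline, eval = FALSE}
res <- run_pipeline(pipeline_config(rng_seed = 1, out_dir = "run1"))
res$classification
res$comparisons
plot(res$pca)
```

## Known limitations

* Registration maximizes a smooth but non-concave objective; the rotation
  grid plus refinement can in principle stop at a local maximum. The
  returned pose is guaranteed no worse than the deterministic
  initialization, and identity/recovery cases are asserted in tests.
* The strip integrator is exact in x but discretized in y; J values carry
  an error on the order of 0.1 points at default resolution (zero for the
  identity and disjoint cases by construction).
* Group thresholds (90/94) and the AR boundary are calibrated constants
  of the reference analysis; applying them to seeds measured under a
  different imaging protocol requires re-checking the J scale first.
* The generator draws coefficients independently; real seeds have
  correlated harmonic variation, so synthetic within-population
  covariance is optimistic.
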