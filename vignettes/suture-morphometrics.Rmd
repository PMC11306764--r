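---
title: "Quantitative morphometrics of infant cranial sutures and fontanelles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative morphometrics of infant cranial sutures and fontanelles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suturemorph)
```

## The problem

In young infants the cranial bones are separated by membranous sutures
(metopic, sagittal, coronal, squamosal, lambdoid) and fontanelles (anterior,
posterior, sphenoidal, mastoid). Their geometry matters for skull growth,
for craniosynostosis diagnosis, and for finite-element models of infant head
biomechanics, yet it is rarely quantified beyond a few calliper measures.
`suturemorph` implements a complete measurement-and-modelling chain for this
anatomy, starting from traced 3D border curves (e.g. exported from 3D Slicer
after CT segmentation) and ending in a statistical shape model that predicts
suture morphology from a handful of global covariates.

The chain is:

1. **Semilandmarks.** The seven border polylines of a subject are uniformly
   resampled to a fixed topology of 800 semilandmarks
   (100/100/200/200/50/50/100 per border).
2. **Junction points.** Thirty-two junction points split the semilandmarks
   into nine named parts (five sutures, four fontanelles) using
   width-change criteria.
3. **Morphometrics.** Suture length, width and sinuosity index (SI), cranial
   length/width/circumference, and the total surface area of all sutures and
   fontanelles via thin-plate-spline (TPS) patches, triangulation and
   Heron's formula.
4. **Superimposition.** Three-point rigid registration, generalized
   Procrustes analysis (GPA) in form space (no scaling), and bending-energy
   sliding of the semilandmarks.
5. **Dimension reduction.** Column-standardized geometry, classic PCA,
   five kernel-PCA variants and a variational autoencoder, compared by
   10-fold cross-validation with the location mean deviation (LMD) metric.
6. **Statistical model.** Least-squares regression of component scores on
   morphometric covariates (pseudoinverse solution), leave-one-out
   cross-validation, per-covariate significance, and percentile
   morphologies.

All user-facing functions take tibbles and return tibbles, so stages chain
naturally; fitted objects have `tidy()`/`glance()` methods and `autoplot()`
views.

## Junction detection

The width between two borders is the Euclidean distance between
corresponding semilandmarks (midline sutures, where the two borders carry
the same count) or the nearest distance to the opposite border (all other
sutures). Scanning the paired width series of the frontal (or parietal)
borders from the suture's defined start, an index $i$ is a candidate
junction when

$$ w_{i+1} - w_i > k \quad\text{and}\quad w_{i+1} - w_i > 10\,k\,(w_i - w_{i-1}), $$

i.e. the width jumps by more than $k$ mm *and* the jump dominates the
previous increment. The last candidate is the junction; defaults are
$k = 0.15$ mm for the metopic-to-anterior-fontanelle junctions (JP3/JP4)
and $k = 0.18$ mm for the sagittal-to-posterior-fontanelle junctions
(JP7/JP8). The 24 lateral junctions (JP9-JP32) come from the discrete
second difference of each border's nearest-distance profile,

$$ (w_{i+1} - w_i) - (w_i - w_{i-1}) > m, \qquad m = 0.4, $$

where each run of consecutive qualifying indices contributes its last index.
Because a geometric corner that falls between two samples splits its slope
change across the adjacent ordinals, candidate runs are ranked by their
*summed* second difference when more candidates appear than the border's
topology admits (2/2/6/6/2/2/4 per border); the strongest are kept with a
warning. Both criteria are strategy-switchable (`eq1_form`, `eq2_form`)
because their printed algebra admits more than one reading; the defaults are
the readings documented above.

Two scan conventions are worth spelling out. First, the midline scans are
restricted to a leading fraction of the border (defaults 0.42 of borders 1/2
and 0.35 of borders 3/4): beyond the fontanelle these borders turn laterally
and their paired width no longer measures a suture. Second, the lateral
scans start a few ordinals (`guard`, default 3) after the midline junction
and stop the same margin before the border end, because at the border
extremes the nearest-distance profile reflects the adjacent bone's edge
endpoint rather than a suture. Both are properties of the border topology,
chosen before any tuning and exposed in `junction_config()`.

Indices are 1-based and ranges inclusive throughout, the native R
convention.

## Morphometrics

Suture length is the mean of the two bone edges' arc lengths (bilateral
sutures sum their left and right segments per edge). Width is the mean
paired distance for the midline sutures and the mean nearest distance
otherwise; a width of zero is valid and represents a fused suture. SI is
arc length over endpoint chord, computed per edge segment and averaged —
mirroring the per-edge length rule; SI is 1 exactly for a straight suture.
The "average SI" covariate is the unweighted mean over the five sutures.
Cranial length is the glabella-opisthocranion distance, width the
inter-eurion distance, and circumference the arc length of the closed axial
head contour; without a contour the circumference is reported missing,
never extrapolated.

## Surface areas

Because the suture system wraps around the head, five TPS patches are
fitted per subject: superior (height $z$ over the X-Y plane), left and
right lateral ($x$ over Y-Z) and anterior/posterior ($y$ over Z-X). The TPS
is the exact interpolant with kernel $U(r) = r^2 \log r$ (regularization 0
by default, configurable). Each part's footprint is meshed
boundary-conformingly: ruled strips between the two edges of a suture, and
ear-clipping plus longest-edge bisection for the fontanelle polygons (no
general Delaunay library is required, and the meshes tile the footprint
exactly, so patch areas sum). Every semilandmark feeds exactly one patch;
the metopic's leading 35% joins the anterior patch and the coronal/lambdoid
strips split 50/50 between superior/posterior and lateral patches
(configurable via `patch_plan()`). Mesh vertices are lifted through the
TPS at a target mean edge length of 0.3 mm and the area is the Heron sum
$\sum \sqrt{s(s-a)(s-b)(s-c)}$ over triangles, with degenerate triangles
excluded and counted. On analytic test surfaces (planar rhombus, spherical
cap) the result is within a fraction of a percent of the closed form.

## Superimposition

Rigid registration uses the Kabsch/Horn solution on the
rhinion/frontomalare-orbitale triplet (proper rotation enforced; a
reflection-optimal case falls back with a warning). GPA runs in form space:
translations and rotations are removed iteratively against the evolving
consensus but sizes are never scaled, so each subject's centroid size is
preserved exactly. Sliding follows the standard bending-energy formulation:
the consensus defines a triplet of thin-plate splines (one per coordinate,
3D kernel $U(r) = -r$); each non-anchor semilandmark moves along its local
curve tangent (central difference of its border neighbours) by the
closed-form energy-minimizing step, is re-projected onto its source border
polyline, and the step is halved whenever re-projection would raise the
energy — making the energy non-increasing by construction. Junction points
and border endpoints are anchors and never slide. GPA is re-run between the
(default 3) sliding iterations; whether sliding precedes or interleaves
with GPA is not fixed by the method's sources, and interleaving is the
package's documented choice.

## Dimension reduction and the comparison harness

The aligned geometry is flattened to an $N \times 2400$ matrix and each
column z-scored with the population (divide-by-$N$) standard deviation;
zero-variance columns pass through flagged. Classic PCA is computed from
the SVD of the standardized matrix (numerically stabler than forming the
covariance), with the sign convention that each component's
largest-magnitude loading is positive. Kernel PCA supports linear, cosine,
rbf, sigmoid and laplacian kernels (default bandwidth $1/2400$, sigmoid
offset 1); reconstruction uses a ridge-regularized least-squares pre-image
map from score space back to input space, which reproduces classic PCA
exactly for the linear kernel — a useful internal consistency check. The
VAE (dense or strided 1D-convolutional over the point sequence) is
implemented directly in R with analytic gradients (verified against finite
differences in the test suite) and full-batch Adam; it is deliberately an
opt-in extra and the comparison harness runs without it.

`crossval_reduction()` partitions subjects into folds of as-equal-as-possible
size (for $N = 69$ and 10 folds: nine folds of 7 and one of 6), refits the
standardization on each training fold, and reports mean train/test LMD —
the mean Euclidean distance between corresponding points — per method. A
method failure marks its cells and the run continues. With a fixed seed the
table is bitwise reproducible.

For downstream modelling the component count defaults to the smallest $k$
reaching a 95% cumulative explained-variance threshold: the threshold, not
the count, is the primitive.

## The regression shape model

With scores $S_k$ ($N \times k$) and the standardized covariate matrix $F$
(defaults: cranial length, width, circumference, total surface area,
average SI, plus intercept), the coefficient matrix is the least-squares
solution through the Moore-Penrose pseudoinverse, $C = (F^{+} S_k)^\top$.
Prediction maps covariates to scores to geometry (inverse standardization),
and is affine, so midpoint covariates give midpoint shapes. LOOCV refits
standardization, PCA and regression on $N-1$ subjects and predicts the
held-out geometry from its own measured covariates, reporting overall LMD,
per-part LMD over the nine parts, and predicted-versus-measured suture
length/width/SI. Significance tables regress each component's scores on
each covariate (and on all of them) by OLS, reporting $R^2$ and the F-test
p-value starred at $p<10^{-3}$ and $p<10^{-4}$; p-values are raw by
default with a Bonferroni option, matching the convention of reporting
uncorrected stars. A "percentile infant" is the vector of marginal
empirical covariate percentiles — marginal rather than joint for
reproducibility — and the percentile size table is normalized by its first
(5th-percentile) row.

## The synthetic generator

Real infant CT data of this kind is restricted-access, so the package
ships a generator whose subjects exercise every pipeline stage with known
ground truth. The vault is a half-ellipsoid with half-axes 53.5/62.7/45 mm,
giving cranial length 125.4 mm, width 107.0 mm and circumference ~366 mm —
the configured population means; the per-subject size scale has SD 0.0607
(the ratio of the intended length SD, 7.61 mm, to the mean). Suture base
widths are 1.54/5.45/1.88/2.24/2.62 mm (metopic/sagittal/coronal/squamosal/
lambdoid). Borders are laid out in a 2D template (anterior and posterior
fontanelles as rhombi on the midline, sphenoidal and mastoid fontanelles
as circles at the lateral rim, sutures as offset strips around straight or
Bézier centerlines) and lifted onto the ellipsoid. Centerlines leave each
fontanelle corner along its bisector so that suture mouths are cut
symmetrically — this is what makes the geometric junction and the
width-profile corner coincide to within one semilandmark. Interdigitation
is an in-phase sinusoid applied to both edges of a suture (the two edges of
a real interdigitated suture track each other, and in-phase displacement
keeps the width profile flat so the junction criteria respond to anatomy,
not to the wiggle); amplitudes are mild, as appropriate for 2-4-month
sutures, and scale with a per-subject sinuosity factor. Coordinate noise
(SD 0.02 mm, emulating digitization jitter on smooth manual traces) and a
random rigid displacement are applied only *after* ground truth — junction
arc-length fractions, per-suture length/width/SI by dense quadrature,
cranial measures, footprint polygons — is recorded.

Three latent factors (size, fontanelle/width "area" factor, sinuosity
factor) drive the population. Two representations are available:
`"curves"` runs the full nonlinear generator and is what the end-to-end
pipeline consumes; `"semilandmarks"` returns geometry that is an *exact*
affine function of the latents (size scales the template; the other two
factors act through fixed finite-difference displacement fields). The
second exists because uniform resampling does not commute with non-uniform
deformation: only the affine construction gives the exactly-rank-3,
noiseless populations on which the reduction and regression modules can be
tested for exact recovery.

What passing tests on these populations does *not* show: the generator is
not an anatomically validated cranium (no bone thickness, no real
interdigitation statistics, perfect left-right symmetry up to noise), so
test results certify the correctness of the algorithms, not clinical
performance on CT data.

## Numerical choices and limitations

* TPS systems are solved densely; duplicate base-plane projections merge by
  height averaging and conflicting duplicates are errors.
* The bending-energy solve adds a relative ridge of $10^{-12}$ (and warns
  at $10^{-6}$ if the plain solve fails); sliding steps are halved up to 12
  times before a zero step is accepted.
* Fold assignment, VAE initialization and reparameterization draws, and all
  generator randomness are controlled by a single integer seed; reruns are
  byte-identical.
* Problem sizes used in the shipped tests — a 30-subject population at the
  full 800-semilandmark topology for the end-to-end and cross-validation
  checks, smaller fixtures elsewhere — were chosen as the smallest sizes at
  which the exact-recovery properties are non-trivial.
* Known limitations: the five-patch split indices are configurable defaults,
  not anatomy derived from data; per-side SI uses each edge's own junction
  endpoints (the alternative — chords between averaged endpoints — is not
  implemented); no surface (2D) semilandmark sliding, curves only; the
  regression is strictly linear by design.

## A worked example

```{r example, eval = FALSE}
library(suturemorph)

cfg <- pipeline_config(input = synthetic_config(n_subjects = 30, seed = 42),
                       output_dir = "suturemorph_run")
res <- run_pipeline(cfg)

dplyr::select(res$records, subject_id, cranial_length, sagittal_width,
              average_si, total_surface_area)
tidy(res$pca)          # explained variance per component
res$cv$table           # reduction-method comparison (train/test LMD)
glance(res$loocv)      # overall LOOCV error
autoplot(res$percentiles)
```
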