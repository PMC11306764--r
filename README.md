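# suturemorph

Quantitative morphometrics and statistical shape modelling of infant cranial
sutures and fontanelles from traced 3D border curves.

In 2–4-month-old infants the cranial bones are separated by membranous
sutures (metopic, sagittal, coronal, squamosal, lambdoid) and fontanelles
(anterior, posterior, sphenoidal, mastoid). `suturemorph` turns traced border
curves of this anatomy — e.g. 3D Slicer markups exported after CT
segmentation — into reproducible measurements and a predictive shape model:

* **Semilandmarks** — the seven border polylines are resampled to a fixed
  800-point topology (100/100/200/200/50/50/100 per border).
* **Junction points** — 32 junctions split the semilandmarks into the nine
  suture/fontanelle parts, detected from width-change criteria: a junction
  between a midline suture and its fontanelle is the last index with
  `w[i+1] − w[i] > k` and `w[i+1] − w[i] > 10·k·(w[i] − w[i−1])`
  (k = 0.15 mm metopic, 0.18 mm sagittal); lateral junctions are
  second-difference corners `(w[i+1] − w[i]) − (w[i] − w[i−1]) > m`
  (m = 0.4).
* **Morphometrics** — suture length, width, sinuosity index
  (SI = arc length / endpoint chord), cranial length `L`, width `W`,
  circumference `C`, and the total suture/fontanelle surface area `S` from
  five thin-plate-spline patches (kernel `r² log r`), boundary-conforming
  triangulation at a 0.3 mm mean edge, and Heron's formula
  `S = Σ √(s(s−a)(s−b)(s−c))`.
* **Superimposition** — three-point rigid (Kabsch) registration, form-space
  GPA (sizes preserved), and bending-energy sliding of semilandmarks against
  the consensus (triplet of thin-plate splines, anchors fixed).
* **Dimension reduction** — per-column standardized geometry
  `G = Z G₀ = S P`; classic PCA via SVD, five kernel-PCA variants with a
  learned pre-image map, and a pure-R VAE (dense and 1D-convolutional),
  compared by 10-fold cross-validation on the location mean deviation
  (LMD) — the mean Euclidean distance between corresponding points.
* **Statistical model** — component scores regressed on covariates
  {L, W, C, S, SI} through the Moore–Penrose pseudoinverse (`C = (F⁺ Sₖ)ᵀ`),
  evaluated by leave-one-out cross-validation (overall, per-part, and
  predicted-vs-measured suture sizes), with per-covariate R²/F-test
  significance tables and 5th–95th percentile morphologies.

Real CT data of this kind is restricted-access, so the package ships a
synthetic border-curve generator (half-ellipsoid vault, rhombic and circular
fontanelles, interdigitated suture strips) with analytic ground truth for
every stage.

## Worked example

```r
library(suturemorph)

cfg <- pipeline_config(input = synthetic_config(n_subjects = 30, seed = 42),
                       output_dir = "suturemorph_run")
res <- run_pipeline(cfg)

dplyr::summarise(res$records,
                 L = mean(cranial_length), W = mean(cranial_width),
                 C = mean(cranial_circumference),
                 S = mean(total_surface_area), SI = mean(average_si))
#>          L       W        C        S      SI
#> 1 124.5118 106.238 363.0282 3060.588 1.02555

res$cv$table
#>           method  train_lmd   test_lmd failed_folds
#> 1    classic_pca 0.06437011 0.07221646            0
#> 2    kpca_linear 0.06437011 0.07221646            0
#> 3    kpca_cosine 1.01090647 1.17167530            0
#> 4       kpca_rbf 1.13194930 1.46310264            0
#> 5   kpca_sigmoid 0.37278486 0.45057020            0
#> 6 kpca_laplacian 1.07929997 1.39873491            0

mean(res$loocv$per_subject$lmd)
#> [1] 0.07774796
```

The summary row is the synthetic population's cranial length/width/
circumference (mm), total suture-and-fontanelle surface area (mm²) and mean
sinuosity index. The cross-validation table shows that the linear methods
reconstruct held-out subjects to ~0.07 mm mean point error on this
population while the nonlinear kernels generalize worse — the pattern that
motivates using classic PCA for the regression model. The last number is the
leave-one-out error of the full statistical model: predicting each held-out
subject's 800-point geometry from its five measured covariates to within
~0.08 mm on average.

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "suturemorph.R", package = "suturemorph"))')" \
    pipeline --subjects 30 --seed 42 --out suturemorph_run
```

Subcommands `simulate`, `measure` and `pipeline` mirror the exported
functions; every framework constant is a flag (`--k-metopic`,
`--k-sagittal`, `--m-lateral`, `--target-edge`, `--folds`, `--components`,
`--variance-threshold`).

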