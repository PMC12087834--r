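# oculoshape

Quantifies three-dimensional posterior eye shape from binary MRI masks,
computes a twelve-feature fundus morphometry battery from geometric scene
annotations, and links the two with random-intercept mixed models — the
analysis chain for asking whether ordinary fundus photographs carry 3D eye
shape information beyond what refractive error provides. Intended for
ophthalmic imaging researchers who have (or simulate) posterior-eye
segmentations and fundus annotations per eye.

## The model in brief

The posterior segment (vitreous chamber without the lens) is modelled as an
ellipsoid

```
x²/a² + y²/b² + z²/c² = 1
```

with semidiameters *a* (anterior–posterior), *b* (nasal–temporal), *c*
(inferior–superior), fitted by PCA of the foreground voxel coordinates
(eigenvectors give the axes, so rotation is free; semidiameters are
`sqrt(5·eigenvalue)`, the uniform-solid-ellipsoid relation). Shape is
summarised by the asphericities

```
Q_h = b²/a² − 1      Q_v = c²/a² − 1
```

(zero = sphere, negative = prolate, positive = oblate), volume by voxel
counting, and goodness of fit by a radial RMS over boundary voxels.
Repeatability tools: Dice overlap and ICC(A,1). Fundus features include
OD–fovea geometry, Knudtson big-six CRAE/CRVE, arc/chord tortuosity,
box-counting fractal dimension, temporal-arcade concavity and foveal pixel
intensity, with Garway-Heath-style ocular magnification correction.
Associations are estimated with `outcome ~ terms + (1 | participant)`
(lme4, REML, Wald inference), standardizing continuous predictors.

Everything is testable offline: seeded generators produce voxelised
ellipsoids, fundus scenes and cohorts with known ground truth. See the
methods vignette (`vignettes/oculoshape-methods.Rmd`) for every modelling
choice and its rationale.

## Worked example

```r
library(oculoshape)

# a known rotated ellipsoid, voxelised at 1 mm
spec <- ellipsoid_spec(a = 10.5, b = 12, c = 11.2,
                       rotation = c(5, -10, 20), spacing = c(1, 1, 1))
mask <- make_ellipsoid_mask(spec)
fit  <- fit_ellipsoid(mask)
fit
#> <ellipsoid> a = 10.52, b = 11.99, c = 11.22 mm
compute_asphericity(fit)
#>       Q_h       Q_v
#> 0.2988280 0.1361462
compute_volume(mask)     # mm³, vs analytic 4/3·pi·abc = 5910.6
#> [1] 5929
rms_fit_error(mask, fit) # mm; sub-voxel, i.e. excellent fit
#> [1] 0.4873871
```

The recovered semidiameters are within 0.2% of the generating (10.5, 12,
11.2) despite the rotation; both asphericities are positive, i.e. this
synthetic eye is oblate. A fundus scene and its features:

```r
scene <- make_fundus_scene(seed = 7, waviness = 2, ser = -3)
t(extract_features(scene, fd_side = 256))
#> od_fovea_distance   312.50      # px, magnification-corrected (myopic eye: factor > 1)
#> od_fovea_angle       -7.00      # degrees; fovea below the disc horizontal
#> od_area            9374.05
#> od_orientation       75.00
#> od_ovality            1.10
#> crae                 23.27      # big-six arteriolar equivalent
#> crve                 35.12
#> tortuosity            0.032
#> fd                    1.19      # line-like vasculature, as expected
#> arterial_concavity    0.0050    # equals the generating arcade coefficient
#> venous_concavity      0.0050
#> fpi                  60.00
```

A synthetic cohort with the default SER–asphericity slope (0.12 per 2.5 D)
and the Table-2-style model:

```r
tab <- make_cohort(cohort_spec(n_participants = 150, seed = 7))
res <- run_shape_models(tab)
res[res$model == "Q_h", ]
#>   model        term     beta      se  ci_low ci_high         p
#> 1   Q_h (Intercept)  0.18616 0.00840  0.1697  0.2026 6.06e-109
#> 2   Q_h         ser  0.11901 0.00739  0.1045  0.1335  2.16e-58
#> 3   Q_h         age -0.00296 0.00706 -0.0168  0.0109  6.75e-01
#> 4   Q_h        male -0.00148 0.01595 -0.0327  0.0298  9.26e-01
```

The standardized SER coefficient (0.119) recovers the generating slope
(0.12 per 2.5 D × SD(SER)/2.5 ≈ 0.118); age and sex are null by
construction and their intervals cover zero.

## Command line

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "oculoshape.R", package = "oculoshape"))')" \
    simulate --seed 1 --out-dir out/
```

Subcommands: `simulate` (full synthetic run: shape, feature, cohort and
model CSVs plus a provenance JSON recording every methodological toggle),
`fit` (one NIfTI mask + JSON sidecar → shape CSV), `extract` (scene JSON →
feature CSV), `assoc` (cohort CSV → model tables), `all`. Exit status is 0
on success (per-eye failures are logged, not fatal) and 1 on structural
errors.

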