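---
title: "Quantifying posterior eye shape and its fundus correlates: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying posterior eye shape and its fundus correlates: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oculoshape)
```

# The problem

The posterior segment of the eye (the vitreous chamber without the
crystalline lens) is close to an ellipsoid. How far it deviates from a
sphere — its *asphericity* — varies with refractive error: myopic eyes tend
to elongate along the visual axis faster than they widen, moving from an
oblate towards a prolate shape. Asphericity has to be measured in 3D
(typically from MRI), which is impractical in most clinical settings, so a
natural question is whether ordinary fundus photographs carry some of the
same shape information. `oculoshape` implements the full analysis chain for
that question:

1. **eye shape** — ellipsoid fitting and asphericity from binary
   posterior-eye masks;
2. **fundus morphometry** — a twelve-feature battery computed from
   geometric scene annotations;
3. **association** — random-intercept linear mixed models linking features
   to asphericity while absorbing inter-eye correlation;
4. **synthetic data** — seeded generators for all three inputs, so every
   stage is testable without access-restricted cohort data.

# Eye shape model

A binary mask on a voxel grid with spacing $(s_x, s_y, s_z)$ mm is analysed
in millimetre coordinates (indices are scaled by the spacing; the grid is
never resampled). The ellipsoid

$$\frac{x^2}{a^2} + \frac{y^2}{b^2} + \frac{z^2}{c^2} = 1$$

has semidiameters $a$ (anterior–posterior), $b$ (nasal–temporal) and $c$
(inferior–superior). The fit is by principal component analysis of the
foreground voxel-centre coordinates: the centre is the centroid, the axes
are the eigenvectors of the covariance matrix (population $1/N$
normalisation, fixed for reproducibility), and rotation is therefore free —
no assumption of primary gaze is needed.

**Semidiameter scaling.** The variance of a uniform solid ellipsoid along a
principal axis with semidiameter $s$ is $s^2/5$, so the package uses
$s = \sqrt{5\lambda}$. This solid-body convention matches fitting to the
*entire volume* of the segmentation rather than its surface. It is isolated
in one place so a surface-based alternative can be swapped in; alternatives
we evaluated (a Sheppard cube-moment correction, down-weighted boundary
voxels, and radial least squares on boundary voxels) were no better — the
boundary-based variants are biased because boundary voxel centres sit
systematically inside the true surface.

**Asphericity** is $Q_h = b^2/a^2 - 1$ (horizontal meridian) and
$Q_v = c^2/a^2 - 1$ (vertical). Zero is a perfect sphere along that
meridian, negative (long AP axis) is prolate, positive is oblate.

**Volume** is the foreground voxel count times the voxel volume, in mm³.

**Goodness of fit** is a radial RMS: over boundary voxels (foreground with
a background 6-neighbour), the residual is the difference between the voxel
centre's distance from the ellipsoid centre and the surface radius along
the same ray. The true point-to-ellipsoid distance has no closed form; the
radial version is deterministic, fast, and recorded in the output metadata
so downstream users know which definition produced the number.

**Anatomical labelling.** Eigen-axes are assigned to anatomical axes by
maximal absolute dot product with the header directions, with the
nasal–temporal sign resolved by laterality. Perfect eigenvalue ties (a
sphere) fall back to header order; a genuinely ambiguous assignment (two
eigen-axes claiming one label, as happens under very oblique rotations) is
an error rather than a guess. For synthetic masks with arbitrary known
rotations, `fit_ellipsoid(..., label_axes = "none")` skips labelling and
returns size-ordered semidiameters.

**Repeatability statistics.** Dice overlap is $2|A\cap B|/(|A|+|B|)$. The
intraclass correlation defaults to ICC(A,1) — two-way, single-measurement,
absolute agreement — because the analysis compares repeated segmentations
of the same eyes where a systematic session shift should count against
agreement; the consistency form ICC(C,1) is available behind a parameter.

## A numerical subtlety: lattice-aligned centres

While validating rotation invariance we found that voxelising an ellipsoid
whose centre sits exactly on a voxel centre makes the discretisation
antipodally symmetric: the voxel at $+x$ is foreground exactly when the
voxel at $-x$ is. Boundary-inclusion noise then flips in perfectly
correlated antipodal pairs, doubling the jitter of the covariance
eigenvalues across rotations (about 1.2% semidiameter spread at eye scale
with 1 mm voxels, versus about 0.6–0.8% for generic sub-voxel offsets).
Real anatomy is never lattice-aligned, so the acceptance suite draws random
sub-voxel centre offsets alongside random rotations; the lattice-aligned
worst case remains covered by unit tests against the looser 3% recovery
contract.

# Synthetic masks

`make_ellipsoid_mask()` voxelises a rotated ellipsoid, deciding membership
at voxel centres — the convention that keeps counted volume comparable to
the analytic $\tfrac{4}{3}\pi abc$. Default spacing is 1.05 × 1 × 1 mm
(the acquisition geometry of the motivating dataset); isotropic 1 mm is
used in tests. Optional features, both off by default so recovery tests are
exact:

- `surface_noise_sd` (mm): zero-mean Gaussian perturbation of the radial
  boundary decision, seeded explicitly;
- `anterior_truncation_fraction`: removes the anterior cap (modelling the
  lens-excluded chamber) by cutting at $x = a(1 - 2f)$; a sensitivity
  fixture at 0.15 is exercised in the tests.

The generator exposes only these global deviations; staphyloma-like local
bulges and other pathological shape families are out of scope, so a green
recovery test establishes accuracy for globally ellipsoidal eyes only.

# Fundus features

Scenes are geometric annotations (not photographs): an optic-disc ellipse,
a fovea point, vessel centreline polylines with per-point widths and
arteriole/venule labels, and an optional intensity raster. Coordinates are
pixels, y up; left-eye scenes are mirrored internally so every feature is
laterality-invariant (negative OD–fovea angle always means the fovea sits
below the disc horizontal, i.e. greater angular separation).

The twelve features and their key conventions:

| Feature | Definition | Units |
|---|---|---|
| OD–fovea distance | Euclidean distance × magnification factor | px |
| OD–fovea angle | signed angle of the OD→fovea ray vs the horizontal | degrees |
| OD area | $\pi \cdot$ semi-major $\cdot$ semi-minor × factor² | px² |
| OD orientation | major-axis angle folded to [0°, 90°]; a circle reports 90° | degrees |
| OD ovality | major/minor axis ratio (≥ 1) | — |
| CRAE / CRVE | big-six iterative pairing, $\hat w = k\sqrt{w_1^2+w_2^2}$, $k$ = 0.88 / 0.95 | px |
| Tortuosity | length-weighted mean of arc/chord − 1, arterioles and venules pooled | — |
| Fractal dimension | box-counting slope, dyadic ladder side/4 … 2 px | — |
| Arterial / venous concavity | quadratic coefficient of the arcade parabola in the OD→fovea frame | 1/px |
| Foveal pixel intensity | mean intensity in a 10 px disc at the fovea | intensity |

Notes on the open choices:

- **Circle orientation tie-break.** A circular disc has no oblique axis;
  since larger orientation means "more vertical or less oblique", circles
  report 90°. The tie-break is deterministic and documented in the output.
- **Knudtson constants.** The revised branching constants (0.88 arteriolar,
  0.95 venular) are config-exposed arguments. The per-vessel summary width
  is the median of the per-point widths; the measurement-annulus definition
  of the upstream pipeline is not reproduced here, so callers supply widths
  already restricted to their zone of interest.
- **Tortuosity definition.** Arc/chord − 1, length-weighted. Curvature-
  integral variants exist in the literature; arc/chord is the one whose
  analytic test values (semicircle: $\pi/2 - 1$) are exact.
- **Concavity frame.** Both temporal arcades are fitted jointly with the
  parabola's symmetry axis along OD→fovea; the coefficient is positive when
  the arcade opens towards the fovea. The raw coefficient has units 1/px,
  so it scales as $c/f$ under uniform magnification $f$ — it is reported
  raw, not normalised, to keep exact coefficient recovery well defined.
- **Magnification correction.** True retinal dimension per image pixel is
  modelled as proportional to $q = 0.01306\,(\mathrm{AL} - 1.82)$ with
  axial length AL estimated from corneal radius CR and spherical equivalent
  refraction: $\mathrm{AL} = 0.58 + 2.92\,\mathrm{CR} - 0.299\,\mathrm{SER}$.
  These regression constants are package defaults chosen to reproduce
  typical adult biometry (AL ≈ 23.4 mm at CR 7.8 mm, ≈ 0.3 mm of axial
  elongation per dioptre of myopia) and are exposed via `mag_constants()`
  for substitution by a calibrated set. The factor is anchored to exactly 1
  at the emmetropic reference (SER 0, CR 7.8 mm), applied to linear metrics
  (squared for areas) and monotone: more myopic eyes get factors above 1.
- **FPI.** Defined here as the mean intensity in a 10 px disc (radius
  configurable); the colour channel is whatever the supplied raster
  contains. Discs clipped by the image border are averaged over the
  in-bounds intersection and flagged.

The scene generator `make_fundus_scene()` records its exact generating
parameters, so feature extraction can be tested as a round trip. Its
defaults emulate a 45° macula-centred photograph at roughly 1000 px scale
(OD–fovea distance 300 px, angle −7°, OD 55 × 50 px, arcade coefficient
0.005/px, arteriolar widths ≈ 13 px, venular ≈ 16 px). It does not emulate
photographic appearance, vessel branching topology, or segmentation error —
a green round-trip test establishes correctness of the geometry code, not
robustness to annotation noise.

# Association models

All models are linear mixed models with a per-participant random intercept,
the standard device for using both eyes of a participant without
pretending they are independent: `outcome ~ terms + (1 | participant)`,
fitted by REML via `lme4`. Continuous predictors are standardized to zero
mean and unit variance *on the analysis sample after exclusions*; sex is a
0/1 male indicator (female reference) and is never z-scored, so its
coefficient stays interpretable as a group difference.

Inference is Wald with a normal reference distribution (95% CI
$\hat\beta \pm 1.96\,\mathrm{SE}$). Satterthwaite small-sample degrees of
freedom would be marginally more conservative but the required package is
not a dependency here; at the simulation sizes used for calibration
(150 participants) the Wald intervals hold their nominal coverage within
the acceptance band, which the test suite verifies by simulation
(200 replicates: coverage in [90%, 98%], type-I error for a null feature in
[2%, 9%]).

Degenerate limits are handled explicitly: when every participant
contributes one eye the intercept variance is unidentifiable and the fit
drops to ordinary least squares, flagged `degenerate_clustering`; a fitted
intercept variance of zero (boundary REML estimate) is flagged `singular`,
not failed, and reproduces OLS coefficients exactly. Rank-deficient fixed
designs error, naming the aliased terms.

`run_shape_models()` fits asphericity and volume on SER + age + sex (plus
the height-adjusted volume variant); `run_feature_models()` fits each
feature × each meridian, unadjusted and adjusted for SER + age + sex. No
multiple-testing correction is applied by default across the 24 feature
models (a `p_adjust` option exists), matching the convention of reporting
unadjusted p-values.

# Synthetic cohorts

`make_cohort()` generates the statistical world the models are tested
against. Defaults follow the motivating study population: SER ~ Normal
(−0.26, 2.46²) D with a small (0.25 D SD) inter-eye difference; age
54.5 ± 7.7 years truncated to 45–71; 72% female; heights around
163/177 cm (female/male). Horizontal asphericity is linear in SER at 0.12
per 2.5 D around a baseline of 0.20 (eyes mostly oblate), vertical uses
0.11 per 2.5 D around 0.16 (vertically less oblate); volume is centred at
4433 mm³, grows 240 mm³ per 2.5 D of myopic shift, and carries a height
effect of 33.5 mm³/cm calibrated so the ≈ 470 mm³ male–female difference
is fully height-mediated — reproducing the attenuation of the sex effect
once height enters the model. The random-intercept SD (0.07) and residual
SD (0.05) are the package's choice of a realistic split: they give a
within-participant correlation of about 0.66 and a total asphericity SD
near 0.15. Features are unit-variance z-scores with a 0.3 loading on
standardized SER, plus any direct effects supplied via `feature_effects`.

Every generator draws all randomness from one explicit seed and restores
the caller's RNG state, so identical specs give bit-identical outputs.

# Numerical choices and degenerate inputs

- Covariance normalisation 1/N (population); at thousands of voxels the
  1/(N−1) difference is far below all tolerances, but the choice is fixed.
- Voxel membership at centres; no partial-volume weighting.
- Box-counting ladder: dyadic sizes from side/4 down to 2 px, at least
  5 ladder points, least squares in log–log space; maps with fewer than
  10 foreground pixels return the missing-value sentinel (`NA`).
- Empty masks load but are rejected by analysis operations; masks with
  fewer than 30 foreground voxels or coplanar foreground refuse to fit.
- Zero-chord (closed-loop) vessels are excluded from tortuosity with a
  warning; a fovea coincident with the OD centre is an error (angle
  undefined); features that cannot be computed are `NA` sentinels, and
  model fitting skips all-sentinel columns with a logged reason.
- NIfTI pixdim is float32; spacing is snapped to 7 significant digits on
  read so values like 1.05 mm survive the round trip exactly.

# Known limitations

- The magnification constants are plausible defaults, not a calibrated
  reproduction of any specific camera model; treat corrected dimensional
  features as internally consistent rather than absolutely scaled.
- The radial RMS definition may differ systematically from other
  goodness-of-fit definitions in the literature; compare like with like.
- Wald (normal) inference, not Satterthwaite; with very few participants
  intervals will be anticonservative.
- The generators produce globally ellipsoidal eyes and noiseless geometric
  annotations; neither pathological shape families nor annotation error are
  modelled, and test results should be read with that scope in mind.
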