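---
title: "Accumulated dose modelling for combined EBRT and brachytherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accumulated dose modelling for combined EBRT and brachytherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtaccum)
```

## The problem

Cervical-cancer radiotherapy combines a whole-pelvis external beam course
(EBRT; 45 or 50 Gy in 25 fractions here) with an intracavitary high-dose-rate
brachytherapy boost (BT; four fractions of 6 Gy). The courses are optimized
independently and live on different planning images, so the dose the bladder
and rectum accumulate across both is not directly visible — least of all at
EBRT planning time, when the BT dose does not exist yet. `rtaccum` provides
the pieces of a pipeline that (i) accumulates the two courses in a common
radiobiological currency on a common grid, (ii) learns to predict the
accumulated dose from EBRT-planning anatomy alone, and (iii) turns the
prediction into an actionable avoidance contour and quantifies the benefit
of replanning with DVH metrics and NTCP.

## Dose accumulation model

All physical doses are first converted voxel-wise to the equivalent dose in
2 Gy fractions under the linear-quadratic model,

$$\mathrm{EQD2} = D\,\frac{d + \alpha/\beta}{2 + \alpha/\beta},\qquad
d = D/n_\text{fractions},$$

with $\alpha/\beta$ = 10 Gy for tumour and 3 Gy for late-responding normal
tissue. The grid is assumed to hold the total dose of a course delivered in
equal fractions, so the per-fraction dose $d$ varies voxel by voxel.
Delivery at exactly 2 Gy per fraction is a fixed point of the conversion,
which the tests exploit. Only the first BT fraction is imaged; because EQD2
is additive over identical fractions, the full course is obtained by
multiplying the single-fraction EQD2 grid by the fraction count — applied
*after* the per-fraction conversion, which is algebraically identical to
converting four equal fractions.

Deformable registration between the BT and EBRT frames is deliberately out
of scope: it is performed by dedicated (typically commercial, hybrid
contour-plus-intensity) systems. The package instead accepts an explicit
deformation vector field as input — pull-back displacement vectors in mm on
the reference (EBRT) grid — and implements the application of that field:
trilinear resampling of the BT dose at `center(v) + displacement(v)`, with
zeros outside the source extent. The CT-number override utility
(`override_ct_numbers()`) supports the standard preprocessing that gives
registration contours a consistent intensity in both image sets.
Voxel-center convention throughout: physical coordinate = origin +
index · spacing, 0-based, mm.

A deliberately open point: at structure boundaries a voxel-level α/β
assignment is ambiguous (a voxel cannot belong to both a tumour and a
late-responding tissue class at conversion time). The package converts each
course with the α/β the caller supplies and leaves per-structure choices to
masking at the analysis stage; NTCP is evaluated on accumulated EQD2 grids,
the only accumulated quantity the pipeline defines.

## Anatomy channels

The dose predictor sees three channels per axial slice:

* **CT**, windowed −1000…1000 HU and scaled to [0, 1];
* **structure label map**: each target/OAR gets a power-of-two base label
  (body-only voxels are 1, exterior 0) and overlapping voxels get the *sum*
  of their labels. Powers of two make every sum unique and invertible
  (`decode_label()`), which the round-trip property tests check; custom
  tables are screened for collisions over the overlaps actually present;
* **distance-to-target (DTT) map**: for each body voxel outside the PTV,
  the minimum Euclidean distance (mm, anisotropic spacing respected) to the
  nearest PTV voxel; 0 inside the PTV and outside the body. "Surface
  distance" is operationalized as distance to the nearest PTV *voxel
  center* — a face-adjacent voxel is one spacing away, not half — because
  the half-voxel convention is ambiguous on coarse grids. The computation
  is exact: query voxels are compared against the PTV's 6-neighbourhood
  boundary voxels (the nearest PTV voxel to an external point is always one
  of these) with a chunked BLAS distance expansion, and the tests verify
  exact agreement with an exhaustive oracle on small anisotropic grids.

## The prediction model

No deep-learning framework is assumed: the network is a compact residual
encoder–decoder whose 3×3/1×1 convolution kernels (forward and backward)
are compiled C++ (im2col + BLAS), with leaky-ReLU activations (negative
slope 0.01, which keeps every unit trainable on unlucky seeds), stride-2
downsampling, nearest-neighbour upsampling and additive skip connections;
one residual block per resolution level on each path. Two presets satisfy
one I/O contract: `full` (3 levels, 16 base channels) is shaped for real
cohorts; `reduced` (2 levels, 8 base channels, ~21k parameters) trains on a
single CPU in minutes and is what the test suite exercises. Prediction is
2-D, slice by slice; 3-D context is out of scope.

Training minimizes the mean squared error on normalized dose (dose divided
by the summed prescription EQD2, 76.25 Gy by default) with Adam at an
initial rate of 4·10⁻³, divided by 5 for the last quarter of the epochs —
the step settles the steep-gradient hotspot region without destabilizing
the smooth plateau — and global gradient-norm clipping at 0.5 as a guard
against occasional exploding minibatch steps. Weight initialization, fold assignment and minibatch
shuffling all derive from one root seed, and the kernels are deterministic,
so a rerun reproduces the loss trajectory exactly. Cross-validation is
patient-level: folds are seeded, disjoint, and no slice of a validation
patient is ever seen in training. Model quality is reported as held-out MAE
in Gy over the body mask, next to a *cohort-mean baseline* — the voxel-wise
mean training dose map used as a constant predictor — which any model that
actually reads the anatomy must beat.

## Scoring and the redesign aid

`cumulative_dvh()` builds relative cumulative DVHs (inclusive thresholds,
default bin 0.1 Gy); V50/V60 are percent of structure volume; D2cc is
computed by discrete voxel sorting without sub-voxel interpolation — with
phantom voxels of 0.08 cm³ the discretization error is far below a bin
width. The dice similarity of isodose volumes is evaluated from 10 to
160 Gy in 10 Gy steps; isodose thresholds are inclusive, and the DSC of two
empty masks is defined as 1 (perfect agreement of absence) because high
levels can vanish on both grids. NTCP uses the standard
Lyman–Kutcher–Burman probit-on-gEUD form with the printed organ parameters;
$\Phi$ is evaluated via `pnorm` (error-function accuracy, ~10⁻¹²), gEUD in
log space so that volume exponents as small as 10⁻³ cannot overflow. The
self-consistency check — root-finding the uniform dose at which NTCP = ½ —
recovers D50 = 80 Gy for both organs to below 10⁻⁶ Gy, independent of the
volume exponent (a uniform field makes gEUD equal that dose for every
exponent). Probabilities are stored as fractions; ‰/% formatting is left to
the reporting layer.

The redesign aid intersects a predicted isodose volume (70 Gy by default)
with an OAR mask to form an avoidance contour. `simulate_redesign()` is an
analytic stand-in for replanning: it scales the EBRT component down by a
chosen fraction inside the contour with a Gaussian falloff (σ = 16 mm — a
plan re-optimization redistributes dose over centimetre scales, not single
voxels) at its border, never increases dose anywhere, and leaves dose
outside the falloff support untouched. On a 4 mm grid the discrete V50/V60
estimators only move when a voxel crosses the threshold, so per-case strict
decreases additionally require that a voxel sit within the falloff's reach
of the threshold — which the phantom geometry below provides by placing
both organs against the boost region. Paired conventional/redesigned metrics are
compared with a two-sided Wilcoxon signed-rank test at α = 0.05
(`stats::wilcox.test`: exact for small samples without ties, normal
approximation with corrections otherwise).

## The synthetic phantom cohort

The generator emulates the pelvic geometry the pipeline must handle, not
patient realism: an ellipsoidal body with a bony rim, an anterior bladder
(~60 cm³, its posterior wall against the central boost region), a posterior
rectum whose anterior wall likewise abuts it — both organs are partly
inside the EBRT target, which is exactly the clinical configuration that
makes their accumulated dose hard to manage — a central uterus+vagina
(U+V) ellipsoid, and a PTV formed by expanding the U+V by a 15 mm margin
(clipped to the body).
Per-case variation comes from uniform centre jitter (±4 mm) and radius
scaling (±15%); organs that fail to fit inside the body are re-jittered
with derived seeds a bounded number of times. CT is tissue-class
intensities plus Gaussian noise (σ = 20 HU).

The truth dose is built analytically, already in accumulated-EQD2 form:

* **EBRT term** — prescription EQD2 (45 Gy/25 fx, α/β 10 → 44.25 Gy) times
  a Gaussian-smoothed PTV indicator (penumbra σ = 6 mm);
* **BT term** — an inverse-square kernel summed over dwell points spaced
  5 mm along the central U+V axis, normalized so the physical fraction dose
  is 6 Gy at 35 mm laterally, converted per fraction to EQD2, multiplied by
  4 fractions, and capped at 160 Gy so the full 10–160 Gy isodose range is
  exercised.

The kernel is a generic line-source surrogate, *not* TG-43 dosimetry; its
purpose is the steep central gradient. The normalization radius is chosen
so the 70 Gy accumulated isodose reliably reaches the anterior rectal and
posterior bladder walls across the jitter range — the clinical situation
the redesign aid exists for; with it, every phantom in a seeded cohort has
a non-empty 70 Gy overlap with both organs. Because the truth dose is a
deterministic function of the anatomy, it is learnable in principle from
the channels; what passing the learnability tests does **not** show is
performance on real patients, where dose is shaped by optimizer trade-offs,
applicator variation and registration error that the phantom deliberately
omits. The two dose components are stored separately on each case, so the
accumulation identity (EBRT term + BT term = truth, exactly) is testable,
and an analytic redesign can rescale only the EBRT part.

The default problem size — 64×64×24 voxels at 4×4×5 mm, 10-patient cohorts,
30 epochs per fold — was chosen so that a full 5-fold run of the reduced
model completes in minutes on a single CPU while still spanning the full
dose range; the tests and the worked example use exactly these sizes.

## Numerical choices and degenerate inputs

* Trilinear interpolation with zero fill outside the voxel-center hull; at
  exact voxel centers the interpolation weights are exactly 0/1, so warping
  with an identity field is bit-for-bit.
* Dose grids reject negative or non-finite values at construction instead
  of clamping, so corrupt inputs surface immediately.
* Empty masks raise errors in every mask-reducing metric (MAE, DVH, V_x,
  D_xcc, gEUD); a structure smaller than the requested D_xcc volume is an
  error, not an extrapolation.
* gEUD of an all-zero dose region is 0 by convention; zero-dose voxels
  contribute exp(−∞) = 0 terms in log space rather than NaNs.
* Identical paired samples short-circuit the signed-rank test to p = 1
  (the test statistic is undefined when all differences are zero).
* Label maps with custom (non-power-of-two) tables are accepted only if no
  two observed overlap combinations share a summed value.

## Known limitations

* No deformable registration and no DICOM import: volumes travel as NIfTI,
  fields as explicit arrays.
* The network is a compact stand-alone architecture; it does not claim
  fidelity to any specific published classification backbone, and the
  `full` preset has not been trained on clinical data here.
* D2cc uses discrete voxel sorting; on coarse grids with very small
  structures the estimate is conservative by up to one voxel volume.
* The phantom's BT kernel ignores applicator geometry, source anisotropy
  and tissue heterogeneity.
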