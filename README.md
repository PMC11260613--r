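# rtaccum

Accumulated-dose modelling for combined cervical-cancer radiotherapy in R.

Definitive cervical-cancer treatment combines whole-pelvis external beam
radiotherapy (EBRT, typically 45–50 Gy in 25 fractions) with an
intracavitary high-dose-rate brachytherapy boost (BT, e.g. 4 × 6 Gy).
Because the two courses are planned independently, the *accumulated* dose a
patient's bladder and rectum actually receive is not visible at EBRT
planning time. `rtaccum` implements the full analysis chain needed to
estimate, predict and act on that accumulated dose:

1. **EQD2 accumulation** — physical dose grids are converted voxel-wise to
   equivalent dose in 2 Gy fractions under the linear-quadratic model,

   `EQD2 = D (d + α/β) / (2 + α/β)`, `d = D / n`,

   with α/β = 10 Gy for tumours and 3 Gy for late-responding normal tissue;
   the single imaged BT fraction is scaled to the full course, warped onto
   the EBRT frame with a supplied deformation vector field, and summed.
2. **Anatomy channels** — the inputs of the dose-prediction model: the
   planning CT, a unique-label structure map (power-of-two base labels,
   summed in overlaps so every combination stays decodable), and the
   distance-to-target map (DTT: minimum distance in mm from the PTV surface
   to each normal-tissue voxel).
3. **Voxel-wise dose prediction** — a residual encoder–decoder network
   mapping the three anatomy channels to the accumulated dose, slice by
   slice, trained with k-fold cross-validation at patient level. The
   convolution kernels are compiled (Rcpp/RcppArmadillo); no external deep
   learning framework is required.
4. **Plan scoring** — cumulative DVHs, V50/V60 (% of structure volume),
   D2cc (minimum dose of the hottest 2 cm³), the dice similarity (DSC) of
   isodose volumes from 10 to 160 Gy, and Lyman–Kutcher–Burman NTCP,

   `NTCP = Φ((gEUD − D50) / (m · D50))`, `gEUD = (mean dᵢ^{1/n})ⁿ`,

   with printed parameter sets for rectum (D50 = 80 Gy, m = 0.15, n = 0.12)
   and bladder (D50 = 80 Gy, m = 0.11, n = 0.50).
5. **Redesign aid** — the overlap between a predicted isodose volume
   (70 Gy) and the bladder/rectum as an avoidance contour, plus an analytic
   redesign simulator and a Wilcoxon signed-rank comparison of paired
   conventional/redesigned plan metrics.

A seeded synthetic pelvic-phantom generator (body, PTV, bladder, rectum,
uterus+vagina, EBRT-like plateau plus BT-like central hotspot) makes the
whole pipeline runnable and testable without patient data.

## Worked example

```r
library(rtaccum)

# EQD2 accumulation of the two courses (uniform fields for illustration)
ebrt <- eqd2_convert(uniform_dose_grid(45), fractionation_scheme(45, 25, 10))
bt   <- scale_bt_course(
          eqd2_convert(uniform_dose_grid(6), fractionation_scheme(6, 1, 10)), 4)
acc  <- accumulate_dose(ebrt, bt)
max(acc$values)
#> [1] 76.25

# NTCP of a uniform 80 Gy rectum dose sits exactly at the D50 point
m <- array(TRUE, c(8, 8, 8))
lkb_ntcp(uniform_dose_grid(80), m, default_lkb_parameters()$rectum)
#> <ntcp_result> rectum: gEUD = 80.00 Gy, t = 0.000, NTCP = 0.5

# Synthetic cohort -> 5-fold training of the reduced model -> evaluation
cohort  <- generate_cohort(phantom_spec(), 10, 1)
samples <- assemble_cohort(cohort$cases, dose_ref = 76.25)
fit     <- train_kfold(samples, training_config(seed = 1))   # ~12 min on 1 CPU
glance(fit)
#> # A tibble: 1 × 5
#>   folds n_patients mean_mae_gy mean_baseline_mae_gy preset
#>   <int>      <int>       <dbl>                <dbl> <chr>
#> 1     5         10        1.64                 3.00 reduced
```

The held-out whole-body mean absolute error (1.64 Gy, ≈2% of the 76.25 Gy
summed prescription) beats the cohort-mean-dose baseline (3.00 Gy), showing
the model actually reads the per-case anatomy rather than memorizing an
average dose map.

A command-line front end covering the same pipeline
(`phantom-generate`, `accumulate`, `make-inputs`, `train`, `predict`,
`evaluate`, `ntcp`, `compare`, `overlap`) is installed at
`inst/cli/rtaccum`:

```sh
Rscript inst/cli/rtaccum phantom-generate --n 10 --seed 7 --out cohort/
```

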