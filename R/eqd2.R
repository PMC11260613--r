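#' Fractionation scheme
#'
#' Describes how a physical dose course was delivered: total prescription
#' dose, number of equal fractions, and the tissue radiosensitivity ratio
#' alpha/beta used by the linear-quadratic model. Conventional values are
#' alpha/beta = 10 Gy for tumours and 3 Gy for late-responding normal tissue.
#'
#' @param total_dose prescription dose of the course in Gy (>= 0).
#' @param n_fractions number of equal fractions (positive integer).
#' @param alpha_beta alpha/beta ratio in Gy (> 0).
#' @return An object of class `fractionation_scheme`.
#' @examples
#' fractionation_scheme(45, 25, alpha_beta = 10)
#' @export
fractionation_scheme <- function(total_dose, n_fractions, alpha_beta) {
  total_dose <- as.numeric(total_dose)
  n_fractions <- as.numeric(n_fractions)
  alpha_beta <- as.numeric(alpha_beta)
  if (!is.finite(total_dose) || total_dose < 0) {
    stop("`total_dose` must be finite and non-negative", call. = FALSE)
  }
  if (!is.finite(n_fractions) || n_fractions < 1 ||
      n_fractions != round(n_fractions)) {
    stop("`n_fractions` must be a positive integer", call. = FALSE)
  }
  if (!is.finite(alpha_beta) || alpha_beta <= 0) {
    stop("`alpha_beta` must be positive", call. = FALSE)
  }
  structure(list(total_dose = total_dose, n_fractions = as.integer(n_fractions),
                 alpha_beta = alpha_beta),
            class = "fractionation_scheme")
}

#' @export
print.fractionation_scheme <- function(x, ...) {
  cat(sprintf("<fractionation_scheme> %g Gy in %d fx (%.3g Gy/fx), a/b = %g Gy\n",
              x$total_dose, x$n_fractions, x$total_dose / x$n_fractions,
              x$alpha_beta))
  invisible(x)
}

#' Convert a physical dose grid to EQD2
#'
#' Converts voxel-wise physical dose to equivalent dose in 2 Gy fractions
#' under the linear-quadratic model:
#' `EQD2 = D * (d + alpha/beta) / (2 + alpha/beta)`, where `D` is the voxel
#' total dose and `d = D / n_fractions` the voxel dose per fraction. The grid
#' is assumed to hold the total dose delivered in `n_fractions` equal
#' fractions, so the per-fraction dose varies voxel by voxel. A course
#' delivered at exactly 2 Gy per fraction is unchanged; zero voxels stay zero.
#'
#' @param dose a [dose_grid()] of total physical dose.
#' @param scheme a [fractionation_scheme()]; its `n_fractions` and
#'   `alpha_beta` drive the conversion.
#' @return A [dose_grid()] of EQD2 values on the same geometry.
#' @examples
#' ebrt <- uniform_dose_grid(45)
#' eqd2_convert(ebrt, fractionation_scheme(45, 25, 10))$values[1]  # 44.25
#' @export
eqd2_convert <- function(dose, scheme) {
  stopifnot(inherits(dose, "dose_grid"))
  if (!inherits(scheme, "fractionation_scheme")) {
    stop("`scheme` must be a fractionation_scheme", call. = FALSE)
  }
  ab <- scheme$alpha_beta
  d <- dose$values / scheme$n_fractions
  with_values(dose, dose$values * (d + ab) / (2 + ab))
}

#' Scale a single-fraction BT dose to a full course
#'
#' EQD2 is additive over identical fractions, so the total-course EQD2 of a
#' brachytherapy boost imaged only at its first fraction is obtained by
#' multiplying the single-fraction EQD2 grid by the number of fractions.
#'
#' @param bt_fraction_eqd2 a [dose_grid()] holding one BT fraction already in
#'   EQD2.
#' @param n_bt_fractions number of BT fractions (>= 1).
#' @return A [dose_grid()] of the full BT course in EQD2.
#' @export
scale_bt_course <- function(bt_fraction_eqd2, n_bt_fractions) {
  stopifnot(inherits(bt_fraction_eqd2, "dose_grid"))
  n <- as.numeric(n_bt_fractions)
  if (!is.finite(n) || n < 1) {
    stop("`n_bt_fractions` must be >= 1", call. = FALSE)
  }
  with_values(bt_fraction_eqd2, bt_fraction_eqd2$values * n)
}

#' Sum two dose grids on a common frame
#'
#' Voxel-wise accumulation of the EBRT EQD2 grid and the warped total-course
#' BT EQD2 grid. Both grids must share one geometry and frame label; the
#' operation is commutative and the result is at least as large as either
#' input everywhere.
#'
#' @param ebrt_eqd2,bt_total_eqd2_warped [dose_grid()] objects on one frame.
#' @return The accumulated [dose_grid()].
#' @export
accumulate_dose <- function(ebrt_eqd2, bt_total_eqd2_warped) {
  stopifnot(inherits(ebrt_eqd2, "dose_grid"),
            inherits(bt_total_eqd2_warped, "dose_grid"))
  if (!same_geometry(ebrt_eqd2, bt_total_eqd2_warped) ||
      !identical(ebrt_eqd2$frame_id, bt_total_eqd2_warped$frame_id)) {
    stop_geometry_mismatch("dose grids (geometry and frame_id)")
  }
  with_values(ebrt_eqd2, ebrt_eqd2$values + bt_total_eqd2_warped$values)
}
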