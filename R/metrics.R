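#' Mean absolute dose error inside a structure
#'
#' Voxel-wise mean of `|pred - actual|` over the mask, in Gy. The standard
#' per-structure accuracy score for voxel-wise dose prediction.
#'
#' @param pred,actual [dose_grid()] objects on one geometry.
#' @param mask non-empty 3-D logical array on the same geometry.
#' @return MAE in Gy.
#' @export
mae_in_mask <- function(pred, actual, mask) {
  stopifnot(inherits(pred, "dose_grid"), inherits(actual, "dose_grid"))
  if (!same_geometry(pred, actual) ||
      !identical(as.integer(dim(mask)), pred$geometry$shape)) {
    stop_geometry_mismatch("dose grids and mask")
  }
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  mean(abs(pred$values[mask] - actual$values[mask]))
}

#' Dice similarity coefficient of two masks
#'
#' `2|A & B| / (|A| + |B|)`; defined as 1 when both masks are empty (perfect
#' agreement of absence — relevant for isodose levels above both grids'
#' maxima).
#'
#' @param a,b 3-D logical arrays of the same dimensions.
#' @return DSC in `[0, 1]`.
#' @export
dsc <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop_geometry_mismatch("masks")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

#' Dice profile of isodose volumes
#'
#' Compares predicted and actual dose distributions level by level: the DSC
#' of the two isodose volumes at each level, by default 10 to 160 Gy in
#' 10 Gy steps (16 levels).
#'
#' @param pred,actual [dose_grid()] objects on one geometry.
#' @param levels isodose levels in Gy.
#' @return A tibble with columns `level_gy`, `dsc`.
#' @export
isodose_dsc_profile <- function(pred, actual, levels = seq(10, 160, by = 10)) {
  stopifnot(inherits(pred, "dose_grid"), inherits(actual, "dose_grid"))
  if (!same_geometry(pred, actual)) stop_geometry_mismatch("dose grids")
  tibble::tibble(
    level_gy = as.numeric(levels),
    dsc = vapply(levels, function(L) {
      dsc(isodose_volume(pred, L), isodose_volume(actual, L))
    }, numeric(1))
  )
}

#' Cumulative dose-volume histogram
#'
#' Relative cumulative DVH of a structure: the fraction of the structure
#' volume receiving at least each dose bin edge (inclusive), starting at
#' 1 for 0 Gy and non-increasing in dose. The absolute structure volume in
#' cm^3 is attached as an attribute and column.
#'
#' @param dose a [dose_grid()].
#' @param mask non-empty 3-D logical array on the dose geometry.
#' @param bin_width histogram bin width in Gy (default 0.1).
#' @return A tibble of class `dvh` with columns `dose_gy`, `rel_volume`,
#'   and attribute `volume_cc`.
#' @export
cumulative_dvh <- function(dose, mask, bin_width = 0.1) {
  stopifnot(inherits(dose, "dose_grid"))
  if (!identical(as.integer(dim(mask)), dose$geometry$shape)) {
    stop_geometry_mismatch("dose grid and mask")
  }
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  if (!is.finite(bin_width) || bin_width <= 0) {
    stop("`bin_width` must be positive", call. = FALSE)
  }
  d <- dose$values[mask]
  edges <- seq(0, max(d) + bin_width, by = bin_width)
  counts <- vapply(edges, function(e) sum(d >= e), numeric(1))
  out <- tibble::tibble(dose_gy = edges, rel_volume = counts / length(d))
  attr(out, "volume_cc") <- length(d) * voxel_volume_cc(dose$geometry)
  class(out) <- c("dvh", class(out))
  out
}

#' Volume receiving at least a dose threshold (V_x)
#'
#' Percentage of the structure volume receiving at least `threshold` Gy
#' (inclusive), the V50/V60-style DVH parameter.
#'
#' @param dose a [dose_grid()].
#' @param mask non-empty 3-D logical array.
#' @param threshold dose threshold in Gy.
#' @return percent of structure volume, in `[0, 100]`.
#' @export
volume_at_dose <- function(dose, mask, threshold) {
  stopifnot(inherits(dose, "dose_grid"))
  if (!identical(as.integer(dim(mask)), dose$geometry$shape)) {
    stop_geometry_mismatch("dose grid and mask")
  }
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  100 * sum(dose$values[mask] >= threshold) / sum(mask)
}

#' Minimum dose to the hottest fixed volume (D_x cc)
#'
#' Sorts the structure's voxel doses in decreasing order and returns the dose
#' of the voxel at which the cumulative voxel volume first reaches
#' `volume_cc` — the D2cc-style near-maximum dose metric. Discrete voxel
#' sorting, no sub-voxel interpolation.
#'
#' @param dose a [dose_grid()].
#' @param mask 3-D logical array; its volume must be at least `volume_cc`.
#' @param volume_cc hottest volume of interest in cm^3 (default 2).
#' @return dose in Gy.
#' @export
dose_at_volume_cc <- function(dose, mask, volume_cc = 2) {
  stopifnot(inherits(dose, "dose_grid"))
  if (!identical(as.integer(dim(mask)), dose$geometry$shape)) {
    stop_geometry_mismatch("dose grid and mask")
  }
  vox_cc <- voxel_volume_cc(dose$geometry)
  n_mask <- sum(mask)
  if (n_mask * vox_cc < volume_cc) {
    stop(sprintf("structure volume %.2f cc is smaller than the requested %g cc",
                 n_mask * vox_cc, volume_cc), call. = FALSE)
  }
  d <- sort(dose$values[mask], decreasing = TRUE)
  k <- which(seq_along(d) * vox_cc >= volume_cc)[1]
  d[k]
}

#' Tidy metric table for one predicted/actual dose pair
#'
#' Convenience wrapper producing the tidy (structure, metric, value) table
#' used by the pipeline's evaluate step: per-structure MAE plus V50, V60 and
#' D2cc of the actual and predicted dose.
#'
#' @param pred,actual [dose_grid()] objects.
#' @param structures a [structure_set()]; all masks are scored.
#' @return A tibble with columns `structure`, `metric`, `value`.
#' @export
evaluate_dose_pair <- function(pred, actual, structures) {
  stopifnot(inherits(structures, "structure_set"))
  rows <- lapply(names(structures$masks), function(nm) {
    m <- structures$masks[[nm]]
    if (!any(m)) return(NULL)
    tibble::tibble(structure = nm,
                   metric = c("mae_gy", "v50_actual_pct", "v50_pred_pct",
                              "v60_actual_pct", "v60_pred_pct"),
                   value = c(mae_in_mask(pred, actual, m),
                             volume_at_dose(actual, m, 50),
                             volume_at_dose(pred, m, 50),
                             volume_at_dose(actual, m, 60),
                             volume_at_dose(pred, m, 60)))
  })
  do.call(rbind, rows)
}

#' Plot a cumulative DVH
#'
#' @param dvh a `dvh` tibble from [cumulative_dvh()], or a named list of them
#'   (one curve per structure).
#' @return a ggplot object.
#' @export
plot_dvh <- function(dvh) {
  if (inherits(dvh, "dvh")) dvh <- list(structure = dvh)
  df <- do.call(rbind, lapply(names(dvh), function(nm) {
    tibble::tibble(structure = nm, dose_gy = dvh[[nm]]$dose_gy,
                   rel_volume = dvh[[nm]]$rel_volume)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = dose_gy,
                                   y = 100 * rel_volume,
                                   colour = structure)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = "Dose (Gy)", y = "Volume (%)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an isodose DSC profile
#'
#' @param profile tibble from [isodose_dsc_profile()].
#' @return a ggplot object.
#' @export
plot_isodose_dsc <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = level_gy, y = dsc)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Isodose level (Gy)", y = "DSC") +
    ggplot2::theme_minimal()
}
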