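#' Trilinear sampling of a 3-D field at arbitrary physical points
#'
#' Points outside the voxel-center hull of the source grid return 0.
#'
#' @param values 3-D array.
#' @param geom `grid_geometry` of `values`.
#' @param pts n x 3 matrix of physical coordinates (mm).
#' @return numeric vector of sampled values.
#' @noRd
sample_trilinear <- function(values, geom, pts) {
  n <- geom$shape
  t1 <- (pts[, 1] - geom$origin[1]) / geom$spacing[1]
  t2 <- (pts[, 2] - geom$origin[2]) / geom$spacing[2]
  t3 <- (pts[, 3] - geom$origin[3]) / geom$spacing[3]
  eps <- 1e-9
  outside <- t1 < -eps | t1 > n[1] - 1 + eps |
             t2 < -eps | t2 > n[2] - 1 + eps |
             t3 < -eps | t3 > n[3] - 1 + eps

  clamp_idx <- function(t, nn) pmin(pmax(floor(t), 0), max(nn - 2, 0))
  i1 <- clamp_idx(t1, n[1]); f1 <- pmin(pmax(t1 - i1, 0), 1)
  i2 <- clamp_idx(t2, n[2]); f2 <- pmin(pmax(t2 - i2, 0), 1)
  i3 <- clamp_idx(t3, n[3]); f3 <- pmin(pmax(t3 - i3, 0), 1)
  s1 <- if (n[1] > 1) 1L else 0L
  s2 <- if (n[2] > 1) 1L else 0L
  s3 <- if (n[3] > 1) 1L else 0L

  base <- 1 + i1 + n[1] * (i2 + n[2] * i3)
  v <- numeric(nrow(pts))
  for (d1 in 0:1) for (d2 in 0:1) for (d3 in 0:1) {
    w <- (if (d1 == 1) f1 else 1 - f1) *
         (if (d2 == 1) f2 else 1 - f2) *
         (if (d3 == 1) f3 else 1 - f3)
    idx <- base + d1 * s1 + n[1] * (d2 * s2) + n[1] * n[2] * (d3 * s3)
    v <- v + w * values[idx]
  }
  v[outside] <- 0
  v
}

physical_extent <- function(geom) {
  lo <- geom$origin
  hi <- geom$origin + (geom$shape - 1) * geom$spacing
  list(lo = lo, hi = hi)
}

#' Resample a dose grid onto a new geometry
#'
#' Trilinear interpolation of the dose onto the voxel centers of
#' `target_geometry`; target voxels falling outside the source voxel-center
#' extent are set to 0. Used to bring accumulated doses onto the EBRT CT
#' pixel grid.
#'
#' @param dose a [dose_grid()].
#' @param target_geometry a [grid_geometry()].
#' @return A [dose_grid()] on `target_geometry` (frame label preserved).
#' @export
resample_to_grid <- function(dose, target_geometry) {
  stopifnot(inherits(dose, "dose_grid"),
            inherits(target_geometry, "grid_geometry"))
  src <- physical_extent(dose$geometry)
  tgt <- physical_extent(target_geometry)
  if (any(tgt$hi < src$lo) || any(tgt$lo > src$hi)) {
    stop("disjoint physical extents: target grid does not overlap the source",
         call. = FALSE)
  }
  pts <- voxel_centers(target_geometry)
  vals <- sample_trilinear(dose$values, dose$geometry, pts)
  dose_grid(array(vals, target_geometry$shape), target_geometry,
            frame_id = dose$frame_id)
}

#' Deformation vector field
#'
#' Pull-back displacement vectors in millimetres defined on the reference
#' (EBRT) grid: warping samples the source image at
#' `center(voxel) + displacement(voxel)`. This is the explicit input contract
#' standing in for the output of an external deformable image registration.
#'
#' @param displacements 4-D numeric array of dim `c(shape, 3)`, mm.
#' @param geometry the reference [grid_geometry()].
#' @return An object of class `deformation_field`.
#' @export
deformation_field <- function(displacements, geometry) {
  stopifnot(inherits(geometry, "grid_geometry"))
  dm <- dim(displacements)
  if (length(dm) != 4L || dm[4] != 3L ||
      !identical(as.integer(dm[1:3]), geometry$shape)) {
    stop("`displacements` must have dim c(shape, 3) matching the geometry",
         call. = FALSE)
  }
  if (any(!is.finite(displacements))) {
    stop("displacement components must all be finite", call. = FALSE)
  }
  structure(list(displacements = displacements, geometry = geometry),
            class = "deformation_field")
}

#' Warp a dose grid with a deformation field
#'
#' Produces the dose on the reference frame of the field:
#' `out[v] = trilinear sample of dose at center(v) + displacement(v)`.
#' Samples falling outside the source extent are 0. With a zero field and a
#' shared geometry this is the identity.
#'
#' @param dose the source (e.g. BT) [dose_grid()].
#' @param field a [deformation_field()] on the reference geometry.
#' @param frame_id frame label of the output; defaults to the dose's label.
#' @return A [dose_grid()] on the field's reference geometry.
#' @export
warp_dose <- function(dose, field, frame_id = dose$frame_id) {
  stopifnot(inherits(dose, "dose_grid"), inherits(field, "deformation_field"))
  geom <- field$geometry
  pts <- voxel_centers(geom) + matrix(field$displacements, ncol = 3)
  vals <- sample_trilinear(dose$values, dose$geometry, pts)
  dose_grid(array(vals, geom$shape), geom, frame_id = frame_id)
}
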