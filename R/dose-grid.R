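#' Regular 3-D grid geometry
#'
#' A grid geometry records the voxel lattice shared by dose grids, images,
#' masks and deformation fields: array shape, voxel spacing and the physical
#' position of the first voxel center. Physical coordinates follow the
#' voxel-center convention: `coord = origin + index * spacing` with 0-based
#' indices, all distances in millimetres.
#'
#' @param shape integer vector of length 3, voxels per axis.
#' @param spacing numeric vector of length 3, voxel spacing in mm (all > 0).
#' @param origin numeric vector of length 3, physical position (mm) of the
#'   center of voxel (0,0,0).
#' @return An object of class `grid_geometry`.
#' @export
grid_geometry <- function(shape, spacing, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(shape) != 3L || any(shape < 1L)) {
    stop("`shape` must be three positive integers", call. = FALSE)
  }
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three positive finite values (mm)", call. = FALSE)
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be three finite values (mm)", call. = FALSE)
  }
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("<grid_geometry> %s voxels, spacing (%s) mm, origin (%s) mm\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' @rdname grid_geometry
#' @param x object to extract a geometry from.
#' @export
geometry_of <- function(x) {
  if (inherits(x, "grid_geometry")) return(x)
  g <- attr(x, "geometry", exact = TRUE)
  if (!is.null(g)) return(g)
  if (is.list(x) && !is.null(x$geometry)) return(x$geometry)
  stop("cannot determine the grid geometry of this object", call. = FALSE)
}

#' @rdname grid_geometry
#' @param a,b objects carrying grid geometries.
#' @param tol numeric comparison tolerance.
#' @export
same_geometry <- function(a, b, tol = 1e-6) {
  ga <- geometry_of(a); gb <- geometry_of(b)
  identical(ga$shape, gb$shape) &&
    all(abs(ga$spacing - gb$spacing) <= tol) &&
    all(abs(ga$origin - gb$origin) <= tol)
}

stop_geometry_mismatch <- function(what = "inputs") {
  stop(sprintf("geometry mismatch: %s must share one grid geometry", what),
       call. = FALSE)
}

#' Physical voxel-center coordinates of a geometry axis
#' @noRd
axis_coords <- function(geom, axis) {
  geom$origin[axis] + (seq_len(geom$shape[axis]) - 1) * geom$spacing[axis]
}

#' All voxel-center coordinates as an n x 3 matrix (column-major voxel order)
#' @noRd
voxel_centers <- function(geom) {
  cx <- axis_coords(geom, 1); cy <- axis_coords(geom, 2); cz <- axis_coords(geom, 3)
  n <- geom$shape
  cbind(rep(cx, times = n[2] * n[3]),
        rep(rep(cy, each = n[1]), times = n[3]),
        rep(cz, each = n[1] * n[2]))
}

#' Volume of one voxel in cubic centimetres
#' @noRd
voxel_volume_cc <- function(geom) prod(geom$spacing) / 1000

#' Dose grid
#'
#' A `dose_grid` holds a 3-D scalar field of absorbed or EQD2 dose in Gy on a
#' regular grid, together with its geometry and a frame label identifying the
#' reference image the grid lives on. Values must be finite and non-negative;
#' negative inputs are rejected rather than clamped so that corrupt files
#' surface early.
#'
#' @param values 3-D numeric array of dose values in Gy.
#' @param spacing,origin grid geometry (see [grid_geometry()]); alternatively
#'   pass a `grid_geometry` as `spacing`.
#' @param frame_id text label of the reference frame (e.g. `"ebrt_ct"`).
#' @return An object of class `dose_grid`.
#' @examples
#' g <- dose_grid(array(2, c(4, 4, 4)), spacing = c(2, 2, 2))
#' max(g$values)
#' @export
dose_grid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      frame_id = "ref") {
  if (inherits(spacing, "grid_geometry")) {
    geom <- spacing
  } else {
    geom <- grid_geometry(dim(values), spacing, origin)
  }
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3-D array", call. = FALSE)
  }
  if (!identical(as.integer(dim(values)), geom$shape)) {
    stop("`values` dimensions do not match the geometry shape", call. = FALSE)
  }
  storage.mode(values) <- "double"
  if (any(!is.finite(values))) {
    stop("dose values must all be finite", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("dose values must be non-negative", call. = FALSE)
  }
  structure(list(values = values, geometry = geom,
                 frame_id = as.character(frame_id)),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> frame '%s', %s voxels, dose %.2f-%.2f Gy\n",
              x$frame_id, paste(x$geometry$shape, collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Replace the values of a dose grid, keeping geometry and frame
#' @noRd
with_values <- function(grid, values) {
  grid$values <- values
  grid
}

#' Uniform dose grid helper
#'
#' @param value dose in Gy assigned to every voxel.
#' @param shape,spacing,origin,frame_id grid definition.
#' @export
uniform_dose_grid <- function(value, shape = c(8, 8, 8), spacing = c(2, 2, 2),
                              origin = c(0, 0, 0), frame_id = "ref") {
  dose_grid(array(value, shape), spacing, origin, frame_id)
}
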