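#' Structure set
#'
#' Named binary masks (body, PTV, organs at risk) sharing one grid geometry.
#' Every non-body mask must be a subset of the body mask; the body mask must
#' be present for label maps and distance-to-target maps to be well defined.
#'
#' @param masks named list of 3-D logical arrays.
#' @param geometry the shared [grid_geometry()].
#' @param check_subsets verify the subset-of-body invariant (default TRUE).
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(masks, geometry, check_subsets = TRUE) {
  stopifnot(inherits(geometry, "grid_geometry"))
  if (!is.list(masks) || is.null(names(masks)) || any(names(masks) == "")) {
    stop("`masks` must be a named list of logical arrays", call. = FALSE)
  }
  masks <- lapply(masks, function(m) {
    if (!identical(as.integer(dim(m)), geometry$shape)) {
      stop_geometry_mismatch("structure masks")
    }
    storage.mode(m) <- "logical"
    m
  })
  if (check_subsets && "body" %in% names(masks)) {
    body <- masks[["body"]]
    for (nm in setdiff(names(masks), "body")) {
      if (any(masks[[nm]] & !body)) {
        stop(sprintf("structure '%s' is not contained in the body mask", nm),
             call. = FALSE)
      }
    }
  }
  structure(list(masks = masks, geometry = geometry), class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  vox <- vapply(x$masks, sum, numeric(1))
  cat(sprintf("<structure_set> %s voxels: %s\n",
              paste(x$geometry$shape, collapse = "x"),
              paste(sprintf("%s (%d)", names(vox), as.integer(vox)),
                    collapse = ", ")))
  invisible(x)
}

get_mask <- function(structures, name) {
  m <- structures$masks[[name]]
  if (is.null(m)) {
    stop(sprintf("structure '%s' not found in the structure set", name),
         call. = FALSE)
  }
  m
}

#' Default power-of-two base labels for a structure set
#'
#' Body background is reserved label 1 and the exterior 0, so structure base
#' labels start at 2 and double per structure (in the set's name order,
#' body excluded). Powers of two make every summed overlap value unique and
#' decodable.
#'
#' @param structures a [structure_set()] or character vector of names.
#' @return named integer vector of base labels.
#' @export
default_label_table <- function(structures) {
  nms <- if (inherits(structures, "structure_set")) names(structures$masks)
         else as.character(structures)
  nms <- setdiff(nms, "body")
  stats::setNames(as.integer(2^(seq_along(nms))), nms)
}

#' Build the unique-label structure map
#'
#' Every target and organ-at-risk voxel is assigned the structure's base
#' label; voxels lying in several structures get the sum of the base labels,
#' which is unique for power-of-two tables. Remaining body voxels are 1 and
#' voxels outside the body 0.
#'
#' @param structures a [structure_set()] containing `body`.
#' @param label_table named integer base labels (>= 2); defaults to
#'   [default_label_table()]. Custom tables are checked for sum collisions
#'   over the overlaps actually present.
#' @return An object of class `label_map`: list of `values` (integer array),
#'   `label_table` and `geometry`.
#' @export
build_structure_label_map <- function(structures, label_table = NULL) {
  stopifnot(inherits(structures, "structure_set"))
  body <- get_mask(structures, "body")
  if (is.null(label_table)) label_table <- default_label_table(structures)
  if (any(label_table < 2) || anyDuplicated(label_table)) {
    stop("base labels must be distinct integers >= 2", call. = FALSE)
  }
  nms <- names(label_table)
  missing <- setdiff(nms, names(structures$masks))
  if (length(missing)) {
    stop(sprintf("label table names not in the structure set: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }

  vals <- array(0, dim = structures$geometry$shape)
  combo <- array(0, dim = structures$geometry$shape)  # power-of-two signature
  for (i in seq_along(nms)) {
    m <- structures$masks[[nms[i]]]
    vals <- vals + as.numeric(label_table[i]) * m
    combo <- combo + 2^(i - 1) * m
  }
  # A custom table collides if two distinct structure combinations that both
  # occur on this grid share one summed value.
  obs <- unique(cbind(as.vector(vals), as.vector(combo)))
  if (anyDuplicated(obs[, 1])) {
    stop("label collision: distinct structure overlaps share a summed label",
         call. = FALSE)
  }
  vals[vals == 0 & body] <- 1
  vals[!body] <- 0
  structure(list(values = vals, label_table = label_table,
                 geometry = structures$geometry),
            class = "label_map")
}

#' Decode label-map values back to structure memberships
#'
#' For power-of-two label tables the summed voxel value identifies the exact
#' set of containing structures by binary decomposition.
#'
#' @param values integer vector (or scalar) of label-map values.
#' @param label_table the named base-label table used to build the map.
#' @return A list (one element per value) of character vectors of structure
#'   names; `character(0)` for body-only (1) and exterior (0) voxels.
#' @export
decode_label <- function(values, label_table) {
  if (any(bitwAnd(label_table, label_table - 1L) != 0L)) {
    stop("decoding requires a power-of-two label table", call. = FALSE)
  }
  lapply(as.integer(values), function(v) {
    if (v <= 1L) return(character(0))
    names(label_table)[bitwAnd(v, as.integer(label_table)) != 0L]
  })
}

#' Boundary voxels of a mask (6-neighbourhood)
#' @noRd
mask_boundary <- function(mask) {
  interior <- mask
  n <- dim(mask)
  shift_and <- function(m, axis, by) {
    out <- array(FALSE, dim = dim(m))
    idx_src <- lapply(dim(m), seq_len)
    idx_dst <- idx_src
    rng <- seq_len(n[axis] - abs(by))
    idx_src[[axis]] <- rng + max(0, by)
    idx_dst[[axis]] <- rng + max(0, -by)
    out <- array(FALSE, dim = dim(m))
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (axis in 1:3) for (by in c(-1L, 1L)) {
    if (n[axis] > 1) {
      shifted <- shift_and(mask, axis, by)
      # voxels at the array edge count as boundary: shifted is FALSE there
      interior <- interior & shifted
    } else {
      interior[] <- FALSE
    }
  }
  mask & !interior
}

#' Minimum physical distances from points to a set of mask voxels
#'
#' Chunked exact computation via the expansion
#' `|a-b|^2 = |a|^2 + |b|^2 - 2 a.b`, BLAS-backed.
#' @noRd
min_dist_to_mask <- function(pts, ref_pts, chunk = 4096L) {
  rb2 <- rowSums(ref_pts^2)
  out <- numeric(nrow(pts))
  start <- 1L
  while (start <= nrow(pts)) {
    end <- min(start + chunk - 1L, nrow(pts))
    a <- pts[start:end, , drop = FALSE]
    d2 <- outer(rowSums(a^2), rb2, "+") - 2 * tcrossprod(a, ref_pts)
    out[start:end] <- sqrt(pmax(apply(d2, 1, min), 0))
    start <- end + 1L
  }
  out
}

#' Distance-to-target (DTT) map
#'
#' For every normal-tissue voxel inside the body and outside the PTV, the
#' minimum Euclidean distance in millimetres (anisotropic spacing respected)
#' to the nearest PTV voxel center; voxels inside the PTV and outside the
#' body are 0. Only the PTV's 6-neighbourhood boundary voxels need to be
#' searched: the nearest PTV voxel to an external point is always one of
#' them.
#'
#' @param structures a [structure_set()] with `body` and `ptv` masks.
#' @return An object of class `dtt_map`: list of `values` (mm) and `geometry`.
#' @export
compute_dtt_map <- function(structures) {
  stopifnot(inherits(structures, "structure_set"))
  body <- get_mask(structures, "body")
  ptv <- get_mask(structures, "ptv")
  if (!any(ptv)) stop("PTV mask is empty", call. = FALSE)
  geom <- structures$geometry

  vals <- array(0, dim = geom$shape)
  query <- body & !ptv
  if (any(query)) {
    centers <- voxel_centers(geom)
    ref <- centers[as.vector(mask_boundary(ptv)), , drop = FALSE]
    vals[query] <- min_dist_to_mask(centers[as.vector(query), , drop = FALSE],
                                    ref)
  }
  structure(list(values = vals, geometry = geom), class = "dtt_map")
}

#' Override CT numbers inside named structures
#'
#' Sets the image intensity inside each listed mask to a fixed value, in the
#' listed order (the last listed structure wins in overlaps). Used to give
#' the registration contours a consistent intensity on both image sets
#' before deformable registration.
#'
#' @param image 3-D numeric array (HU).
#' @param structures a [structure_set()] on the image grid.
#' @param values named numeric vector, structure name to intensity; may be
#'   empty (image returned unchanged).
#' @return The overridden image array.
#' @export
override_ct_numbers <- function(image, structures, values) {
  stopifnot(inherits(structures, "structure_set"))
  if (!identical(as.integer(dim(image)), structures$geometry$shape)) {
    stop_geometry_mismatch("image and structure set")
  }
  for (nm in names(values)) {
    image[get_mask(structures, nm)] <- values[[nm]]
  }
  image
}

#' Isodose volume
#'
#' Binary mask of voxels receiving at least `level` Gy (inclusive threshold).
#'
#' @param dose a [dose_grid()].
#' @param level isodose level in Gy (> 0).
#' @return 3-D logical array.
#' @export
isodose_volume <- function(dose, level) {
  stopifnot(inherits(dose, "dose_grid"))
  if (!is.finite(level) || level <= 0) {
    stop("`level` must be a positive dose in Gy", call. = FALSE)
  }
  dose$values >= level
}

#' Overlap of a predicted isodose volume with an organ at risk
#'
#' Intersection of `isodose_volume(predicted, level)` with the OAR mask,
#' intended as an avoidance contour when redesigning the EBRT plan: hotspots
#' are steered out of the region where the predicted accumulated dose already
#' exceeds the level inside the organ.
#'
#' @param predicted predicted accumulated [dose_grid()].
#' @param level isodose level in Gy (default 70, the clinical choice for
#'   bladder/rectum avoidance).
#' @param oar_mask 3-D logical array on the same geometry.
#' @return 3-D logical array.
#' @export
overlap_contour <- function(predicted, level, oar_mask) {
  stopifnot(inherits(predicted, "dose_grid"))
  if (!identical(as.integer(dim(oar_mask)), predicted$geometry$shape)) {
    stop_geometry_mismatch("predicted dose and OAR mask")
  }
  isodose_volume(predicted, level) & oar_mask
}
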