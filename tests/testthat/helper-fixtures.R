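# Shared fixtures: everything is generated in code at test time.

# A small phantom specification for fast pipeline tests: same anatomy
# layout as the default, scaled to a 16x16x8 grid at 8x8x8 mm.
tiny_spec <- function(...) {
  phantom_spec(shape = c(16, 16, 8), spacing = c(8, 8, 8),
               body_radii = c(55, 50, 26),
               uv_radii = c(12, 13, 14),
               bladder_center = c(0, -22, 0), bladder_radii = c(8, 8, 10),
               rectum_center = c(0, 22, 0), rectum_radii = c(6, 6, 12),
               ptv_margin = 8, center_jitter = 2,
               bt_norm_radius = 20, bt_dwell_step = 8,
               dvf_coarse_shape = c(4, 4, 3), ...)
}

# A hand-built structure set on an anisotropic grid: rectangular body with
# a small box PTV and one OAR box overlapping the PTV.
box_structures <- function(shape = c(10, 9, 6), spacing = c(2, 3, 5)) {
  geom <- grid_geometry(shape, spacing)
  body <- array(FALSE, shape); body[2:9, 2:8, 2:5] <- TRUE
  ptv <- array(FALSE, shape); ptv[4:6, 4:6, 3:4] <- TRUE
  oar <- array(FALSE, shape); oar[6:8, 5:7, 3:4] <- TRUE
  structure_set(list(body = body, ptv = ptv, oar = oar), geom)
}

# Exhaustive DTT oracle: minimum distance from every body voxel outside the
# PTV to every PTV voxel center (physical mm).
dtt_oracle <- function(structures) {
  geom <- structures$geometry
  centers <- rtaccum:::voxel_centers(geom)
  body <- as.vector(structures$masks$body)
  ptv <- as.vector(structures$masks$ptv)
  vals <- numeric(length(body))
  ptv_pts <- centers[ptv, , drop = FALSE]
  for (i in which(body & !ptv)) {
    d2 <- (ptv_pts[, 1] - centers[i, 1])^2 +
          (ptv_pts[, 2] - centers[i, 2])^2 +
          (ptv_pts[, 3] - centers[i, 3])^2
    vals[i] <- sqrt(min(d2))
  }
  array(vals, geom$shape)
}

# Random structure set (body ball + random blobs) for property tests.
random_structures <- function(seed, shape = c(12, 12, 8),
                              spacing = c(3, 3, 4), n_organs = 3) {
  set.seed(seed)
  geom <- grid_geometry(shape, spacing)
  ctr <- rtaccum:::voxel_centers(geom)
  mid <- geom$origin + (shape - 1) * spacing / 2
  body_r <- min((shape - 1) * spacing) / 2
  body <- array(sqrt(rowSums(t(t(ctr) - mid)^2)) <= body_r, shape)
  masks <- list(body = body)
  nm <- c("ptv", paste0("organ", seq_len(max(0, n_organs - 1))))
  for (k in seq_len(n_organs)) {
    c0 <- mid + runif(3, -body_r / 3, body_r / 3)
    r0 <- runif(1, body_r / 4, body_r / 2)
    masks[[nm[k]]] <- array(sqrt(rowSums(t(t(ctr) - c0)^2)) <= r0, shape) & body
  }
  # ensure a non-empty PTV
  if (!any(masks$ptv)) masks$ptv <- body & array(seq_along(body) == which(body)[1], shape)
  structure_set(masks, geom)
}
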