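#' Separable Gaussian smoothing of a 3-D field
#'
#' Truncated (3 sigma) discrete Gaussian applied along each axis with
#' zero padding, spacing-aware. `sigma_mm = 0` returns the input unchanged.
#'
#' @param values 3-D numeric array.
#' @param geom `grid_geometry` of the array.
#' @param sigma_mm kernel standard deviation in mm.
#' @return smoothed array.
#' @noRd
gaussian_smooth3 <- function(values, geom, sigma_mm) {
  if (sigma_mm <= 0) return(values)
  d <- dim(values)
  for (axis in 1:3) {
    n <- d[axis]; sp <- geom$spacing[axis]
    half <- max(1L, ceiling(3 * sigma_mm / sp))
    k <- stats::dnorm(seq(-half, half) * sp, sd = sigma_mm)
    k <- k / sum(k)
    K <- matrix(0, n, n)
    for (off in -half:half) {
      i <- seq_len(n)
      keep <- i + off >= 1 & i + off <= n
      K[cbind(i[keep], i[keep] + off)] <-
        K[cbind(i[keep], i[keep] + off)] + k[off + half + 1]
    }
    perm <- c(axis, setdiff(1:3, axis))
    v <- aperm(values, perm)
    dv <- dim(v)
    v <- K %*% matrix(v, nrow = n)
    dim(v) <- dv
    values <- aperm(v, order(perm))
  }
  values
}

#' Synthetic pelvic phantom specification
#'
#' Defines the study conditions the synthetic cohort emulates: a pelvic body
#' with a bone rim, an anterior bladder, a posterior rectum, a central
#' uterus+vagina (U+V) region, and a PTV formed by expanding the U+V by a
#' margin. The accumulated EQD2 truth dose is the sum of an EBRT-like
#' plateau (prescription EQD2 times a Gaussian-smoothed PTV indicator) and a
#' BT-like central hotspot (inverse-square kernel from dwell points on the
#' central U+V axis, converted per fraction to EQD2, scaled by the fraction
#' count and capped). All lengths in mm, doses in Gy.
#'
#' @param shape,spacing,origin grid definition (defaults 64x64x24 voxels at
#'   4x4x5 mm).
#' @param body_radii body ellipsoid semi-axes.
#' @param bone_rim normalized-radius interval of the bony shell.
#' @param uv_center,uv_radii uterus+vagina ellipsoid (offsets from the body
#'   center).
#' @param bladder_center,bladder_radii anterior bladder ellipsoid.
#' @param rectum_center,rectum_radii posterior rectum ellipsoid.
#' @param ptv_margin PTV expansion margin around the U+V.
#' @param center_jitter,radius_jitter_frac per-case anatomical variation:
#'   uniform center shifts (+/- mm per axis) and relative radius scaling.
#' @param ebrt_dose,ebrt_fractions,alpha_beta_tumor EBRT prescription
#'   (45 Gy / 25 fx, alpha/beta 10 Gy).
#' @param penumbra_sigma Gaussian penumbra width of the EBRT plateau (mm).
#' @param bt_fraction_dose BT physical dose per fraction (Gy) at
#'   `bt_norm_radius` lateral from the dwell line; 0 disables the BT term.
#' @param bt_norm_radius normalization radius of the BT kernel (mm), chosen
#'   so the high-dose region reaches the anterior rectal / posterior bladder
#'   wall as in the clinical situation the redesign aid addresses.
#' @param bt_fractions number of BT fractions.
#' @param bt_dwell_step dwell-point spacing along the central axis (mm).
#' @param bt_dwell_span dwell line half-length as a fraction of the U+V
#'   z semi-axis.
#' @param bt_rmin inverse-square clamp radius (mm).
#' @param hotspot_cap ceiling of the BT EQD2 term (Gy).
#' @param noise_sigma CT Gaussian noise (HU).
#' @param dvf_amplitude,dvf_coarse_shape smooth random deformation field:
#'   per-component displacement s.d. (mm) on a coarse control grid,
#'   trilinearly upsampled.
#' @param max_retries anatomy re-jitter attempts before a geometry error.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 24), spacing = c(4, 4, 5),
                         origin = c(0, 0, 0),
                         body_radii = c(105, 90, 54),
                         bone_rim = c(0.9, 1.0),
                         uv_center = c(0, 0, 0), uv_radii = c(20, 22, 30),
                         bladder_center = c(0, -38, 0),
                         bladder_radii = c(24, 22, 26),
                         rectum_center = c(0, 30, 0),
                         rectum_radii = c(11, 12, 38),
                         ptv_margin = 15,
                         center_jitter = 4, radius_jitter_frac = 0.15,
                         ebrt_dose = 45, ebrt_fractions = 25,
                         alpha_beta_tumor = 10,
                         penumbra_sigma = 6,
                         bt_fraction_dose = 6, bt_norm_radius = 35,
                         bt_fractions = 4, bt_dwell_step = 5,
                         bt_dwell_span = 0.8, bt_rmin = 3,
                         hotspot_cap = 160,
                         noise_sigma = 20,
                         dvf_amplitude = 2, dvf_coarse_shape = c(6, 6, 4),
                         max_retries = 10) {
  spec <- as.list(environment())
  if (ebrt_dose <= 0 || ebrt_fractions < 1) {
    stop("EBRT prescription must be positive", call. = FALSE)
  }
  if (bt_fraction_dose < 0 || bt_fractions < 0) {
    stop("BT course parameters must be non-negative", call. = FALSE)
  }
  structure(spec, class = "phantom_spec")
}

ellipsoid_mask <- function(geom, center, radii) {
  cx <- axis_coords(geom, 1); cy <- axis_coords(geom, 2); cz <- axis_coords(geom, 3)
  n <- geom$shape
  r2 <- outer(outer(((cx - center[1]) / radii[1])^2,
                    ((cy - center[2]) / radii[2])^2, "+"),
              ((cz - center[3]) / radii[3])^2, "+")
  array(r2 <= 1, n)
}

ellipsoid_r2 <- function(geom, center, radii) {
  cx <- axis_coords(geom, 1); cy <- axis_coords(geom, 2); cz <- axis_coords(geom, 3)
  outer(outer(((cx - center[1]) / radii[1])^2,
              ((cy - center[2]) / radii[2])^2, "+"),
        ((cz - center[3]) / radii[3])^2, "+")
}

#' Generate one synthetic pelvic phantom case
#'
#' Deterministic given `spec` and `seed`: anatomy jitter, CT noise and the
#' deformation field are all drawn from a seeded RNG stream. Organs are
#' re-jittered (with derived seeds) up to `spec$max_retries` times if they do
#' not fit inside the body, then a geometry error is raised. The returned
#' case carries the separate EBRT and BT EQD2 dose components alongside
#' their sum, so accumulation identities can be verified.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed for this case.
#' @return An object of class `phantom_case`: fields `ct` (HU array),
#'   `structures` ([structure_set()]), `truth_dose`, `ebrt_dose`, `bt_dose`
#'   ([dose_grid()]s), `dvf` ([deformation_field()]), `seed`, `spec`.
#' @export
generate_phantom <- function(spec, seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  geom <- grid_geometry(spec$shape, spec$spacing, spec$origin)
  body_center <- spec$origin + (spec$shape - 1) * spec$spacing / 2

  for (attempt in 0:spec$max_retries) {
    try_seed <- (seed + attempt * 1000003) %% .Machine$integer.max
    set.seed(try_seed)
    jit <- function(center, radii) {
      list(center = body_center + center +
             stats::runif(3, -spec$center_jitter, spec$center_jitter),
           radii = radii * stats::runif(3, 1 - spec$radius_jitter_frac,
                                        1 + spec$radius_jitter_frac))
    }
    uv <- jit(spec$uv_center, spec$uv_radii)
    bl <- jit(spec$bladder_center, spec$bladder_radii)
    re <- jit(spec$rectum_center, spec$rectum_radii)

    body <- ellipsoid_mask(geom, body_center, spec$body_radii)
    uv_m <- ellipsoid_mask(geom, uv$center, uv$radii)
    bl_m <- ellipsoid_mask(geom, bl$center, bl$radii)
    re_m <- ellipsoid_mask(geom, re$center, re$radii)
    ptv_m <- ellipsoid_mask(geom, uv$center, uv$radii + spec$ptv_margin) & body

    fits <- !any(uv_m & !body) && !any(bl_m & !body) && !any(re_m & !body) &&
      any(uv_m) && any(bl_m) && any(re_m)
    if (fits) break
    if (attempt == spec$max_retries) {
      stop("organs do not fit inside the body after the allowed retries",
           call. = FALSE)
    }
  }

  structures <- structure_set(
    list(body = body, ptv = ptv_m, bladder = bl_m, rectum = re_m,
         uterus_vagina = uv_m), geom)

  # CT: tissue-class intensities plus Gaussian noise
  r2_body <- ellipsoid_r2(geom, body_center, spec$body_radii)
  ct <- array(-1000, geom$shape)
  ct[body] <- 40
  ct[body & r2_body >= spec$bone_rim[1]^2] <- 300
  ct <- override_ct_numbers(ct, structures,
                            c(uterus_vagina = 45, bladder = 10, rectum = -30))
  ct <- ct + array(stats::rnorm(prod(geom$shape), sd = spec$noise_sigma),
                   geom$shape)

  # EBRT term: prescription EQD2 x Gaussian-smoothed PTV indicator
  pres_eqd2 <- spec$ebrt_dose *
    (spec$ebrt_dose / spec$ebrt_fractions + spec$alpha_beta_tumor) /
    (2 + spec$alpha_beta_tumor)
  ebrt_vals <- pres_eqd2 *
    gaussian_smooth3(array(as.numeric(ptv_m), geom$shape), geom,
                     spec$penumbra_sigma)

  # BT term: inverse-square line-source surrogate on the central U+V axis,
  # converted per fraction to EQD2, scaled by the fraction count, capped
  bt_vals <- array(0, geom$shape)
  if (spec$bt_fraction_dose > 0 && spec$bt_fractions > 0) {
    half_len <- spec$bt_dwell_span * uv$radii[3]
    zs <- seq(uv$center[3] - half_len, uv$center[3] + half_len,
              by = spec$bt_dwell_step)
    dwells <- cbind(uv$center[1], uv$center[2], zs)
    kern <- function(pts) {
      out <- numeric(nrow(pts))
      for (i in seq_len(nrow(dwells))) {
        r2 <- (pts[, 1] - dwells[i, 1])^2 + (pts[, 2] - dwells[i, 2])^2 +
              (pts[, 3] - dwells[i, 3])^2
        out <- out + 1 / pmax(r2, spec$bt_rmin^2)
      }
      out
    }
    k_ref <- kern(matrix(uv$center + c(spec$bt_norm_radius, 0, 0), nrow = 1))
    phys_fx <- spec$bt_fraction_dose * kern(voxel_centers(geom)) / k_ref
    ab <- spec$alpha_beta_tumor
    eqd2_fx <- phys_fx * (phys_fx + ab) / (2 + ab)
    bt_vals <- array(pmin(spec$bt_fractions * eqd2_fx, spec$hotspot_cap),
                     geom$shape)
  }

  frame <- sprintf("phantom_%d", seed)
  ebrt <- dose_grid(ebrt_vals, geom, frame_id = frame)
  bt <- dose_grid(bt_vals, geom, frame_id = frame)

  # small smooth random deformation field from a coarse control grid
  cs <- spec$dvf_coarse_shape
  coarse_geom <- grid_geometry(cs, (geom$shape - 1) * geom$spacing / (cs - 1),
                               geom$origin)
  ctr <- voxel_centers(geom)
  disp <- vapply(1:3, function(comp) {
    coarse <- array(stats::rnorm(prod(cs), sd = spec$dvf_amplitude), cs)
    sample_trilinear(coarse, coarse_geom, ctr)
  }, numeric(prod(geom$shape)))
  dvf <- deformation_field(array(disp, c(geom$shape, 3)), geom)

  structure(list(ct = ct, structures = structures,
                 truth_dose = accumulate_dose(ebrt, bt),
                 ebrt_dose = ebrt, bt_dose = bt, dvf = dvf,
                 seed = seed, spec = spec),
            class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> seed %d, %s voxels, truth dose max %.1f Gy\n",
              x$seed, paste(x$structures$geometry$shape, collapse = "x"),
              max(x$truth_dose$values)))
  invisible(x)
}

#' Generate a seeded synthetic cohort
#'
#' Derives one child seed per patient from the root seed and generates that
#' many phantoms; anatomies differ by the spec's jitter ranges but the whole
#' cohort is byte-reproducible from `root_seed`.
#'
#' @param spec a [phantom_spec()].
#' @param n_patients cohort size (>= 1).
#' @param root_seed integer root seed.
#' @return list with `cases` (list of [generate_phantom()] results) and
#'   `manifest` (tibble: patient, seed, structure volumes in cc).
#' @export
generate_cohort <- function(spec, n_patients, root_seed) {
  if (n_patients < 1) stop("`n_patients` must be >= 1", call. = FALSE)
  set.seed(root_seed)
  seeds <- sample.int(.Machine$integer.max - 1, n_patients)
  cases <- lapply(seeds, function(s) generate_phantom(spec, s))
  vox_cc <- voxel_volume_cc(cases[[1]]$structures$geometry)
  manifest <- do.call(rbind, lapply(seq_along(cases), function(i) {
    vols <- vapply(cases[[i]]$structures$masks, sum, numeric(1)) * vox_cc
    tibble::tibble(patient = sprintf("P%02d", i), seed = seeds[i],
                   body_cc = vols[["body"]], ptv_cc = vols[["ptv"]],
                   bladder_cc = vols[["bladder"]], rectum_cc = vols[["rectum"]],
                   uv_cc = vols[["uterus_vagina"]])
  }))
  list(cases = cases, manifest = manifest)
}

#' Analytic stand-in for EBRT plan redesign
#'
#' Reduces the EBRT component of a phantom's accumulated dose by a given
#' fraction inside an avoidance mask, with a smooth Gaussian falloff at the
#' mask border, and returns the re-accumulated dose. Dose is never increased
#' anywhere and is unchanged outside the (falloff-dilated) avoidance region.
#' Used to emulate steering EBRT hotspots out of the overlap between a
#' predicted high-isodose volume and an organ at risk.
#'
#' @param case a [generate_phantom()] case.
#' @param avoid_mask 3-D logical array on the case geometry (e.g. from
#'   [overlap_contour()]).
#' @param reduction fractional EBRT dose reduction in (0, 1).
#' @param falloff_sigma Gaussian falloff width at the mask border (mm).
#'   EBRT plan changes are not voxel-local, so the default lets the
#'   reduction taper over a few voxel widths beyond the contour, as a plan
#'   re-optimization does.
#' @return The redesigned accumulated [dose_grid()].
#' @export
simulate_redesign <- function(case, avoid_mask, reduction, falloff_sigma = 16) {
  stopifnot(inherits(case, "phantom_case"))
  geom <- case$structures$geometry
  if (!identical(as.integer(dim(avoid_mask)), geom$shape)) {
    stop_geometry_mismatch("avoid mask and phantom")
  }
  if (!is.finite(reduction) || reduction <= 0 || reduction >= 1) {
    stop("`reduction` must lie strictly between 0 and 1", call. = FALSE)
  }
  w <- gaussian_smooth3(array(as.numeric(avoid_mask), geom$shape), geom,
                        falloff_sigma)
  if (max(w) > 0) w <- w / max(w)
  new_ebrt <- with_values(case$ebrt_dose,
                          case$ebrt_dose$values * (1 - reduction * w))
  accumulate_dose(new_ebrt, case$bt_dose)
}
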