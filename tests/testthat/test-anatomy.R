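test_that("structure sets enforce shared geometry and body containment", {
  geom <- grid_geometry(c(4, 4, 4), c(1, 1, 1))
  body <- array(TRUE, c(4, 4, 4))
  expect_error(structure_set(list(body = body,
                                  ptv = array(TRUE, c(4, 4, 5))), geom),
               "geometry")
  body2 <- array(FALSE, c(4, 4, 4)); body2[2:3, 2:3, 2:3] <- TRUE
  stray <- array(FALSE, c(4, 4, 4)); stray[1, 1, 1] <- TRUE
  expect_error(structure_set(list(body = body2, ptv = stray), geom),
               "not contained")
})

test_that("label map follows the sum rule with reserved 0/1 labels", {
  s <- box_structures()
  lm <- build_structure_label_map(s)
  tab <- lm$label_table
  expect_identical(unname(tab), c(2L, 4L))  # ptv, oar
  expect_equal(lm$values[1, 1, 1], 0)                      # outside body
  expect_equal(lm$values[2, 2, 2], 1)                      # body only
  expect_equal(lm$values[5, 5, 3], 2)                      # ptv only
  expect_equal(lm$values[6, 5, 3], 6)                      # ptv + oar overlap
  expect_equal(lm$values[8, 7, 3], 4)                      # oar only
})

test_that("label maps decode back to the exact structure combination", {
  for (seed in 1:5) {
    s <- random_structures(seed, n_organs = 4)
    lm <- build_structure_label_map(s)
    tab <- lm$label_table
    idx <- sample(length(lm$values), 200)
    membership <- vapply(names(tab), function(nm) s$masks[[nm]][idx],
                         logical(200))
    decoded <- decode_label(lm$values[idx], tab)
    for (j in seq_along(idx)) {
      expect_setequal(decoded[[j]], names(tab)[membership[j, ]])
    }
  }
})

test_that("colliding custom label tables are rejected", {
  s <- box_structures()  # ptv and oar overlap on this grid
  # ptv + oar sum = 5 collides with a third label that also occurs... use
  # a direct collision: two structures with labels 3 and 5 overlapping (8)
  # while a third structure labelled 8 exists on the same grid.
  geom <- s$geometry
  third <- array(FALSE, geom$shape); third[2, 2, 2] <- TRUE
  s2 <- structure_set(c(s$masks, list(extra = third)), geom)
  expect_error(
    build_structure_label_map(s2, c(ptv = 3L, oar = 5L, extra = 8L)),
    "collision")
  # non-colliding custom table is accepted
  lm <- build_structure_label_map(s2, c(ptv = 3L, oar = 5L, extra = 9L))
  expect_equal(max(lm$values), 9)  # extra alone; the ptv+oar overlap sums to 8
})

test_that("DTT equals the exhaustive oracle on anisotropic grids", {
  for (seed in 1:4) {
    s <- random_structures(seed)
    dtt <- compute_dtt_map(s)
    expect_equal(dtt$values, dtt_oracle(s), tolerance = 1e-9)
  }
})

test_that("DTT is zero inside the PTV and outside the body, positive elsewhere", {
  s <- box_structures()
  dtt <- compute_dtt_map(s)
  expect_true(all(dtt$values[s$masks$ptv] == 0))
  expect_true(all(dtt$values[!s$masks$body] == 0))
  off <- s$masks$body & !s$masks$ptv
  expect_true(all(dtt$values[off] > 0))
  # face-adjacent voxel at spacing 2 mm along x
  expect_equal(dtt$values[3, 5, 3], 2)
})

test_that("DTT is 1-Lipschitz in physical distance", {
  s <- random_structures(9)
  dtt <- compute_dtt_map(s)
  centers <- rtaccum:::voxel_centers(s$geometry)
  sel <- which(s$masks$body & !s$masks$ptv)
  set.seed(1)
  u <- sample(sel, 150, replace = TRUE)
  v <- sample(sel, 150, replace = TRUE)
  gap <- sqrt(rowSums((centers[u, ] - centers[v, ])^2))
  expect_true(all(abs(dtt$values[u] - dtt$values[v]) <= gap + 1e-9))
})

test_that("empty PTV raises an invalid-structure error", {
  geom <- grid_geometry(c(4, 4, 4), c(1, 1, 1))
  body <- array(TRUE, c(4, 4, 4))
  s <- structure_set(list(body = body, ptv = array(FALSE, c(4, 4, 4))), geom)
  expect_error(compute_dtt_map(s), "empty")
})

test_that("CT override honours listed order and leaves the rest unchanged", {
  s <- box_structures()
  img <- array(50, s$geometry$shape)
  expect_identical(override_ct_numbers(img, s, c()), img)
  out <- override_ct_numbers(img, s, c(ptv = 100, oar = -20))
  expect_true(all(out[s$masks$oar] == -20))                 # last wins
  expect_true(all(out[s$masks$ptv & !s$masks$oar] == 100))
  expect_true(all(out[!s$masks$ptv & !s$masks$oar] == 50))
  expect_error(override_ct_numbers(img, s, c(nosuch = 1)), "not found")
})

test_that("isodose volumes threshold inclusively and nest monotonically", {
  # ramp along x: 0..100 Gy over 11 voxels
  vals <- array(rep(seq(0, 100, by = 10), times = 9), c(11, 3, 3))
  g <- dose_grid(vals)
  m50 <- isodose_volume(g, 50)
  expect_equal(sum(m50), 6 * 9)   # voxels 50..100 inclusive
  expect_true(all(isodose_volume(g, 80) <= m50))
  levels <- sort(runif(8, 1, 120))
  masks <- lapply(levels, function(L) isodose_volume(g, L))
  for (i in seq_len(7)) expect_true(all(masks[[i + 1]] <= masks[[i]]))
  expect_equal(sum(isodose_volume(g, 1000)), 0)
  expect_error(isodose_volume(g, 0), "positive")
})

test_that("overlap contours equal the element-wise AND oracle", {
  case <- generate_phantom(tiny_spec(), 21)
  oar <- case$structures$masks$rectum
  ov <- overlap_contour(case$truth_dose, 70, oar)
  oracle <- array(FALSE, dim(oar))
  for (i in seq_along(oar)) {
    oracle[i] <- oar[i] && case$truth_dose$values[i] >= 70
  }
  expect_identical(ov, oracle)
  # OAR fully below the level: empty overlap
  expect_equal(sum(overlap_contour(case$truth_dose, 1e5, oar)), 0)
  # OAR entirely inside the isodose volume: the OAR mask itself
  hot <- uniform_dose_grid(80, shape = dim(oar), spacing = c(8, 8, 8))
  expect_identical(overlap_contour(hot, 70, oar), oar)
  expect_error(overlap_contour(case$truth_dose, 70, oar[1:2]), "geometry")
})
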