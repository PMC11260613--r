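norm_fix <- dose_normalization(label_max = 30, dtt_max = 100, dose_ref = 76.25)

test_that("sample assembly slices the volumes into 3-channel stacks", {
  case <- generate_phantom(tiny_spec(), 2)
  lm <- build_structure_label_map(case$structures)
  dtt <- compute_dtt_map(case$structures)
  s <- assemble_samples(case$ct, lm, dtt, dose = case$truth_dose, norm = norm_fix)
  expect_equal(dim(s$x), c(16, 16, 3, 8))
  expect_equal(dim(s$y), c(16, 16, 1, 8))
  expect_true(all(is.finite(s$x)))
  expect_true(all(s$x[, , 1, ] >= 0 & s$x[, , 1, ] <= 1))
  # slice k of channel 2 is the normalized label map slice k
  expect_equal(s$x[, , 2, 3], lm$values[, , 3] / 30)
})

test_that("dose normalization round-trips and zero targets stay zero", {
  set.seed(9)
  v <- array(runif(64, 0, 160), c(4, 4, 4))
  expect_equal(denormalize_dose(normalize_dose(v, norm_fix), norm_fix), v,
               tolerance = 1e-14)
  case <- generate_phantom(tiny_spec(bt_fraction_dose = 0, ebrt_dose = 1e-9), 2)
  s <- assemble_samples(case$ct, build_structure_label_map(case$structures),
                        compute_dtt_map(case$structures),
                        dose = case$truth_dose, norm = norm_fix)
  expect_lt(max(abs(s$y)), 1e-9)
})

test_that("geometry mismatches in channel assembly are rejected", {
  case <- generate_phantom(tiny_spec(), 2)
  lm <- build_structure_label_map(case$structures)
  dtt <- compute_dtt_map(case$structures)
  bad_ct <- array(0, c(16, 16, 9))
  expect_error(assemble_samples(bad_ct, lm, dtt, norm = norm_fix), "geometry")
})

test_that("model building is deterministic and presets order by capacity", {
  m1 <- build_model("reduced", seed = 5)
  m2 <- build_model("reduced", seed = 5)
  expect_identical(m1$params, m2$params)
  m3 <- build_model("reduced", seed = 6)
  expect_false(identical(m1$params, m3$params))
  full <- build_model("full", seed = 5)
  expect_gt(n_parameters(full), n_parameters(m1))
})

test_that("the network is fully convolutional with shape checking", {
  m <- build_model("reduced", seed = 1)
  x <- array(0, c(32, 24, 3, 2))
  y <- rtaccum:::net_forward(m, x)$y
  expect_equal(dim(y), c(32, 24, 1, 2))
  expect_true(all(is.finite(y)))
  full <- build_model("full", seed = 1)
  y2 <- rtaccum:::net_forward(full, array(0, c(32, 32, 3, 1)))$y
  expect_equal(dim(y2), c(32, 32, 1, 1))
  expect_error(rtaccum:::net_forward(m, array(0, c(30, 30, 3, 1))),
               "divisible")
})

test_that("training is deterministic and reduces the loss", {
  set.seed(33)
  n <- 24
  x <- array(runif(16 * 16 * 3 * n), c(16, 16, 3, n))
  # target: a smooth deterministic function of the channels
  y <- array(0, c(16, 16, 1, n))
  y[, , 1, ] <- 0.3 * x[, , 1, ] + 0.5 * x[, , 3, ]
  m <- build_model("reduced", seed = 2)
  t1 <- train_model(m, x, y, epochs = 3, batch_size = 8, seed = 4)
  t2 <- train_model(m, x, y, epochs = 3, batch_size = 8, seed = 4)
  expect_identical(t1$loss, t2$loss)
  expect_identical(t1$params, t2$params)
  expect_lt(tail(t1$loss, 1), t1$loss[1])
})

test_that("a constant-dose cohort is learned to near-zero error", {
  set.seed(44)
  n <- 20
  x <- array(runif(16 * 16 * 3 * n), c(16, 16, 3, n))
  y <- array(0.5, c(16, 16, 1, n))
  m <- build_model("reduced", seed = 3)
  m <- train_model(m, x, y, epochs = 20, batch_size = 8, lr = 4e-3, seed = 5)
  pred <- rtaccum:::net_predict(m, x)
  expect_lt(mean(abs(pred - 0.5)), 0.05)
})

test_that("fold assignment partitions patients exactly once, patient-level", {
  f <- assign_folds(10, 5, seed = 3)
  expect_equal(length(f), 10)
  expect_equal(sort(unique(f)), 1:5)
  expect_true(all(table(f) == 2))
  expect_identical(f, assign_folds(10, 5, seed = 3))
  expect_error(assign_folds(3, 5, seed = 1), "fewer patients")
})

test_that("k-fold training on a tiny cohort validates every patient once", {
  co <- generate_cohort(tiny_spec(), 4, root_seed = 9)
  samples <- assemble_cohort(co$cases, dose_ref = 76.25)
  cfg <- training_config(folds = 2, epochs = 2, seed = 11)
  fit <- train_kfold(samples, cfg)
  expect_equal(sort(fit$metrics$patient), 1:4)
  expect_equal(nrow(fit$metrics), 4)
  expect_true(all(fit$metrics$mae_gy >= 0))
  expect_equal(length(fit$models), 2)
  g <- glance(fit)
  expect_equal(g$n_patients, 4)
  td <- tidy(fit)
  expect_identical(td, fit$metrics)
})

test_that("dose prediction returns a clamped grid on the input geometry", {
  co <- generate_cohort(tiny_spec(), 4, root_seed = 9)
  samples <- assemble_cohort(co$cases, dose_ref = 76.25)
  fit <- train_kfold(samples, training_config(folds = 2, epochs = 2, seed = 11))
  case <- co$cases[[1]]
  pred <- predict_dose(fit$models[[1]], case$ct,
                       build_structure_label_map(case$structures),
                       compute_dtt_map(case$structures))
  expect_s3_class(pred, "dose_grid")
  expect_true(same_geometry(pred, case$truth_dose))
  expect_true(all(pred$values >= 0))
  expect_true(all(is.finite(pred$values)))
  m_none <- build_model("reduced", 1)
  expect_error(predict_dose(m_none, case$ct,
                            build_structure_label_map(case$structures),
                            compute_dtt_map(case$structures)),
               "normalization")
})
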