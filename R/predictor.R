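#' Normalization factors for the prediction channels
#'
#' CT is windowed to `ct_window` HU and scaled to `[0, 1]`; the label map is
#' divided by the largest base-label sum it can attain; the DTT map by the
#' cohort-wide maximum distance; dose by the summed prescription (so a
#' normalized dose of 1 is the prescription EQD2). All factors are recorded
#' so predictions can be inverted back to Gy.
#'
#' @param label_max maximum label-map value across the cohort.
#' @param dtt_max maximum DTT (mm) across the cohort.
#' @param dose_ref reference dose in Gy (summed prescription; > 0).
#' @param ct_window CT intensity window in HU.
#' @return An object of class `dose_norm`.
#' @export
dose_normalization <- function(label_max, dtt_max, dose_ref,
                               ct_window = c(-1000, 1000)) {
  if (!is.finite(dose_ref) || dose_ref <= 0) {
    stop("`dose_ref` must be a positive dose", call. = FALSE)
  }
  if (label_max <= 0 || dtt_max <= 0) {
    stop("`label_max` and `dtt_max` must be positive", call. = FALSE)
  }
  structure(list(label_max = as.numeric(label_max),
                 dtt_max = as.numeric(dtt_max),
                 dose_ref = as.numeric(dose_ref),
                 ct_window = as.numeric(ct_window)),
            class = "dose_norm")
}

#' Derive cohort-wide normalization factors from phantom cases
#'
#' @param cases list of [generate_phantom()] cases.
#' @param dose_ref summed prescription EQD2 in Gy.
#' @return a [dose_normalization()] object.
#' @export
cohort_normalization <- function(cases, dose_ref) {
  label_max <- max(vapply(cases, function(cs) {
    max(build_structure_label_map(cs$structures)$values)
  }, numeric(1)))
  dtt_max <- max(vapply(cases, function(cs) {
    max(compute_dtt_map(cs$structures)$values)
  }, numeric(1)))
  dose_normalization(label_max, dtt_max, dose_ref)
}

normalize_ct <- function(ct, norm) {
  w <- norm$ct_window
  pmin(pmax((ct - w[1]) / (w[2] - w[1]), 0), 1)
}

#' Normalize / denormalize dose values
#'
#' @param values numeric array or vector of dose in Gy (or normalized dose).
#' @param norm a [dose_normalization()].
#' @export
normalize_dose <- function(values, norm) values / norm$dose_ref

#' @rdname normalize_dose
#' @export
denormalize_dose <- function(values, norm) values * norm$dose_ref

#' Assemble training samples from one patient's volumes
#'
#' Stacks axial slices of the three normalized anatomy channels (CT, label
#' map, DTT map) into a 4-D input array and, when a target dose is given,
#' the matching normalized dose slices.
#'
#' @param ct 3-D CT array (HU).
#' @param labels a `label_map` from [build_structure_label_map()].
#' @param dtt a `dtt_map` from [compute_dtt_map()].
#' @param dose optional target [dose_grid()] (accumulated EQD2).
#' @param norm a [dose_normalization()].
#' @return list with `x` (H, W, 3, n_slices), `y` (H, W, 1, n_slices) or
#'   NULL, `geometry`, `norm`.
#' @export
assemble_samples <- function(ct, labels, dtt, dose = NULL, norm) {
  stopifnot(inherits(labels, "label_map"), inherits(dtt, "dtt_map"),
            inherits(norm, "dose_norm"))
  geom <- labels$geometry
  if (!identical(as.integer(dim(ct)), geom$shape) ||
      !same_geometry(labels, dtt) ||
      (!is.null(dose) && !same_geometry(dose, labels))) {
    stop_geometry_mismatch("prediction channels")
  }
  n <- geom$shape
  x <- array(0, c(n[1], n[2], 3, n[3]))
  x[, , 1, ] <- normalize_ct(ct, norm)
  x[, , 2, ] <- labels$values / norm$label_max
  x[, , 3, ] <- dtt$values / norm$dtt_max
  y <- NULL
  if (!is.null(dose)) {
    y <- array(normalize_dose(dose$values, norm), c(n[1], n[2], 1, n[3]))
  }
  list(x = x, y = y, geometry = geom, norm = norm)
}

#' Assemble samples for a whole phantom cohort
#'
#' @param cases list of [generate_phantom()] cases.
#' @param norm a [dose_normalization()]; defaults to
#'   [cohort_normalization()] with `dose_ref`.
#' @param dose_ref summed prescription EQD2 (used when `norm` is NULL).
#' @return list of per-patient sample lists (see [assemble_samples()]), with
#'   the body mask attached as `body` for masked evaluation.
#' @export
assemble_cohort <- function(cases, norm = NULL, dose_ref = 76.25) {
  if (is.null(norm)) norm <- cohort_normalization(cases, dose_ref)
  lapply(cases, function(cs) {
    s <- assemble_samples(cs$ct, build_structure_label_map(cs$structures),
                          compute_dtt_map(cs$structures),
                          dose = cs$truth_dose, norm = norm)
    s$body <- cs$structures$masks$body
    s
  })
}

#' Training configuration
#'
#' @param folds number of cross-validation folds (>= 2, default 5).
#' @param epochs training epochs per fold.
#' @param learning_rate initial Adam learning rate (step schedule, see
#'   [train_model()]).
#' @param batch_size minibatch size in slices.
#' @param preset model preset, `"reduced"` or `"full"`.
#' @param seed root seed for fold assignment, weight init and shuffling.
#' @return An object of class `training_config`.
#' @export
training_config <- function(folds = 5, epochs = 30, learning_rate = 4e-3,
                            batch_size = 8, preset = "reduced", seed = 1) {
  if (folds < 2) stop("`folds` must be >= 2", call. = FALSE)
  structure(list(folds = as.integer(folds), epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 preset = preset, seed = as.integer(seed)),
            class = "training_config")
}

bind_slices <- function(arrays) {
  d <- dim(arrays[[1]])
  n <- vapply(arrays, function(a) dim(a)[4], numeric(1))
  out <- array(0, c(d[1], d[2], d[3], sum(n)))
  at <- 0
  for (a in arrays) {
    out[, , , at + seq_len(dim(a)[4])] <- a
    at <- at + dim(a)[4]
  }
  out
}

#' Patient-level fold assignment
#'
#' Seeded random partition of patients into `folds` groups of near-equal
#' size; every patient appears in exactly one validation fold and folds are
#' patient-level (no slice leakage).
#'
#' @param n_patients number of patients.
#' @param folds number of folds.
#' @param seed integer seed.
#' @return integer vector of fold labels per patient.
#' @export
assign_folds <- function(n_patients, folds, seed) {
  if (n_patients < folds) {
    stop("fewer patients than folds", call. = FALSE)
  }
  set.seed(seed)
  sample(rep_len(seq_len(folds), n_patients))
}

#' K-fold cross-validated training of the dose-prediction model
#'
#' Partitions patients into seeded folds, trains one model per fold on the
#' out-of-fold patients (MSE on normalized dose), and evaluates the held-out
#' patients: per-patient MAE in Gy (over the body mask when present,
#' otherwise the whole volume), alongside the MAE of a cohort-mean-dose
#' baseline computed from the same training patients.
#'
#' @param cohort list of per-patient samples from [assemble_cohort()].
#' @param config a [training_config()].
#' @return list of class `dose_kfold`: `models` (per fold), `fold_of`
#'   (patient fold labels), `metrics` (tibble: fold, patient, mae_gy,
#'   baseline_mae_gy), `config`.
#' @export
train_kfold <- function(cohort, config) {
  stopifnot(inherits(config, "training_config"))
  n_pat <- length(cohort)
  fold_of <- assign_folds(n_pat, config$folds, config$seed)
  norm <- cohort[[1]]$norm

  models <- vector("list", config$folds)
  rows <- list()
  for (f in seq_len(config$folds)) {
    train_idx <- which(fold_of != f)
    val_idx <- which(fold_of == f)
    x_tr <- bind_slices(lapply(cohort[train_idx], `[[`, "x"))
    y_tr <- bind_slices(lapply(cohort[train_idx], `[[`, "y"))

    model <- build_model(config$preset, seed = config$seed + f)
    model$norm <- norm
    model <- train_model(model, x_tr, y_tr, epochs = config$epochs,
                         batch_size = config$batch_size,
                         lr = config$learning_rate,
                         seed = config$seed * 1000 + f)
    models[[f]] <- model

    # cohort-mean baseline: the mean training dose map, voxel by voxel
    y_mean <- Reduce(`+`, lapply(cohort[train_idx], `[[`, "y")) /
      length(train_idx)

    for (i in val_idx) {
      pred <- net_predict(model, cohort[[i]]$x)
      pred[pred < 0] <- 0
      err <- abs(pred - cohort[[i]]$y)
      err_base <- abs(y_mean - cohort[[i]]$y)
      if (!is.null(cohort[[i]]$body)) {
        sel <- array(cohort[[i]]$body,
                     dim(err)[c(1, 2, 4)])  # drop the channel dim
        dim(sel) <- dim(err)
        mae <- mean(err[sel]); mae_b <- mean(err_base[sel])
      } else {
        mae <- mean(err); mae_b <- mean(err_base)
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        fold = f, patient = i,
        mae_gy = denormalize_dose(mae, norm),
        baseline_mae_gy = denormalize_dose(mae_b, norm))
    }
  }
  structure(list(models = models, fold_of = fold_of,
                 metrics = do.call(rbind, rows), config = config),
            class = "dose_kfold")
}

#' @export
print.dose_kfold <- function(x, ...) {
  cat(sprintf("<dose_kfold> %d folds, mean held-out MAE %.2f Gy (baseline %.2f Gy)\n",
              x$config$folds, mean(x$metrics$mae_gy),
              mean(x$metrics$baseline_mae_gy)))
  invisible(x)
}

#' Tidy per-patient cross-validation metrics
#' @param x a `dose_kfold` object.
#' @param ... unused.
#' @export
tidy.dose_kfold <- function(x, ...) x$metrics

#' One-row summary of a cross-validated training run
#' @param x a `dose_kfold` object.
#' @param ... unused.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @rdname glance
#' @export
glance.dose_kfold <- function(x, ...) {
  tibble::tibble(folds = x$config$folds,
                 n_patients = length(x$fold_of),
                 mean_mae_gy = mean(x$metrics$mae_gy),
                 mean_baseline_mae_gy = mean(x$metrics$baseline_mae_gy),
                 preset = x$config$preset)
}

#' Predict an accumulated dose grid from anatomy channels
#'
#' Slice-wise forward pass of a trained model, denormalized to Gy, negative
#' outputs clamped to 0, assembled on the input geometry.
#'
#' @param model a trained [build_model()] (with `norm` attached, e.g. by
#'   [train_kfold()]); alternatively pass `norm` explicitly.
#' @param ct 3-D CT array (HU).
#' @param labels a `label_map`.
#' @param dtt a `dtt_map`.
#' @param norm a [dose_normalization()]; defaults to `model$norm`.
#' @param frame_id frame label of the output grid.
#' @return A predicted [dose_grid()].
#' @export
predict_dose <- function(model, ct, labels, dtt, norm = model$norm,
                         frame_id = "predicted") {
  stopifnot(inherits(model, "dose_model"))
  if (is.null(norm)) {
    stop("no normalization factors: train the model or pass `norm`",
         call. = FALSE)
  }
  s <- assemble_samples(ct, labels, dtt, dose = NULL, norm = norm)
  pred <- net_predict(model, s$x)
  vals <- denormalize_dose(pred, norm)
  vals[vals < 0] <- 0
  dose_grid(array(vals, s$geometry$shape), s$geometry, frame_id = frame_id)
}
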