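#' Read and write dose grids as NIfTI
#'
#' Volumes are stored as `.nii`/`.nii.gz` with the voxel spacing in `pixdim`
#' and the origin in the sform translation (axis-aligned grids only).
#'
#' @param path file path.
#' @param frame_id frame label to attach on read.
#' @return [read_dose_nifti()] returns a [dose_grid()];
#'   [write_dose_nifti()] returns `path` invisibly.
#' @export
read_dose_nifti <- function(path, frame_id = "ref") {
  v <- read_volume_nifti(path)
  dose_grid(v$values, v$geometry, frame_id)
}

#' @rdname read_dose_nifti
#' @param grid a [dose_grid()] (or 3-D array for [write_volume_nifti()]).
#' @export
write_dose_nifti <- function(grid, path) {
  stopifnot(inherits(grid, "dose_grid"))
  write_volume_nifti(grid$values, grid$geometry, path)
}

#' @rdname read_dose_nifti
#' @param values 3-D array (numeric or logical).
#' @param geometry a [grid_geometry()].
#' @export
write_volume_nifti <- function(values, geometry, path) {
  storage.mode(values) <- "double"
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- geometry$spacing
  m <- diag(c(geometry$spacing, 1))
  m[1:3, 4] <- geometry$origin
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_dose_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  vals <- array(as.vector(as.array(img)), dim(img))  # drop RNifti attributes
  list(values = vals,
       geometry = grid_geometry(dim(vals), RNifti::pixdim(img)[1:3],
                                xf[1:3, 4]))
}

#' Write a structure set as per-structure NIfTI masks with a JSON manifest
#'
#' @param structures a [structure_set()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_structure_dir <- function(structures, dir) {
  stopifnot(inherits(structures, "structure_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  table <- default_label_table(structures)
  entries <- lapply(names(structures$masks), function(nm) {
    f <- paste0(nm, ".nii.gz")
    write_volume_nifti(structures$masks[[nm]] * 1, structures$geometry,
                       file.path(dir, f))
    list(name = nm, file = f,
         base_label = if (nm %in% names(table)) unname(table[[nm]]) else NULL)
  })
  manifest <- file.path(dir, "structures.json")
  jsonlite::write_json(entries, manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a structure set written by [write_structure_dir()]
#'
#' @param dir directory containing `structures.json` and the mask volumes.
#' @return a [structure_set()].
#' @export
read_structure_dir <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "structures.json"))
  geom <- NULL
  masks <- list()
  for (e in manifest) {
    v <- read_volume_nifti(file.path(dir, e$file))
    if (is.null(geom)) geom <- v$geometry
    masks[[e$name]] <- v$values > 0.5
  }
  structure_set(masks, geom)
}

#' Save / load a trained dose model
#'
#' The checkpoint is an RDS of the parameter arrays plus a JSON sidecar
#' recording the preset, seed, normalization factors and (optionally) fold
#' assignment, so a prediction run can be reproduced from the files alone.
#'
#' @param model a trained `dose_model`.
#' @param path checkpoint path (`.rds`); the sidecar is `path` + `.json`.
#' @param extra named list merged into the sidecar (e.g. fold assignment).
#' @export
save_model <- function(model, path, extra = list()) {
  stopifnot(inherits(model, "dose_model"))
  saveRDS(model, path)
  sidecar <- c(list(preset = model$preset, levels = model$levels,
                    base = model$base, seed = model$seed,
                    n_parameters = n_parameters(model),
                    norm = unclass(model$norm)), extra)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "dose_model"))
  model
}

#' Read a pipeline configuration from JSON or YAML
#'
#' @param path a `.json`, `.yaml` or `.yml` file.
#' @return named list.
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}
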