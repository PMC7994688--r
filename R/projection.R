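# Projection of voxel metrics onto skeleton vertices: sample the volume by
# trilinear interpolation along the vertex normal out to the tract boundary
# (+/- half_thickness) and keep the maximum (study default) or mean.

#' Project a scalar volume onto skeleton vertices
#'
#' For each vertex the volume is sampled at `vertex + t * normal` for `t`
#' in `[-half_thickness, +half_thickness]` spaced by `step` (the endpoints
#' are always included).  Samples falling outside the volume are excluded
#' from the max/mean; a vertex whose entire segment is outside the volume
#' is an error that reports the offending indices.
#'
#' @param volume a [scalar_volume()].
#' @param mesh a `skeleton_mesh`.
#' @param mode `"max"` (default, as used for the study's FA maps) or
#'   `"mean"`.
#' @param step sampling step along the normal, mm; defaults to one quarter
#'   of the smallest voxel dimension.
#' @return numeric vector of per-vertex projected values.
#' @export
project_metric <- function(volume, mesh, mode = c("max", "mean"), step = NULL) {
  mode <- match.arg(mode)
  validate_mesh(mesh)
  if (!inherits(volume, "scalar_volume"))
    abort("volume must be a scalar_volume", "tractsa_volume_error")
  step <- step %||% (0.25 * min(volume$voxel_size))
  if (step <= 0) abort("step must be positive", "tractsa_config_error")
  n <- nrow(mesh$vertices)
  hmax <- max(mesh$half_thickness)
  toff <- unique(c(seq(0, hmax, by = step), hmax))
  toff <- c(-rev(toff[-1]), toff)
  # sample all vertices at all offsets, mask offsets beyond each vertex's
  # own half-thickness
  k <- length(toff)
  pts <- mesh$vertices[rep(seq_len(n), each = k), , drop = FALSE] +
    mesh$normals[rep(seq_len(n), each = k), , drop = FALSE] * rep(toff, n)
  vals <- matrix(interpolate_trilinear(volume, pts), nrow = k)
  hm <- matrix(rep(abs(toff), n), nrow = k)
  vals[hm > rep(mesh$half_thickness, each = k) + 1e-12] <- NA
  n_in <- colSums(!is.na(vals))
  if (any(n_in == 0))
    abort(sprintf("vertex segment(s) entirely outside the volume: %s",
                  paste(which(n_in == 0), collapse = ", ")),
          "tractsa_projection_outside", vertices = which(n_in == 0))
  if (mode == "max") {
    suppressWarnings(apply(vals, 2, max, na.rm = TRUE))
  } else {
    colMeans(vals, na.rm = TRUE)
  }
}

#' Project one volume per subject into a vertex dataset
#'
#' @param volumes named list of `scalar_volume`, one per subject.
#' @param mesh a `skeleton_mesh`.
#' @inheritParams project_metric
#' @return a [vertex_dataset()].
#' @export
project_cohort <- function(volumes, mesh, mode = "max", step = NULL) {
  vals <- t(vapply(volumes, project_metric, numeric(nrow(mesh$vertices)),
                   mesh = mesh, mode = mode, step = step))
  vertex_dataset(mesh$tract, names(volumes), vals)
}

#' Per-subject tract mean FA
#'
#' Unweighted arithmetic mean over all skeleton vertices, the scalar used
#' for per-tract group comparison and brain-behaviour correlation.
#'
#' @param dataset a [vertex_dataset()].
#' @return named numeric vector, one mean per subject.
#' @export
tract_mean_fa <- function(dataset) {
  if (!inherits(dataset, "vertex_dataset"))
    abort("dataset must be a vertex_dataset", "tractsa_data_error")
  if (nrow(dataset$values) == 0 || ncol(dataset$values) == 0)
    abort("empty dataset", "tractsa_data_error")
  rowMeans(dataset$values)
}

#' Mean FA for every tract
#'
#' @param datasets named list of `vertex_dataset` sharing subject order.
#' @return matrix subjects x tracts of per-subject mean FA.
#' @export
tract_mean_fa_table <- function(datasets) {
  check_same_subjects(datasets)
  out <- sapply(datasets, tract_mean_fa)
  rownames(out) <- datasets[[1]]$subjects
  out
}

check_same_subjects <- function(datasets) {
  if (!length(datasets)) abort("no datasets", "tractsa_data_error")
  s0 <- datasets[[1]]$subjects
  for (d in datasets)
    if (!identical(d$subjects, s0))
      abort("datasets must share the same subject order", "tractsa_data_error")
  invisible(s0)
}
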