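# Scalar volumes: a 3-D array with a voxel-to-world affine (NIfTI
# convention, 0-based voxel indices) and trilinear sampling in world space.

#' Construct a scalar volume
#'
#' @param data 3-D numeric array.
#' @param affine 4 x 4 voxel-to-world matrix mapping 0-based voxel indices
#'   to world mm; must be invertible.
#' @param voxel_size voxel edge lengths (mm); derived from `affine` when
#'   omitted.
#' @return object of class `scalar_volume`.
#' @export
scalar_volume <- function(data, affine = NULL, voxel_size = NULL) {
  data <- as.array(data)
  if (length(dim(data)) == 1) dim(data) <- c(length(data), 1, 1)
  if (length(dim(data)) != 3) abort("data must be a 3-D array", "tractsa_volume_error")
  if (is.null(affine)) {
    voxel_size <- voxel_size %||% c(1, 1, 1)
    affine <- rbind(cbind(diag(voxel_size), c(0, 0, 0)), c(0, 0, 0, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4)) || abs(det(affine[1:3, 1:3])) < 1e-12)
    abort("affine must be an invertible 4 x 4 matrix", "tractsa_volume_error")
  voxel_size <- voxel_size %||% sqrt(colSums(affine[1:3, 1:3]^2))
  structure(list(data = data, affine = affine, voxel_size = voxel_size),
            class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume> %s voxels, voxel size %s mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x")))
  invisible(x)
}

world_to_voxel <- function(volume, points) {
  inv <- solve(volume$affine)
  p <- cbind(points, 1) %*% t(inv)
  p[, 1:3, drop = FALSE]  # 0-based continuous voxel coordinates
}

#' Trilinear interpolation at world coordinates
#'
#' @param volume a `scalar_volume`.
#' @param points n x 3 matrix of world coordinates (mm).
#' @return numeric vector of interpolated values; `NA` outside the volume.
#' @export
interpolate_trilinear <- function(volume, points) {
  points <- matrix(points, ncol = 3)
  vx <- world_to_voxel(volume, points)
  d <- dim(volume$data)
  i0 <- floor(vx)
  f <- vx - i0
  inside <- vx[, 1] >= 0 & vx[, 1] <= d[1] - 1 &
    vx[, 2] >= 0 & vx[, 2] <= d[2] - 1 &
    vx[, 3] >= 0 & vx[, 3] <= d[3] - 1
  out <- rep(NA_real_, nrow(points))
  if (!any(inside)) return(out)
  i0 <- i0[inside, , drop = FALSE]; f <- f[inside, , drop = FALSE]
  # clamp the base corner so that exact upper-boundary points index validly
  i0 <- pmin(i0, matrix(rep(d - 2L, each = nrow(i0)), ncol = 3))
  i0 <- pmax(i0, 0)
  f <- vx[inside, , drop = FALSE] - i0
  at <- function(dx, dy, dz) {
    volume$data[cbind(i0[, 1] + dx + 1, i0[, 2] + dy + 1, i0[, 3] + dz + 1)]
  }
  v <- at(0, 0, 0) * (1 - f[, 1]) * (1 - f[, 2]) * (1 - f[, 3]) +
    at(1, 0, 0) * f[, 1] * (1 - f[, 2]) * (1 - f[, 3]) +
    at(0, 1, 0) * (1 - f[, 1]) * f[, 2] * (1 - f[, 3]) +
    at(0, 0, 1) * (1 - f[, 1]) * (1 - f[, 2]) * f[, 3] +
    at(1, 1, 0) * f[, 1] * f[, 2] * (1 - f[, 3]) +
    at(1, 0, 1) * f[, 1] * (1 - f[, 2]) * f[, 3] +
    at(0, 1, 1) * (1 - f[, 1]) * f[, 2] * f[, 3] +
    at(1, 1, 1) * f[, 1] * f[, 2] * f[, 3]
  out[inside] <- v
  out
}

#' Rasterize vertex values into a scalar volume
#'
#' Builds a per-subject FA volume from values on a skeleton mesh: every
#' voxel whose centre lies within `half_thickness + margin` of its nearest
#' vertex takes that vertex's value; other voxels take `background`.  Used
#' to exercise the projection stage on synthetic data.
#'
#' @param mesh a `skeleton_mesh`.
#' @param values per-vertex values.
#' @param voxel_size voxel edge length, mm (isotropic).
#' @param background value outside the tract slab.
#' @param margin extra slab half-width, mm.
#' @return a `scalar_volume` covering the mesh bounding box.
#' @export
rasterize_vertex_values <- function(mesh, values, voxel_size = 2.5,
                                    background = 0, margin = 1) {
  stopifnot(length(values) == nrow(mesh$vertices))
  pad <- max(mesh$half_thickness) + margin + 2 * voxel_size
  lo <- apply(mesh$vertices, 2, min) - pad
  hi <- apply(mesh$vertices, 2, max) + pad
  n <- pmax(2L, ceiling((hi - lo) / voxel_size) + 1L)
  affine <- rbind(cbind(diag(rep(voxel_size, 3)), lo), c(0, 0, 0, 1))
  gx <- lo[1] + voxel_size * (seq_len(n[1]) - 1)
  gy <- lo[2] + voxel_size * (seq_len(n[2]) - 1)
  gz <- lo[3] + voxel_size * (seq_len(n[3]) - 1)
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  arr <- rep(background, nrow(pts))
  # chunked nearest-vertex search to bound memory
  chunk <- 20000L
  vv <- mesh$vertices
  for (s in seq(1, nrow(pts), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(pts))
    P <- pts[s:e, , drop = FALSE]
    d2 <- outer(rowSums(P^2), rep(1, nrow(vv))) +
      outer(rep(1, nrow(P)), rowSums(vv^2)) - 2 * P %*% t(vv)
    j <- max.col(-d2)
    dmin <- sqrt(pmax(0, d2[cbind(seq_len(nrow(P)), j)]))
    hit <- dmin <= mesh$half_thickness[j] + margin
    arr[s:e][hit] <- values[j[hit]]
  }
  scalar_volume(array(arr, dim = n), affine = affine,
                voxel_size = rep(voxel_size, 3))
}
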