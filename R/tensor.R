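# Diffusion tensor toolbox: acquisition protocol, synthetic DWI signal
# generation with Rician noise, log-linear least-squares tensor fitting,
# and scalar metrics (FA, MD).
#
# Tensors are stored as the 6 unique elements in the order
# (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), units mm^2/s.

#' Diffusion acquisition protocol
#'
#' @param bvals numeric b-values, s/mm^2 (>= 1 zero entry).
#' @param bvecs 3 x n or n x 3 matrix of gradient directions; unit norm
#'   (within 1e-6) for nonzero b.
#' @return object of class `dwi_protocol` with fields `bvals` (length n)
#'   and `bvecs` (n x 3).
#' @export
dwi_protocol <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  dimnames(bvecs) <- NULL
  if (nrow(bvecs) == 3 && ncol(bvecs) != 3) bvecs <- t(bvecs)
  if (ncol(bvecs) != 3 || nrow(bvecs) != length(bvals))
    abort("bvecs must be n x 3 matching length(bvals)", "tractsa_protocol_error")
  nz <- bvals > 0
  if (sum(!nz) < 1)
    abort("protocol needs at least one b=0 volume", "tractsa_protocol_error")
  if (sum(nz) < 6)
    abort("protocol needs >= 6 diffusion-weighted directions",
          "tractsa_protocol_error")
  nrm <- sqrt(rowSums(bvecs[nz, , drop = FALSE]^2))
  if (any(abs(nrm - 1) > 1e-6))
    abort("nonzero-b gradient directions must be unit norm (1e-6)",
          "tractsa_protocol_error")
  B <- tensor_design(bvals[nz], bvecs[nz, , drop = FALSE])
  if (qr(B)$rank < 6)
    abort("directions are collinear/degenerate: tensor underdetermined",
          "tractsa_protocol_error")
  structure(list(bvals = bvals, bvecs = bvecs), class = "dwi_protocol")
}

#' Default single-shell protocol
#'
#' One b=0 volume plus `n_directions` directions on a deterministic
#' spherical (Fibonacci) lattice at the given b-value, matching the
#' study's 30-direction, b = 1000 s/mm^2 acquisition.
#'
#' @param n_directions number of diffusion-weighted directions.
#' @param b shell b-value, s/mm^2.
#' @return a `dwi_protocol`.
#' @export
default_dwi_protocol <- function(n_directions = 30, b = 1000) {
  i <- seq_len(n_directions) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n_directions
  r <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(r * cos(phi), r * sin(phi), z)
  dwi_protocol(c(0, rep(b, n_directions)), rbind(c(0, 0, 0), dirs))
}

# design matrix rows: b * (gx^2, gy^2, gz^2, 2 gx gy, 2 gx gz, 2 gy gz)
tensor_design <- function(bvals, bvecs) {
  g <- bvecs
  bvals * cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
                2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
                2 * g[, 2] * g[, 3])
}

#' Construct a tensor field
#'
#' @param D numeric matrix, voxels x 6, columns
#'   (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz); or a single symmetric 3 x 3 tensor.
#' @param dim grid dimensions (defaults to a flat list of voxels).
#' @param voxel_size voxel edge lengths, mm.
#' @param affine 4 x 4 voxel-to-world matrix (0-based voxel indices).
#' @return object of class `tensor_field`.
#' @export
tensor_field <- function(D, dim = NULL, voxel_size = c(2.5, 2.5, 2.5),
                         affine = NULL) {
  if (is.matrix(D) && all(dim(D) == c(3, 3))) {
    if (max(abs(D - t(D))) > 1e-12)
      abort("tensor must be symmetric", "tractsa_tensor_error")
    D <- matrix(c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3]),
                1, 6)
  }
  D <- as.matrix(D)
  if (ncol(D) != 6) abort("D must be voxels x 6", "tractsa_tensor_error")
  dim <- dim %||% c(nrow(D), 1, 1)
  if (prod(dim) != nrow(D))
    abort("prod(dim) must equal nrow(D)", "tractsa_tensor_error")
  affine <- affine %||% rbind(cbind(diag(voxel_size), c(0, 0, 0)), c(0, 0, 0, 1))
  structure(list(D = D, dim = as.integer(dim), voxel_size = voxel_size,
                 affine = affine), class = "tensor_field")
}

tensor_as_matrix <- function(d6) {
  matrix(c(d6[1], d6[4], d6[5],
           d6[4], d6[2], d6[6],
           d6[5], d6[6], d6[3]), 3, 3)
}

#' Eigenvalues of every tensor in a field
#'
#' Eigenvalues are returned in non-increasing order; negative eigenvalues
#' are clamped to zero and the number of affected voxels is attached as
#' attribute `"n_clamped"`.
#'
#' @param field a `tensor_field`.
#' @param clamp clamp negative eigenvalues at 0 (default TRUE).
#' @return voxels x 3 matrix of eigenvalues.
#' @export
tensor_eigenvalues <- function(field, clamp = TRUE) {
  ev <- t(apply(field$D, 1, function(d) {
    if (any(is.na(d))) return(c(NA_real_, NA_real_, NA_real_))
    sort(eigen(tensor_as_matrix(d), symmetric = TRUE, only.values = TRUE)$values,
         decreasing = TRUE)
  }))
  n_clamped <- sum(apply(ev, 1, function(l) any(!is.na(l) & l < 0)))
  if (clamp) ev[ev < 0] <- 0
  attr(ev, "n_clamped") <- n_clamped
  ev
}

#' Simulate diffusion-weighted signals
#'
#' Monoexponential tensor model `S = S0 * exp(-b g' D g)` per volume, with
#' Rician noise of scale `S0 / snr` (noise-free when `snr` is infinite) --
#' the standard magnitude-MRI noise model.
#'
#' @param field a `tensor_field`; all tensors must be positive
#'   semidefinite.
#' @param protocol a `dwi_protocol`.
#' @param snr signal-to-noise ratio at b=0; `Inf` for noise-free.
#' @param s0 non-diffusion-weighted signal amplitude.
#' @param seed integer RNG seed (used only when `snr` is finite).
#' @return numeric matrix voxels x volumes of signals, with the protocol
#'   attached as attribute `"protocol"`.
#' @export
generate_dwi <- function(field, protocol, snr = Inf, s0 = 100, seed = 1) {
  if (!inherits(protocol, "dwi_protocol"))
    abort("protocol must be a dwi_protocol", "tractsa_protocol_error")
  if (snr <= 0) abort("snr must be positive (or Inf)", "tractsa_config_error")
  ev <- tensor_eigenvalues(field, clamp = FALSE)
  if (any(ev < -1e-12, na.rm = TRUE))
    abort("tensor field is not positive semidefinite", "tractsa_tensor_error")
  B <- tensor_design(protocol$bvals, protocol$bvecs)  # volumes x 6
  S <- s0 * exp(-field$D %*% t(B))
  if (is.finite(snr)) {
    sigma <- s0 / snr
    S <- with_seed(derive_seed(seed, "dwi"), {
      n <- length(S)
      sqrt((S + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
    })
  }
  attr(S, "protocol") <- protocol
  S
}

#' Fit diffusion tensors by log-linear least squares
#'
#' Per voxel, solves `ln(S/S0) = -b g' D g` for the 6 unique tensor
#' elements by ordinary least squares.  Multiple b=0 volumes are averaged
#' into S0 before fitting.  Voxels with any non-positive signal are left
#' unfitted (`NA` tensors, indices in attribute `"unfitted"`).
#'
#' @param signals voxels x volumes signal matrix.
#' @param protocol a `dwi_protocol` (defaults to the one attached to
#'   `signals`).
#' @param voxel_size,affine,dim passed through to [tensor_field()].
#' @return a `tensor_field`.
#' @export
fit_tensor <- function(signals, protocol = attr(signals, "protocol"),
                       voxel_size = c(2.5, 2.5, 2.5), affine = NULL,
                       dim = NULL) {
  if (!inherits(protocol, "dwi_protocol"))
    abort("protocol must be a dwi_protocol", "tractsa_protocol_error")
  signals <- as.matrix(signals)
  if (ncol(signals) != length(protocol$bvals))
    abort("signal volume count must match protocol length",
          "tractsa_protocol_error")
  b0 <- protocol$bvals == 0
  ok <- rowSums(signals <= 0 | !is.finite(signals)) == 0
  S0 <- rowMeans(signals[, b0, drop = FALSE])
  B <- tensor_design(protocol$bvals[!b0], protocol$bvecs[!b0, , drop = FALSE])
  # precompute the OLS operator once: D' = (B'B)^-1 B' * (-ln(S/S0))
  P <- solve(crossprod(B), t(B))
  Y <- -log(signals[, !b0, drop = FALSE] / S0)  # voxels x ndir
  D <- matrix(NA_real_, nrow(signals), 6)
  if (any(ok)) D[ok, ] <- Y[ok, , drop = FALSE] %*% t(P)
  f <- tensor_field(D, dim = dim %||% c(nrow(signals), 1, 1),
                    voxel_size = voxel_size, affine = affine)
  attr(f, "unfitted") <- which(!ok)
  f
}

#' Fractional anisotropy
#'
#' `FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||` from the
#' (clamped, non-increasing) eigenvalues; the zero tensor maps to FA 0.
#'
#' @param field a `tensor_field`.
#' @return a [scalar_volume()] of FA values in `[0, 1]`.
#' @export
fractional_anisotropy <- function(field) {
  ev <- tensor_eigenvalues(field)
  lbar <- rowMeans(ev)
  num <- sqrt(rowSums((ev - lbar)^2))
  den <- sqrt(rowSums(ev^2))
  fa <- ifelse(den > 0, sqrt(1.5) * num / den, 0)
  fa[is.na(fa)] <- NA_real_
  out <- scalar_volume(array(clamp01(fa), dim = field$dim),
                       affine = field$affine, voxel_size = field$voxel_size)
  attr(out, "n_clamped") <- attr(ev, "n_clamped")
  out
}

#' Mean diffusivity
#'
#' `MD = (lambda1 + lambda2 + lambda3) / 3` in mm^2/s.
#'
#' @param field a `tensor_field`.
#' @return a [scalar_volume()].
#' @export
mean_diffusivity <- function(field) {
  ev <- tensor_eigenvalues(field)
  scalar_volume(array(rowMeans(ev), dim = field$dim),
                affine = field$affine, voxel_size = field$voxel_size)
}

#' Tensor with given eigenvalues at a rotation
#'
#' Convenience builder for tests and phantoms: `R diag(lambda) R'`.
#'
#' @param lambda length-3 eigenvalues.
#' @param rotation 3 x 3 rotation matrix (identity by default).
#' @return symmetric 3 x 3 matrix.
#' @export
tensor_from_eigen <- function(lambda, rotation = diag(3)) {
  rotation %*% diag(lambda) %*% t(rotation)
}

#' Random rotation matrix
#'
#' QR-based uniform(ish) random rotation, for property tests.
#'
#' @param seed integer seed.
#' @return 3 x 3 rotation matrix with determinant +1.
#' @export
random_rotation <- function(seed = 1) {
  with_seed(seed, {
    qrd <- qr(matrix(stats::rnorm(9), 3, 3))
    Q <- qr.Q(qrd)
    d <- sign(diag(qr.R(qrd)))
    Q <- Q %*% diag(d)
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    Q
  })
}
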