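# Projection of scalar volumes onto skeleton vertices and per-tract means.

make_volume <- function(value, n = c(30, 30, 30), voxel = 2.5,
                        origin = c(-35, -35, -35)) {
  scalar_volume(array(value, dim = n),
                affine = rbind(cbind(diag(rep(voxel, 3)), origin),
                               c(0, 0, 0, 1)))
}

test_that("constant volumes project to the constant in both modes", {
  m <- toy_mesh(resolution = 5)
  vol <- make_volume(0.42, n = c(60, 60, 60))
  expect_equal(project_metric(vol, m, "max"), rep(0.42, 25))
  expect_equal(project_metric(vol, m, "mean"), rep(0.42, 25))
})

test_that("vanishing half-thickness reduces to the point sample", {
  m <- toy_mesh(resolution = 5)
  m$half_thickness[] <- 1e-9
  with_seed_vals <- array(runif(60^3), dim = c(60, 60, 60))
  vol <- scalar_volume(with_seed_vals,
                       affine = rbind(cbind(diag(rep(2.5, 3)), c(-75, -75, -75)),
                                      c(0, 0, 0, 1)))
  at_vertex <- interpolate_trilinear(vol, m$vertices)
  expect_equal(project_metric(vol, m, "max"), at_vertex, tolerance = 1e-9)
  expect_equal(project_metric(vol, m, "mean"), at_vertex, tolerance = 1e-9)
})

test_that("a bright voxel on the normal segment is found by max mode", {
  m <- toy_mesh(resolution = 5)
  vtx <- 13
  target <- m$vertices[vtx, ] + 0.5 * m$half_thickness[vtx] * m$normals[vtx, ]
  vol <- make_volume(0.1, n = c(60, 60, 60), origin = c(-75, -75, -75))
  ijk <- round(solve(vol$affine) %*% c(target, 1))[1:3] + 1
  vol$data[ijk[1], ijk[2], ijk[3]] <- 0.9
  got <- project_metric(vol, m, "max", step = 0.05)
  # oracle: dense resampling at step/100 along the same segment
  ts <- seq(-m$half_thickness[vtx], m$half_thickness[vtx], by = 0.05 / 100)
  dense <- max(interpolate_trilinear(
    vol, sweep(outer(ts, m$normals[vtx, ]), 2, m$vertices[vtx, ], "+")))
  expect_equal(got[vtx], dense, tolerance = 0.02)
  expect_gt(got[vtx], 0.5)  # the bright voxel dominates
})

test_that("max mode dominates mean mode and translation commutes", {
  m <- toy_mesh(resolution = 6, seed = 5)
  vol <- make_volume(0, n = c(60, 60, 60), origin = c(-75, -75, -75))
  set.seed(8)
  vol$data[] <- runif(length(vol$data))
  mx <- project_metric(vol, m)
  mn <- project_metric(vol, m, "mean")
  expect_true(all(mx >= mn - 1e-12))
  # shift both volume and mesh by the same world offset
  off <- c(13.5, -7.25, 4)
  vol2 <- vol; vol2$affine[1:3, 4] <- vol2$affine[1:3, 4] + off
  m2 <- m; m2$vertices <- sweep(m$vertices, 2, off, "+")
  expect_equal(project_metric(vol2, m2), mx, tolerance = 1e-9)
})

test_that("fully-outside vertex segments raise an indexed error", {
  m <- toy_mesh(resolution = 5)
  vol <- make_volume(1, n = c(3, 3, 3), origin = c(500, 500, 500))
  err <- expect_error(project_metric(vol, m),
                      class = "tractsa_projection_outside")
  expect_equal(err$vertices, 1:25)
})

test_that("rasterized vertex fields round-trip through projection", {
  m <- toy_mesh(resolution = 6)
  vals <- rep(0.55, nrow(m$vertices))
  vol <- rasterize_vertex_values(m, vals, voxel_size = 2)
  # slab-boundary voxels interpolate toward background; max mode recovers
  # the constant up to that edge effect
  expect_equal(project_metric(vol, m, "max"), vals, tolerance = 0.02)
})

test_that("tract_mean_fa equals the brute-force row mean", {
  set.seed(42)
  vals <- matrix(runif(26 * 200), 26, 200)
  ds <- vertex_dataset("CC", sprintf("S%02d", 1:26), vals)
  oracle <- apply(vals, 1, function(r) sum(r) / length(r))
  expect_equal(unname(tract_mean_fa(ds)), unname(oracle), tolerance = 1e-12)
  expect_equal(unname(tract_mean_fa(
    vertex_dataset("CC", "a", matrix(c(0.2, 0.6), 1)))), 0.4)
  expect_equal(unname(tract_mean_fa(
    vertex_dataset("CC", "a", matrix(0.5, 1, 7)))), 0.5)
  expect_error(tract_mean_fa(vertex_dataset("CC", character(0),
                                            matrix(0, 0, 5))),
               class = "tractsa_data_error")
})

test_that("vertex area weights: barycentric split, conservation, rigidity", {
  # single unit right triangle: area 1/2, each vertex gets 1/6
  tri <- skeleton_mesh("CC", rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                       rbind(c(1, 2, 3)),
                       normals = matrix(rep(c(0, 0, 1), 3), ncol = 3, byrow = TRUE),
                       half_thickness = rep(1, 3))
  expect_equal(vertex_area_weights(tri), rep(1 / 6, 3))
  # 3x3 unit grid sheet: total area 4
  g <- flat_grid <- local({
    r <- 3
    verts <- cbind(rep(0:(r - 1), times = r), rep(0:(r - 1), each = r), 0)
    skeleton_mesh("CC", verts, tractsa:::grid_triangles(r),
                  normals = matrix(rep(c(0, 0, 1), r^2), ncol = 3, byrow = TRUE),
                  half_thickness = rep(1, r^2))
  })
  expect_equal(sum(vertex_area_weights(g)), 4.0)
  # conservation and rigid-motion invariance on a curved mesh
  m <- toy_mesh(resolution = 7, seed = 9)
  w <- vertex_area_weights(m)
  a <- m$vertices; tr <- m$triangles
  tri_areas <- vapply(seq_len(nrow(tr)), function(i) {
    u <- a[tr[i, 2], ] - a[tr[i, 1], ]; v <- a[tr[i, 3], ] - a[tr[i, 1], ]
    0.5 * sqrt(sum(crossprod_vec(u, v)^2))
  }, numeric(1))
  expect_equal(sum(w), sum(tri_areas), tolerance = 1e-9)
  R <- random_rotation(17)
  m2 <- m; m2$vertices <- m$vertices %*% t(R)
  m2$normals <- m$normals %*% t(R)
  expect_equal(vertex_area_weights(m2), w, tolerance = 1e-9)
})
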