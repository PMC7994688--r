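# Skeleton meshes: the medial surface of one white-matter tract, carrying
# per-vertex outward unit normals and half-thickness (distance from the
# skeleton to the tract boundary along the normal).

#' The eleven study tracts
#'
#' Canonical names of the white-matter tracts analysed by the pipeline:
#' corpus callosum (CC) and left/right cortico-spinal tract (CST),
#' inferior fronto-occipital fasciculus (IFO), inferior longitudinal
#' fasciculus (ILF), superior longitudinal fasciculus (SLF) and uncinate
#' fasciculus (UNC).
#'
#' @return character vector of length 11.
#' @export
tract_names <- function() {
  c("CC",
    "CST_L", "CST_R",
    "IFO_L", "IFO_R",
    "ILF_L", "ILF_R",
    "SLF_L", "SLF_R",
    "UNC_L", "UNC_R")
}

#' Construct a skeleton mesh
#'
#' A triangulated medial sheet of one tract.  Vertices are world
#' coordinates in millimetres; `normals` are per-vertex outward unit
#' normals; `half_thickness` is the per-vertex distance (mm) from the
#' skeleton to the tract boundary along the +/- normal.
#'
#' @param tract tract name.
#' @param vertices numeric matrix, n x 3.
#' @param triangles integer matrix, m x 3, 1-based vertex indices.
#' @param normals numeric matrix, n x 3, unit rows.
#' @param half_thickness numeric vector, length n, strictly positive.
#' @param uv optional n x 2 matrix of parametric coordinates (kept by the
#'   generator; used to place default effect centres).
#' @return an object of class `skeleton_mesh`.
#' @export
skeleton_mesh <- function(tract, vertices, triangles, normals, half_thickness,
                          uv = NULL) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles); storage.mode(triangles) <- "integer"
  normals <- as.matrix(normals); storage.mode(normals) <- "double"
  half_thickness <- as.numeric(half_thickness)
  dimnames(vertices) <- dimnames(triangles) <- dimnames(normals) <- NULL
  m <- structure(
    list(tract = as.character(tract), vertices = vertices,
         triangles = triangles, normals = normals,
         half_thickness = half_thickness, uv = uv),
    class = "skeleton_mesh")
  validate_mesh(m)
  m
}

validate_mesh <- function(m) {
  n <- nrow(m$vertices)
  if (ncol(m$vertices) != 3) abort("vertices must be n x 3", "tractsa_mesh_error")
  if (ncol(m$triangles) != 3) abort("triangles must be m x 3", "tractsa_mesh_error")
  if (any(m$triangles < 1L) || any(m$triangles > n))
    abort("triangle indices out of range", "tractsa_mesh_error")
  if (nrow(m$normals) != n || length(m$half_thickness) != n)
    abort("normals/half_thickness must match vertex count", "tractsa_mesh_error")
  nrm <- sqrt(rowSums(m$normals^2))
  if (any(abs(nrm - 1) > 1e-6))
    abort("vertex normals must be unit length", "tractsa_mesh_error")
  if (any(m$half_thickness <= 0))
    abort("half_thickness must be strictly positive", "tractsa_mesh_error")
  invisible(m)
}

#' @export
print.skeleton_mesh <- function(x, ...) {
  cat(sprintf("<skeleton_mesh> tract=%s  %d vertices, %d triangles\n",
              x$tract, nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

#' Undirected edge list of a mesh
#'
#' @param mesh a `skeleton_mesh`.
#' @return integer matrix, E x 2, each row one unique undirected edge
#'   (`[,1] < [,2]`), ordered lexicographically.
#' @export
mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2), drop = FALSE],
             tr[, c(2, 3), drop = FALSE],
             tr[, c(1, 3), drop = FALSE])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

#' Per-vertex surface area weights
#'
#' Each vertex receives one third of the summed area of its incident
#' triangles, so that the weights sum exactly to the mesh surface area.
#' Degenerate (zero-area) triangles contribute nothing and raise a warning.
#'
#' @param mesh a `skeleton_mesh`.
#' @return numeric vector of per-vertex areas (mm^2).
#' @export
vertex_area_weights <- function(mesh) {
  validate_mesh(mesh)
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  tri_area <- 0.5 * sqrt(cx^2 + cy^2 + cz^2)
  if (any(tri_area == 0))
    warning(sprintf("%d degenerate zero-area triangle(s); contributing 0",
                    sum(tri_area == 0)))
  w <- numeric(nrow(v))
  third <- tri_area / 3
  for (k in 1:3) {
    s <- tapply(third, tr[, k], sum)
    idx <- as.integer(names(s))
    w[idx] <- w[idx] + as.numeric(s)
  }
  w
}

#' Geodesic distances on the mesh edge graph
#'
#' Single-source shortest-path (Dijkstra) distances along mesh edges with
#' Euclidean edge lengths.  This graph distance approximates the surface
#' geodesic; at the resolutions used here the approximation error is well
#' below one edge length.
#'
#' @param mesh a `skeleton_mesh`.
#' @param from source vertex index (1-based).
#' @return numeric vector of distances (mm) from `from` to every vertex.
#' @export
geodesic_distances <- function(mesh, from) {
  n <- nrow(mesh$vertices)
  if (!is_count(from) || from < 1 || from > n)
    abort(sprintf("source vertex %s not on tract '%s' (1..%d)",
                  format(from), mesh$tract, n), "tractsa_mesh_error")
  e <- mesh_edges(mesh)
  len <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                         mesh$vertices[e[, 2], , drop = FALSE])^2))
  adj <- vector("list", n)
  for (i in seq_len(nrow(e))) {
    adj[[e[i, 1]]] <- rbind(adj[[e[i, 1]]], c(e[i, 2], len[i]))
    adj[[e[i, 2]]] <- rbind(adj[[e[i, 2]]], c(e[i, 1], len[i]))
  }
  dist <- rep(Inf, n); dist[from] <- 0
  done <- rep(FALSE, n)
  for (it in seq_len(n)) {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    nb <- adj[[u]]
    if (is.null(nb)) next
    alt <- dist[u] + nb[, 2]
    upd <- alt < dist[nb[, 1]]
    dist[nb[, 1][upd]] <- alt[upd]
  }
  dist
}

#' Geodesic disk of vertices
#'
#' @param mesh a `skeleton_mesh`.
#' @param center vertex index of the disk centre.
#' @param radius geodesic radius in mm.
#' @return integer vector of vertex indices with graph-geodesic distance
#'   `<= radius` from the centre (always includes the centre).
#' @export
geodesic_disk <- function(mesh, center, radius) {
  if (!is.numeric(radius) || radius < 0)
    abort("radius must be non-negative", "tractsa_mesh_error")
  which(geodesic_distances(mesh, center) <= radius)
}

# Geometry knobs for the parametric sheet of each tract: physical extent
# (mm), out-of-plane bend amplitude, nominal half-thickness and a rigid
# placement.  Values are plausible adult tract scales; they only need to
# produce well-conditioned sheets at the study's resolution.
tract_geometry <- function(tract) {
  idx <- match(tract, tract_names())
  geo <- list(
    CC    = list(L = 42, W = 30, bend = 6, ht = 2.0, center = c(0, 10, 30)),
    CST_L = list(L = 70, W = 16, bend = 5, ht = 1.8, center = c(-22, -15, 10)),
    CST_R = list(L = 70, W = 16, bend = 5, ht = 1.8, center = c(22, -15, 10)),
    IFO_L = list(L = 60, W = 18, bend = 4, ht = 1.6, center = c(-30, 5, 0)),
    IFO_R = list(L = 60, W = 18, bend = 4, ht = 1.6, center = c(30, 5, 0)),
    ILF_L = list(L = 55, W = 18, bend = 4, ht = 1.6, center = c(-35, -25, -5)),
    ILF_R = list(L = 55, W = 18, bend = 4, ht = 1.6, center = c(35, -25, -5)),
    SLF_L = list(L = 65, W = 20, bend = 5, ht = 1.7, center = c(-28, 0, 25)),
    SLF_R = list(L = 65, W = 20, bend = 5, ht = 1.7, center = c(28, 0, 25)),
    UNC_L = list(L = 45, W = 14, bend = 5, ht = 1.5, center = c(-25, 25, -10)),
    UNC_R = list(L = 45, W = 14, bend = 5, ht = 1.5, center = c(25, 25, -10))
  )[[idx]]
  geo$rot <- (idx - 1) * 0.35
  geo
}

#' Generate synthetic skeleton meshes
#'
#' Parametric curved rectangular sheets standing in for fitted medial
#' surfaces: each tract is a `resolution x resolution` vertex grid over a
#' gently bent rectangle with smooth random corrugation, consistently
#' triangulated (two triangles per grid cell), with area-weighted vertex
#' normals and a smoothly varying positive half-thickness.  Output is
#' bit-for-bit reproducible given `seed`.
#'
#' @param tracts character vector of tract names (subset of
#'   [tract_names()]).
#' @param resolution vertices per grid side (>= 4).
#' @param seed integer RNG seed.
#' @return named list of `skeleton_mesh` objects.
#' @examples
#' sk <- generate_skeletons("CC", resolution = 6, seed = 1)
#' nrow(sk$CC$vertices)  # 36
#' @export
generate_skeletons <- function(tracts = tract_names(), resolution = 14, seed = 1) {
  bad <- setdiff(tracts, tract_names())
  if (length(bad))
    abort(sprintf("unknown tract name(s): %s", paste(bad, collapse = ", ")),
          "tractsa_tract_error")
  if (!is_count(resolution) || resolution < 4)
    abort("resolution must be an integer >= 4 vertices per side",
          "tractsa_config_error")
  out <- lapply(tracts, function(tn) {
    with_seed(derive_seed(seed, paste0("skeleton:", tn)),
              make_sheet(tn, resolution))
  })
  names(out) <- tracts
  out
}

make_sheet <- function(tract, r) {
  geo <- tract_geometry(tract)
  u <- rep(seq(0, 1, length.out = r), times = r)   # fast index: along length
  v <- rep(seq(0, 1, length.out = r), each = r)
  # smooth random corrugation: a few low-frequency sinusoids, ~0.5 mm
  amp <- stats::rnorm(3, 0, 0.25)
  pha <- stats::runif(3, 0, 2 * pi)
  bump <- amp[1] * sin(2 * pi * u + pha[1]) +
    amp[2] * sin(2 * pi * v + pha[2]) +
    amp[3] * sin(2 * pi * (u + v) + pha[3])
  x0 <- (u - 0.5) * geo$L
  y0 <- (v - 0.5) * geo$W
  z0 <- geo$bend * sin(pi * u) * sin(pi * v) + bump
  # rigid placement: rotate about z then translate
  ca <- cos(geo$rot); sa <- sin(geo$rot)
  verts <- cbind(ca * x0 - sa * y0 + geo$center[1],
                 sa * x0 + ca * y0 + geo$center[2],
                 z0 + geo$center[3])
  tri <- grid_triangles(r)
  normals <- vertex_normals(verts, tri)
  htamp <- stats::runif(1, 0.1, 0.3)
  ht <- pmax(0.5, geo$ht * (1 + htamp * sin(2 * pi * u) * cos(pi * v)))
  skeleton_mesh(tract, verts, tri, normals, ht, uv = cbind(u, v))
}

grid_triangles <- function(r) {
  idx <- function(i, j) (j - 1L) * r + i
  cells <- expand.grid(i = seq_len(r - 1L), j = seq_len(r - 1L))
  a <- idx(cells$i, cells$j); b <- idx(cells$i + 1L, cells$j)
  c2 <- idx(cells$i + 1L, cells$j + 1L); d <- idx(cells$i, cells$j + 1L)
  rbind(cbind(a, b, c2), cbind(a, c2, d))
}

vertex_normals <- function(verts, tri) {
  a <- verts[tri[, 2], , drop = FALSE] - verts[tri[, 1], , drop = FALSE]
  b <- verts[tri[, 3], , drop = FALSE] - verts[tri[, 1], , drop = FALSE]
  fn <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])  # area-weighted face normal
  n <- matrix(0, nrow(verts), 3)
  for (k in 1:3) {
    for (d in 1:3) {
      s <- tapply(fn[, d], tri[, k], sum)
      idx <- as.integer(names(s))
      n[idx, d] <- n[idx, d] + as.numeric(s)
    }
  }
  n / sqrt(rowSums(n^2))
}
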