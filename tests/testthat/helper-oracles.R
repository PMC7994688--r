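# Independent oracles used across the suite.  These deliberately use
# naive algorithms (relaxation, flood fill, enumeration) so they share no
# code with the implementation they check.

# Bellman-Ford style distance relaxation over mesh edges
oracle_geodesic <- function(mesh, from) {
  e <- tractsa::mesh_edges(mesh)
  len <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                         mesh$vertices[e[, 2], , drop = FALSE])^2))
  d <- rep(Inf, nrow(mesh$vertices)); d[from] <- 0
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(e))) {
      a <- e[i, 1]; b <- e[i, 2]
      if (d[a] + len[i] < d[b]) { d[b] <- d[a] + len[i]; changed <- TRUE }
      if (d[b] + len[i] < d[a]) { d[a] <- d[b] + len[i]; changed <- TRUE }
    }
    if (!changed) break
  }
  d
}

# recursive flood fill over the supra-threshold subgraph
oracle_flood_fill <- function(supra, edges) {
  n <- length(supra)
  adj <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    if (supra[a] && supra[b]) {
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  seen <- rep(FALSE, n)
  comps <- list()
  for (v in which(supra)) {
    if (seen[v]) next
    stack <- v; comp <- integer(0)
    while (length(stack)) {
      u <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (seen[u]) next
      seen[u] <- TRUE; comp <- c(comp, u)
      stack <- c(stack, adj[[u]])
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

# classical BH step-up rule applied literally
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- max(c(0, which(ps <= seq_len(m) * q / m)))
  reject <- rep(FALSE, m)
  if (k > 0) reject[o[seq_len(k)]] <- TRUE
  reject
}

# pooled-variance two-sample t
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(b) - mean(a)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# small helpers reused across files
toy_mesh <- function(resolution = 6, tract = "CC", seed = 1) {
  tractsa::generate_skeletons(tract, resolution = resolution, seed = seed)[[tract]]
}

flat_strip_mesh <- function(nv = 6) {
  # 2 x (nv/2) flat grid strip in the z = 0 plane, unit spacing
  k <- nv / 2
  verts <- cbind(rep(seq_len(k) - 1, each = 2), rep(c(0, 1), k), 0)
  tri <- do.call(rbind, lapply(seq_len(k - 1), function(i) {
    a <- 2 * i - 1; b <- 2 * i; c2 <- 2 * i + 1; d <- 2 * i + 2
    rbind(c(a, b, c2), c(b, d, c2))
  }))
  tractsa::skeleton_mesh("CC", verts, tri,
                         normals = matrix(rep(c(0, 0, 1), nv), ncol = 3,
                                          byrow = TRUE),
                         half_thickness = rep(1, nv))
}

# temporary seed without touching the suite RNG state
with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

crossprod_vec <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}
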