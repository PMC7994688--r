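# Supra-threshold cluster extraction on skeleton surfaces and
# permutation-based family-wise error (FWER) correction with the maximal
# cluster mass pooled over all tracts (Nichols-Holmes style), using
# Freedman-Lane residual permutation to respect nuisance covariates.

#' Cluster inference configuration
#'
#' @param cluster_forming_p two-sided vertex-level tail probability mapped
#'   to the threshold `t0` via the Student quantile at the design's
#'   residual degrees of freedom (default .01, the study's threshold).
#' @param n_permutations number of label permutations (default 10,000).
#' @param fwer_alpha cluster-level family-wise significance level.
#' @param direction `"both"` (default; the two one-directional analyses
#'   share the pooled maximum null), `"group1_lower"` or `"group2_lower"`.
#' @param seed integer RNG seed for the permutation stream.
#' @return object of class `cluster_config`.
#' @export
cluster_config <- function(cluster_forming_p = 0.01, n_permutations = 10000,
                           fwer_alpha = 0.05,
                           direction = c("both", "group1_lower", "group2_lower"),
                           seed = 1) {
  if (!is.numeric(cluster_forming_p) || cluster_forming_p <= 0 ||
      cluster_forming_p >= 1)
    abort("cluster_forming_p must be in (0, 1)", "tractsa_config_error")
  if (!is_count(n_permutations) || n_permutations < 100)
    abort("n_permutations must be an integer >= 100", "tractsa_config_error")
  stopifnot_scalar_prob(fwer_alpha, "fwer_alpha")
  structure(list(cluster_forming_p = cluster_forming_p,
                 n_permutations = as.integer(n_permutations),
                 fwer_alpha = fwer_alpha,
                 direction = match.arg(direction),
                 seed = seed),
            class = "cluster_config")
}

# union-find with path halving over the supra-threshold subgraph; returns
# 0 when no vertex is supra-threshold
max_component_mass <- function(supra, edges, areas) {
  idx <- which(supra)
  if (!length(idx)) return(0)
  keep <- supra[edges[, 1]] & supra[edges[, 2]]
  if (!any(keep)) return(max(areas[idx]))
  e <- edges[keep, , drop = FALSE]
  pos <- integer(length(supra)); pos[idx] <- seq_along(idx)
  parent <- seq_along(idx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(e))) {
    a <- find(pos[e[r, 1]]); b <- find(pos[e[r, 2]])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  max(tapply(areas[idx], roots, sum))
}

component_membership <- function(supra, edges) {
  idx <- which(supra)
  if (!length(idx)) return(list())
  keep <- supra[edges[, 1]] & supra[edges[, 2]]
  pos <- integer(length(supra)); pos[idx] <- seq_along(idx)
  parent <- seq_along(idx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (any(keep)) {
    e <- edges[keep, , drop = FALSE]
    for (r in seq_len(nrow(e))) {
      a <- find(pos[e[r, 1]]); b <- find(pos[e[r, 2]])
      if (a != b) parent[b] <- a
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  unname(split(idx, roots))
}

#' Extract supra-threshold clusters on one tract
#'
#' Vertices exceeding the cluster-forming threshold in the requested
#' direction are grouped into connected components under shared-edge
#' adjacency; each cluster's mass is the sum of its members' surface-area
#' weights.  Clusters are sorted by decreasing mass, ties broken by the
#' smallest member vertex index.
#'
#' @param t_map per-vertex t values.
#' @param mesh the tract's `skeleton_mesh`.
#' @param t0 positive cluster-forming threshold on |t|.
#' @param direction `"group2_lower"` keeps `t < -t0`, `"group1_lower"`
#'   keeps `t > t0`, `"both"` extracts each side separately.
#' @param areas optional precomputed [vertex_area_weights()].
#' @return list of clusters: each `list(vertices, mass, peak_t,
#'   direction)`.
#' @export
extract_clusters <- function(t_map, mesh, t0,
                             direction = c("both", "group1_lower", "group2_lower"),
                             areas = NULL) {
  direction <- match.arg(direction)
  if (length(t_map) != nrow(mesh$vertices))
    abort("t_map length must equal vertex count", "tractsa_data_error")
  if (!is.numeric(t0) || t0 <= 0) abort("t0 must be > 0", "tractsa_config_error")
  areas <- areas %||% vertex_area_weights(mesh)
  edges <- mesh_edges(mesh)
  sides <- switch(direction,
                  both = c("group1_lower", "group2_lower"),
                  direction)
  out <- list()
  for (side in sides) {
    supra <- if (side == "group1_lower") t_map > t0 else t_map < -t0
    comps <- component_membership(supra, edges)
    out <- c(out, lapply(comps, function(vs) {
      list(vertices = sort(vs),
           mass = sum(areas[vs]),
           peak_t = t_map[vs][which.max(abs(t_map[vs]))],
           direction = side)
    }))
  }
  if (!length(out)) return(out)
  ord <- order(-vapply(out, `[[`, numeric(1), "mass"),
               vapply(out, function(cl) min(cl$vertices), integer(1)))
  out[ord]
}

#' Permutation FWER-corrected cluster inference pooled over tracts
#'
#' Observed clusters are extracted per tract at the cluster-forming
#' threshold `t0 = qt(1 - p/2, df)`.  For each permutation, group labels
#' are permuted under the Freedman-Lane scheme (residuals of the
#' covariate-only fit are permuted and the fitted covariate effects added
#' back), t maps are recomputed, and the single maximal cluster mass over
#' ALL tracts (and both directions when `direction = "both"`) is recorded.
#' Each observed cluster's FWER-corrected p-value is
#' `(1 + #permutation maxima >= mass) / (n_permutations + 1)`.
#'
#' When the design has no covariates and the number of distinct group-label
#' splits is at most `n_permutations`, all splits are enumerated
#' exhaustively instead (reported via a message).
#'
#' @param datasets named list of [vertex_dataset()] sharing subject order
#'   (rows must match the design).
#' @param design a [glm_design()].
#' @param meshes named list of `skeleton_mesh` matching `datasets`.
#' @param config a [cluster_config()].
#' @param exhaustive allow the exhaustive small-sample path (default TRUE).
#' @return data.frame (tract, cluster_id, n_vertices, mass_mm2, peak_t,
#'   direction, p_fwer, significant) sorted by p then mass, with
#'   attributes `"members"` (list of vertex index vectors), `"null_max_mass"`
#'   (the permutation distribution) and `"t0"`.
#' @export
permutation_fwer <- function(datasets, design, meshes,
                             config = cluster_config(), exhaustive = TRUE) {
  if (!inherits(config, "cluster_config"))
    abort("config must be a cluster_config", "tractsa_config_error")
  check_same_subjects(datasets)
  if (!all(names(datasets) %in% names(meshes)))
    abort("every dataset needs its mesh", "tractsa_config_error")
  tracts <- names(datasets)
  n <- nrow(design$X)
  if (nrow(datasets[[1]]$values) != n)
    abort("dataset rows must match the design", "tractsa_design_error")
  t0 <- stats::qt(1 - config$cluster_forming_p / 2, df = design$df)
  pre <- tstat_precompute(design)
  areas_l <- lapply(tracts, function(tn) vertex_area_weights(meshes[[tn]]))
  names(areas_l) <- tracts

  # pooled layout: concatenate vertices of all tracts
  nv <- vapply(tracts, function(tn) ncol(datasets[[tn]]$values), integer(1))
  offs <- cumsum(c(0L, nv[-length(nv)])); names(offs) <- tracts
  Y <- do.call(cbind, lapply(tracts, function(tn) datasets[[tn]]$values))
  areas <- unlist(areas_l, use.names = FALSE)
  edges <- do.call(rbind, lapply(tracts, function(tn)
    mesh_edges(meshes[[tn]]) + offs[[tn]]))

  sides <- if (config$direction == "both")
    c("group1_lower", "group2_lower") else config$direction

  # observed clusters per tract
  tobs <- tstat_closed(Y, pre)
  observed <- list()
  for (tn in tracts) {
    cols <- offs[[tn]] + seq_len(nv[[tn]])
    cls <- extract_clusters(tobs[cols], meshes[[tn]], t0,
                            direction = config$direction,
                            areas = areas_l[[tn]])
    for (cl in cls) observed[[length(observed) + 1L]] <- c(cl, list(tract = tn))
  }

  # Freedman-Lane: reduced model = design without the group column
  Z <- design$X[, -design$group_col, drop = FALSE]
  Hz <- Z %*% solve(crossprod(Z), t(Z))
  Fz <- Hz %*% Y
  Rz <- Y - Fz

  perms <- NULL
  n2 <- sum(design$X[, design$group_col] == 1)
  n_splits <- choose(n, n2)
  use_exhaustive <- exhaustive && ncol(design$X) == 2 &&
    n_splits <= config$n_permutations
  if (use_exhaustive) {
    message(sprintf(
      "exhaustive enumeration: %d distinct label splits (< %d requested permutations)",
      n_splits, config$n_permutations))
    splits <- utils::combn(n, n2)
    B <- ncol(splits)
  } else {
    B <- config$n_permutations
  }
  null_max <- numeric(B)
  with_seed(derive_seed(config$seed, "permutation"), {
    for (b in seq_len(B)) {
      if (use_exhaustive) {
        # with no covariates, permuting labels == regressing on the
        # permuted indicator; realize it by reordering rows accordingly
        g <- numeric(n); g[splits[, b]] <- 1
        ord <- integer(n)
        ord[design$X[, design$group_col] == 0] <- which(g == 0)
        ord[design$X[, design$group_col] == 1] <- which(g == 1)
        Yp <- Y[ord, , drop = FALSE]
      } else {
        Yp <- Fz + Rz[sample.int(n), , drop = FALSE]
      }
      tp <- tstat_closed(Yp, pre)
      mm <- 0
      for (side in sides) {
        supra <- if (side == "group1_lower") tp > t0 else tp < -t0
        mm <- max(mm, max_component_mass(supra, edges, areas))
      }
      null_max[b] <- mm
    }
  })

  res <- data.frame(tract = character(0), cluster_id = integer(0),
                    n_vertices = integer(0), mass_mm2 = numeric(0),
                    peak_t = numeric(0), direction = character(0),
                    p_fwer = numeric(0), significant = logical(0),
                    stringsAsFactors = FALSE)
  members <- list()
  if (length(observed)) {
    mass <- vapply(observed, `[[`, numeric(1), "mass")
    p <- vapply(mass, function(m) (1 + sum(null_max >= m)) / (B + 1),
                numeric(1))
    ord <- order(p, -mass)
    observed <- observed[ord]; p <- p[ord]; mass <- mass[ord]
    res <- data.frame(
      tract = vapply(observed, `[[`, character(1), "tract"),
      cluster_id = seq_along(observed),
      n_vertices = vapply(observed, function(cl) length(cl$vertices), integer(1)),
      mass_mm2 = mass,
      peak_t = vapply(observed, `[[`, numeric(1), "peak_t"),
      direction = vapply(observed, `[[`, character(1), "direction"),
      p_fwer = p,
      significant = p <= config$fwer_alpha,
      stringsAsFactors = FALSE)
    members <- lapply(observed, `[[`, "vertices")
  }
  attr(res, "members") <- members
  attr(res, "null_max_mass") <- null_max
  attr(res, "t0") <- t0
  attr(res, "n_permutations") <- B
  res
}

#' One-call group analysis on a synthetic or projected cohort
#'
#' Builds the age+sex design for a two-group contrast and runs
#' [permutation_fwer()] over all tracts.
#'
#' @param records subject table.
#' @param datasets named list of [vertex_dataset()] (full cohort rows).
#' @param meshes named list of `skeleton_mesh`.
#' @param groups length-2 contrast, default CTL vs SCD.
#' @param config a [cluster_config()].
#' @param covariates include age and sex (default TRUE).
#' @return see [permutation_fwer()].
#' @export
analyze_tsa <- function(records, datasets, meshes, groups = c("CTL", "SCD"),
                        config = cluster_config(), covariates = TRUE) {
  dr <- design_from_records(records, groups, covariates = covariates)
  sub <- lapply(datasets, function(d)
    vertex_dataset(d$tract, d$subjects[dr$rows],
                   d$values[dr$rows, , drop = FALSE]))
  permutation_fwer(sub, dr$design, meshes, config)
}
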