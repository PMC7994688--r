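# Synthetic three-group cohort generator: demographics, per-vertex FA fields
# with planted group effects on geodesic disks, white-matter hyperintensity
# (WMH) lesion sets, and neurocognitive scaled scores coupled to corpus
# callosum mean FA.

#' The nine neurocognitive study measures
#'
#' Scaled-score measures of processing speed (Symbol Search, Coding),
#' working memory (Digit Span) and executive functions (inhibition,
#' set-switching, trail making, verbal fluency).  Column `score_k` of a
#' subject table corresponds to the k-th entry.
#'
#' @return named character vector: `score_1` .. `score_9` -> display name.
#' @export
neurocognitive_measures <- function() {
  c(score_1 = "Symbol Search",
    score_2 = "Coding",
    score_3 = "Digit Span",
    score_4 = "Inhibition",
    score_5 = "Inhibition/Switch",
    score_6 = "Trail Making",
    score_7 = "Category Switch",
    score_8 = "Letter Fluency",
    score_9 = "Category Fluency")
}

#' Cohort generator configuration
#'
#' Defaults mirror the study's three-group design: 21 healthy controls
#' (CTL), 26 sickle cell disease patients (SCD) and 19 non-sickle anemic
#' controls (ACTL); ages 22.6 +/- 8.9, 24.2 +/- 9.7 and 26.1 +/- 11.7
#' years; scaled scores on the mean-10 / SD-3 scale.  The planted group
#' effect subtracts `effect_delta` from the FA of every vertex inside a
#' geodesic disk on each tract in `effect_tracts` (SCD) or
#' `effect_tracts_actl` (ACTL).
#'
#' @param n_ctl,n_scd,n_actl group sizes (>= 2).
#' @param age_mean,age_sd numeric length-3 (CTL, SCD, ACTL), years.
#' @param female_fraction numeric length-3, proportion of females per group.
#' @param fa_baseline mean vertex FA in `[0, 1]`.
#' @param fa_sd between-subject Gaussian SD of vertex FA.
#' @param age_slope FA change per year of age (centred at the cohort mean
#'   age).
#' @param sex_offset additive FA offset for female subjects.
#' @param effect_delta FA decrement planted inside the effect disk.
#' @param effect_tracts tracts carrying the SCD effect disk.
#' @param effect_tracts_actl tracts carrying the ACTL effect disk (defaults
#'   to the genu-of-CC / left-IFO subset).
#' @param effect_center named list tract -> centre vertex index; `NULL`
#'   entries default to the vertex nearest parametric position (0.25, 0.5)
#'   (the anterior/genu end of the generated sheets).
#' @param effect_radius geodesic disk radius, mm.
#' @param score_rho length-9 (or scalar) target correlation between CC mean
#'   FA and each neurocognitive measure; defaults to the study's nine
#'   reported correlations.
#' @param score_mean,score_sd scaled-score scale (10, 3).
#' @param seed integer RNG seed.
#' @return object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_ctl = 21, n_scd = 26, n_actl = 19,
                          age_mean = c(22.6, 24.2, 26.1),
                          age_sd = c(8.9, 9.7, 11.7),
                          female_fraction = c(13 / 21, 13 / 26, 8 / 19),
                          fa_baseline = 0.55,
                          fa_sd = 0.04,
                          age_slope = -0.001,
                          sex_offset = 0.005,
                          effect_delta = 0.04,
                          effect_tracts = "CC",
                          effect_tracts_actl = c("CC", "IFO_L"),
                          effect_center = NULL,
                          effect_radius = 7,
                          score_rho = c(0.30, 0.34, 0.27, 0.51, 0.57,
                                        0.29, 0.25, 0.23, 0.24),
                          score_mean = 10, score_sd = 3,
                          seed = 1) {
  cfg <- structure(list(
    n_ctl = n_ctl, n_scd = n_scd, n_actl = n_actl,
    age_mean = age_mean, age_sd = age_sd,
    female_fraction = female_fraction,
    fa_baseline = fa_baseline, fa_sd = fa_sd,
    age_slope = age_slope, sex_offset = sex_offset,
    effect_delta = effect_delta,
    effect_tracts = effect_tracts,
    effect_tracts_actl = effect_tracts_actl,
    effect_center = effect_center,
    effect_radius = effect_radius,
    score_rho = if (length(score_rho) == 1) rep(score_rho, 9) else score_rho,
    score_mean = score_mean, score_sd = score_sd,
    seed = seed), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  for (f in c("n_ctl", "n_scd", "n_actl")) {
    if (!is_count(cfg[[f]]) || cfg[[f]] < 2)
      abort(sprintf("'%s' must be an integer count >= 2", f),
            "tractsa_config_error")
  }
  if (length(cfg$age_mean) != 3 || length(cfg$age_sd) != 3)
    abort("age_mean/age_sd must have length 3 (CTL, SCD, ACTL)",
          "tractsa_config_error")
  if (length(cfg$female_fraction) != 3 ||
      any(cfg$female_fraction < 0 | cfg$female_fraction > 1))
    abort("female_fraction must be three proportions in [0, 1]",
          "tractsa_config_error")
  stopifnot_scalar_prob(cfg$fa_baseline, "fa_baseline")
  if (cfg$fa_sd < 0) abort("fa_sd must be >= 0", "tractsa_config_error")
  if (length(cfg$score_rho) != 9 || any(abs(cfg$score_rho) >= 1))
    abort("score_rho must be 9 correlations with |rho| < 1",
          "tractsa_config_error")
  if (cfg$effect_radius < 0)
    abort("effect_radius must be >= 0", "tractsa_config_error")
  invisible(cfg)
}

#' Construct a vertex dataset
#'
#' Subjects-by-vertices matrix of a metric projected on one tract skeleton.
#'
#' @param tract tract name.
#' @param subjects character subject ids (rows).
#' @param values numeric matrix, subjects x vertices.
#' @return object of class `vertex_dataset`.
#' @export
vertex_dataset <- function(tract, subjects, values) {
  values <- as.matrix(values)
  if (nrow(values) != length(subjects))
    abort("row count must equal number of subjects", "tractsa_data_error")
  rownames(values) <- subjects
  structure(list(tract = as.character(tract),
                 subjects = as.character(subjects),
                 values = values),
            class = "vertex_dataset")
}

#' @export
print.vertex_dataset <- function(x, ...) {
  cat(sprintf("<vertex_dataset> tract=%s  %d subjects x %d vertices\n",
              x$tract, nrow(x$values), ncol(x$values)))
  invisible(x)
}

default_effect_center <- function(mesh) {
  if (!is.null(mesh$uv)) {
    which.min((mesh$uv[, 1] - 0.25)^2 + (mesh$uv[, 2] - 0.5)^2)
  } else {
    ctr <- colMeans(mesh$vertices)
    which.min(rowSums(sweep(mesh$vertices, 2, ctr)^2))
  }
}

#' Generate a synthetic cohort
#'
#' Draws demographics per group, then builds each subject's per-vertex FA
#' field as
#' `fa_baseline + age_slope * (age - mean age) + sex_offset * 1[female]
#'  - effect_delta * 1[vertex in the group's planted disk] + N(0, fa_sd)`,
#' clamped to `[0, 1]`.  Neurocognitive scaled scores are drawn from a
#' bivariate-normal construction sharing the subject's CC mean FA as the
#' latent variable, so that the population correlation with measure k is
#' `score_rho[k]`; noise is independent across measures.
#'
#' @param config a [cohort_config()].
#' @param skeletons named list of `skeleton_mesh` (as from
#'   [generate_skeletons()]).
#' @return list with elements `records` (data.frame: subject_id, group,
#'   age, sex, wmh_present, score_1..score_9) and `datasets` (named list of
#'   `vertex_dataset`, one per skeleton).  The planted vertex sets are
#'   attached as attribute `"effect_vertices"` (list group -> tract ->
#'   indices).
#' @export
generate_cohort <- function(config, skeletons) {
  validate_cohort_config(config)
  if (!length(skeletons)) abort("skeletons must be nonempty", "tractsa_config_error")
  if (is.null(names(skeletons)) || any(!nzchar(names(skeletons))))
    abort("skeletons must be a named list", "tractsa_config_error")
  with_seed(derive_seed(config$seed, "cohort"), {
    groups <- c("CTL", "SCD", "ACTL")
    ns <- c(config$n_ctl, config$n_scd, config$n_actl)
    n <- sum(ns)
    group <- factor(rep(groups, times = ns), levels = groups)
    age <- numeric(n); sex <- character(n)
    off <- 0
    for (g in 1:3) {
      idx <- off + seq_len(ns[g]); off <- off + ns[g]
      age[idx] <- pmax(10, stats::rnorm(ns[g], config$age_mean[g], config$age_sd[g]))
      nf <- round(config$female_fraction[g] * ns[g])
      sex[idx] <- sample(rep(c("F", "M"), c(nf, ns[g] - nf)))
    }
    subject_id <- sprintf("S%03d", seq_len(n))
    # planted disks, computed once per tract
    effect_vertices <- list(SCD = list(), ACTL = list())
    disks <- list()
    for (tn in unique(c(config$effect_tracts, config$effect_tracts_actl))) {
      if (!tn %in% names(skeletons)) next
      mesh <- skeletons[[tn]]
      ctr <- config$effect_center[[tn]] %||% default_effect_center(mesh)
      if (!is_count(ctr) || ctr < 1 || ctr > nrow(mesh$vertices))
        abort(sprintf("effect_center %s is not a vertex of tract '%s'",
                      format(ctr), tn), "tractsa_config_error")
      disks[[tn]] <- geodesic_disk(mesh, ctr, config$effect_radius)
    }
    for (tn in intersect(config$effect_tracts, names(skeletons)))
      effect_vertices$SCD[[tn]] <- disks[[tn]]
    for (tn in intersect(config$effect_tracts_actl, names(skeletons)))
      effect_vertices$ACTL[[tn]] <- disks[[tn]]

    age_c <- age - mean(age)
    datasets <- lapply(names(skeletons), function(tn) {
      mesh <- skeletons[[tn]]
      V <- nrow(mesh$vertices)
      base <- config$fa_baseline + config$age_slope * age_c +
        config$sex_offset * (sex == "F")
      Y <- matrix(base, n, V) +
        matrix(stats::rnorm(n * V, 0, config$fa_sd), n, V)
      for (g in c("SCD", "ACTL")) {
        dv <- effect_vertices[[g]][[tn]]
        if (length(dv))
          Y[group == g, dv] <- Y[group == g, dv] - config$effect_delta
      }
      vertex_dataset(tn, subject_id, clamp01(Y))
    })
    names(datasets) <- names(skeletons)

    # scores: shared latent = CC mean FA (first tract if CC absent),
    # standardized within the cohort; independent noise per measure
    latent_tract <- if ("CC" %in% names(skeletons)) "CC" else names(skeletons)[1]
    m <- rowMeans(datasets[[latent_tract]]$values)
    z <- if (stats::sd(m) > 0) as.numeric(scale(m)) else rep(0, n)
    scores <- sapply(seq_len(9), function(k) {
      rho <- config$score_rho[k]
      config$score_mean + config$score_sd *
        (rho * z + sqrt(1 - rho^2) * stats::rnorm(n))
    })
    colnames(scores) <- names(neurocognitive_measures())

    records <- data.frame(subject_id = subject_id, group = group,
                          age = age, sex = sex, wmh_present = FALSE,
                          stringsAsFactors = FALSE)
    records <- cbind(records, as.data.frame(scores))
    out <- list(records = records, datasets = datasets)
    attr(out, "effect_vertices") <- effect_vertices
    out
  })
}

default_wmh_weights <- function() {
  # Lesion counts by (region, hemisphere) as tabulated for the study's 132
  # accumulated lesions: frontal 47/39, parietal 8/10, temporal 2/2, with
  # the remaining 24 split evenly over other regions.
  data.frame(
    region = rep(c("frontal", "parietal", "temporal", "other"), each = 2),
    hemisphere = rep(c("L", "R"), 4),
    weight = c(47, 39, 8, 10, 2, 2, 12, 12) / 132,
    stringsAsFactors = FALSE)
}

# nominal world-coordinate boxes per (region, hemisphere) for lesion centres
region_box <- function(region, hemisphere) {
  y <- switch(region, frontal = c(20, 60), parietal = c(-60, -20),
              temporal = c(-30, 10), other = c(-20, 20))
  z <- switch(region, temporal = c(-30, -5), c(0, 40))
  x <- if (hemisphere == "L") c(-50, -5) else c(5, 50)
  list(x = x, y = y, z = z)
}

#' Plant white-matter hyperintensity lesions
#'
#' Allocates exactly `total_count` punctate lesions multinomially over
#' (region, hemisphere) cells, assigns each to a randomly chosen carrier
#' subject, and draws lesion radii uniformly in `[1.5, 2.5]` mm (3-5 mm
#' diameters).  Carriers are selected per group with the study's carrier
#' proportions (7/21 CTL, 14/26 SCD, 8/19 ACTL) unless `carrier_prob` is
#' given.  `wmh_present` is set from actual lesion ownership.
#'
#' @param records subject data.frame from [generate_cohort()].
#' @param total_count total number of lesions (>= 0).
#' @param region_weights data.frame (region, hemisphere, weight); weights
#'   are normalized to sum to 1.  Defaults to the study's tabulated lesion
#'   distribution.
#' @param seed integer RNG seed.
#' @param carrier_prob named numeric, per-group probability that a subject
#'   carries lesions.
#' @return `records` with updated `wmh_present` and a list-column
#'   `wmh_lesions` (each a data.frame region, hemisphere, x, y, z,
#'   radius_mm).
#' @export
generate_wmh <- function(records, total_count = 132, region_weights = NULL,
                         seed = 1,
                         carrier_prob = c(CTL = 7 / 21, SCD = 14 / 26,
                                          ACTL = 8 / 19)) {
  if (!is_count(total_count))
    abort("total_count must be a non-negative integer", "tractsa_config_error")
  w <- region_weights %||% default_wmh_weights()
  if (!all(c("region", "hemisphere", "weight") %in% names(w)))
    abort("region_weights needs columns region, hemisphere, weight",
          "tractsa_config_error")
  if (any(w$weight < 0))
    abort("negative region weight", "tractsa_config_error")
  if (!all(w$region %in% c("frontal", "parietal", "temporal", "other")) ||
      !all(w$hemisphere %in% c("L", "R")))
    abort("region/hemisphere outside the closed vocabulary",
          "tractsa_config_error")
  w$weight <- w$weight / sum(w$weight)
  with_seed(derive_seed(seed, "wmh"), {
    records$wmh_lesions <- replicate(nrow(records), empty_lesions(),
                                     simplify = FALSE)
    records$wmh_present <- FALSE
    if (total_count == 0) return(records)
    counts <- as.integer(stats::rmultinom(1, total_count, w$weight))
    # carriers: fixed per-group counts at the study proportions
    carriers <- integer(0)
    for (g in unique(as.character(records$group))) {
      idx <- which(records$group == g)
      k <- round((carrier_prob[[g]] %||% 0.5) * length(idx))
      if (k > 0) carriers <- c(carriers, sample(idx, k))
    }
    if (!length(carriers)) carriers <- seq_len(nrow(records))
    les <- do.call(rbind, lapply(seq_len(nrow(w)), function(i) {
      if (counts[i] == 0) return(NULL)
      box <- region_box(w$region[i], w$hemisphere[i])
      data.frame(region = w$region[i], hemisphere = w$hemisphere[i],
                 x = stats::runif(counts[i], box$x[1], box$x[2]),
                 y = stats::runif(counts[i], box$y[1], box$y[2]),
                 z = stats::runif(counts[i], box$z[1], box$z[2]),
                 radius_mm = stats::runif(counts[i], 1.5, 2.5),
                 stringsAsFactors = FALSE)
    }))
    owner <- carriers[sample.int(length(carriers), nrow(les), replace = TRUE)]
    for (s in unique(owner)) {
      records$wmh_lesions[[s]] <- les[owner == s, , drop = FALSE]
      rownames(records$wmh_lesions[[s]]) <- NULL
    }
    records$wmh_present <- vapply(records$wmh_lesions,
                                  function(d) nrow(d) > 0, logical(1))
    records
  })
}

empty_lesions <- function() {
  data.frame(region = character(0), hemisphere = character(0),
             x = numeric(0), y = numeric(0), z = numeric(0),
             radius_mm = numeric(0), stringsAsFactors = FALSE)
}

#' Pool all lesions of a cohort into one table
#'
#' @param records subject data.frame with a `wmh_lesions` list-column.
#' @return data.frame of all lesions (possibly 0 rows).
#' @export
pool_lesions <- function(records) {
  if (is.null(records$wmh_lesions)) return(empty_lesions())
  out <- do.call(rbind, records$wmh_lesions)
  rownames(out) <- NULL
  out
}
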