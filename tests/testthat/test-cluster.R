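# Vertex-wise GLM, cluster extraction, permutation FWER inference.

test_that("t statistic matches the textbook pooled two-sample oracle", {
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  d <- glm_design(rep(c("A", "B"), each = 3), c("A", "B"))
  t1 <- vertexwise_tstat(matrix(c(a, b), ncol = 1), d)
  expect_equal(abs(as.numeric(t1)), 1.2247, tolerance = 1e-3)
  expect_equal(as.numeric(t1), oracle_pooled_t(a, b), tolerance = 1e-12)
  # identical samples -> t = 0, flagged zero variance where applicable
  Y <- matrix(rep(c(a, a), 4), ncol = 4)
  t2 <- vertexwise_tstat(Y, d)
  expect_equal(as.numeric(t2), rep(0, 4))
})

test_that("an age-aligned group offset is absorbed by the covariate", {
  # group B sits exactly age_slope * (age difference) above group A;
  # with age in the design the group effect must vanish
  n <- 10
  age <- c(20, 22, 24, 26, 28, 40, 42, 44, 46, 48)
  grp <- rep(c("A", "B"), each = 5)
  slope <- 0.01
  y <- 0.5 + slope * age  # purely age-driven, zero residual noise
  d <- glm_design(grp, c("A", "B"), age = age)
  tv <- vertexwise_tstat(matrix(y, ncol = 1), d)
  expect_lt(abs(as.numeric(tv)), 0.05)
  # oracle: residualize y and the group indicator on [1, age] by hand
  X0 <- cbind(1, age)
  H <- X0 %*% solve(crossprod(X0), t(X0))
  ry <- y - H %*% y
  expect_lt(max(abs(ry)), 1e-10)
})

test_that("design validation rejects degenerate inputs", {
  expect_error(glm_design(c("A", "A", "B"), c("A", "B")),
               class = "tractsa_design_error")  # group B has n = 1
  expect_error(glm_design(rep(c("A", "B", "C"), each = 3), c("A", "B")),
               class = "tractsa_design_error")  # stray third group
  grp <- rep(c("A", "B"), each = 3)
  expect_error(glm_design(grp, c("A", "B"), age = rep(1, 6),
                          sex = rep("F", 6)),
               class = "tractsa_design_error")  # constant covariates: rank deficient
})

test_that("cluster extraction matches brute-force flood fill", {
  m <- flat_strip_mesh(6)
  areas <- vertex_area_weights(m)
  # two adjacent + one isolated supra-threshold vertex (group1_lower side)
  tmap <- c(3, 3.5, 0, 0, 4, 0)
  cls <- extract_clusters(tmap, m, t0 = 2.5, direction = "group1_lower")
  oracle <- oracle_flood_fill(tmap > 2.5, mesh_edges(m))
  expect_equal(length(cls), length(oracle))
  got <- lapply(cls, `[[`, "vertices")
  expect_setequal(lapply(got, paste, collapse = ","),
                  lapply(oracle, paste, collapse = ","))
  expect_equal(vapply(cls, `[[`, numeric(1), "mass"),
               vapply(got, function(v) sum(areas[v]), numeric(1)))
  # all sub-threshold -> empty; all supra -> single full-sheet cluster
  expect_length(extract_clusters(rep(1, 6), m, 2.5, "group1_lower"), 0)
  full <- extract_clusters(rep(9, 6), m, 2.5, "group1_lower")
  expect_length(full, 1)
  expect_equal(full[[1]]$mass, sum(areas))
  expect_equal(full[[1]]$vertices, 1:6)
})

test_that("cluster extraction matches flood fill on random curved meshes", {
  m <- toy_mesh(resolution = 8, seed = 4)
  e <- mesh_edges(m)
  set.seed(99)
  for (i in 1:10) {
    tmap <- rnorm(nrow(m$vertices), sd = 2)
    for (dir in c("group1_lower", "group2_lower")) {
      supra <- if (dir == "group1_lower") tmap > 2 else tmap < -2
      oracle <- oracle_flood_fill(supra, e)
      got <- lapply(extract_clusters(tmap, m, 2, dir), `[[`, "vertices")
      expect_setequal(lapply(got, paste, collapse = ","),
                      lapply(oracle, paste, collapse = ","))
    }
  }
})

test_that("clusters sort by decreasing mass with index tie-break", {
  m <- flat_strip_mesh(8)
  tmap <- c(3, 0, 0, 0, 3, 3, 0, 3)   # vertex 8 isolated? check adjacency below
  cls <- extract_clusters(tmap, m, 2.5, "group1_lower")
  masses <- vapply(cls, `[[`, numeric(1), "mass")
  expect_true(all(diff(masses) <= 1e-12))
  firsts <- vapply(cls, function(cl) min(cl$vertices), integer(1))
  ties <- which(abs(diff(masses)) <= 1e-12)
  expect_true(all(firsts[ties] < firsts[ties + 1]))
})

test_that("permutation p-values: extreme rank bound and determinism", {
  # moderate whole-sheet effect: every vertex supra-threshold in the
  # observed data, while permutations rarely cross t0 anywhere
  sk <- generate_skeletons("CC", resolution = 6, seed = 2)
  cfg <- cohort_config(n_ctl = 10, n_scd = 10, n_actl = 2,
                       effect_delta = 0.08, effect_radius = 100,
                       fa_sd = 0.02, seed = 3)
  co <- generate_cohort(cfg, sk)
  cc <- cluster_config(n_permutations = 200, seed = 7)
  res <- analyze_tsa(co$records, co$datasets, sk, c("CTL", "SCD"), cc)
  expect_gte(nrow(res), 1)
  B <- attr(res, "n_permutations")
  nullmax <- attr(res, "null_max_mass")
  # p-values agree with the +1-corrected rank formula, recomputed here
  expect_equal(res$p_fwer,
               vapply(res$mass_mm2,
                      function(m) (1 + sum(nullmax >= m)) / (B + 1),
                      numeric(1)))
  # the dominant observed cluster exceeds every permutation maximum
  expect_gt(max(res$mass_mm2), max(nullmax))
  expect_equal(min(res$p_fwer), 1 / (B + 1))
  expect_true(all(res$p_fwer >= 1 / (B + 1)))
  res2 <- analyze_tsa(co$records, co$datasets, sk, c("CTL", "SCD"), cc)
  expect_identical(res, res2)
  # p monotone non-increasing in observed mass within one analysis
  ord <- order(res$mass_mm2)
  expect_true(all(diff(res$p_fwer[ord]) <= 1e-12))
})

test_that("Monte-Carlo p agrees with exhaustive enumeration at n = 4 + 4", {
  sk <- generate_skeletons("CC", resolution = 5, seed = 6)
  cfg <- cohort_config(n_ctl = 4, n_scd = 4, n_actl = 2,
                       effect_delta = 0.05, effect_radius = 10, seed = 8)
  co <- generate_cohort(cfg, sk)
  dr <- design_from_records(co$records, c("CTL", "SCD"), covariates = FALSE)
  ds <- lapply(co$datasets, function(d)
    vertex_dataset(d$tract, d$subjects[dr$rows], d$values[dr$rows, , drop = FALSE]))
  ex <- suppressMessages(
    permutation_fwer(ds, dr$design, sk,
                     cluster_config(n_permutations = 10000, seed = 1)))
  expect_equal(attr(ex, "n_permutations"), choose(8, 4))  # 70 splits
  mc <- permutation_fwer(ds, dr$design, sk,
                         cluster_config(n_permutations = 10000, seed = 2),
                         exhaustive = FALSE)
  expect_equal(nrow(ex), nrow(mc))
  expect_equal(mc$p_fwer, ex$p_fwer, tolerance = 0.02)
})

test_that("pooling over tracts makes a pure-noise tract more conservative", {
  skA <- generate_skeletons("CC", resolution = 6, seed = 3)
  skB <- generate_skeletons("ILF_R", resolution = 6, seed = 3)
  both <- c(skA, skB)
  p_pooled <- c(); p_alone <- c()
  for (s in 1:12) {
    co <- generate_cohort(cohort_config(n_ctl = 10, n_scd = 10, n_actl = 2,
                                        effect_delta = 0.15, effect_radius = 12,
                                        effect_tracts = "CC", seed = 40 + s),
                          both)
    dr <- design_from_records(co$records, c("CTL", "SCD"))
    ds <- lapply(co$datasets, function(d)
      vertex_dataset(d$tract, d$subjects[dr$rows], d$values[dr$rows, , drop = FALSE]))
    ccfg <- cluster_config(n_permutations = 150, cluster_forming_p = 0.05,
                           seed = 50 + s)
    pooled <- permutation_fwer(ds, dr$design, both, ccfg)
    alone <- permutation_fwer(ds["ILF_R"], dr$design, both["ILF_R"], ccfg)
    pB <- pooled$p_fwer[pooled$tract == "ILF_R"]
    if (length(pB) && nrow(alone)) {
      p_pooled <- c(p_pooled, mean(pB))
      p_alone <- c(p_alone, mean(alone$p_fwer))
    }
  }
  expect_gt(length(p_pooled), 3)
  expect_gt(mean(p_pooled), mean(p_alone))  # pooled maxima are more extreme
})

test_that("consistent subject reordering leaves observed statistics unchanged", {
  sk <- generate_skeletons(c("CC", "UNC_L"), resolution = 5, seed = 4)
  co <- generate_cohort(cohort_config(n_ctl = 8, n_scd = 8, n_actl = 2,
                                      seed = 21), sk)
  dr <- design_from_records(co$records, c("CTL", "SCD"))
  ds <- lapply(co$datasets, function(d)
    vertex_dataset(d$tract, d$subjects[dr$rows], d$values[dr$rows, , drop = FALSE]))
  cc <- cluster_config(n_permutations = 100, cluster_forming_p = 0.1, seed = 5)
  r1 <- permutation_fwer(ds, dr$design, sk, cc)
  set.seed(77); perm <- sample(length(dr$rows))
  ds2 <- lapply(ds, function(d)
    vertex_dataset(d$tract, d$subjects[perm], d$values[perm, , drop = FALSE]))
  rec2 <- co$records[dr$rows, ][perm, ]
  d2 <- glm_design(rec2$group, c("CTL", "SCD"), age = rec2$age, sex = rec2$sex)
  r2 <- permutation_fwer(ds2, d2, sk, cc)
  expect_equal(r2$mass_mm2, r1$mass_mm2, tolerance = 1e-9)
  expect_equal(r2$peak_t, r1$peak_t, tolerance = 1e-9)
  expect_identical(attr(r2, "members"), attr(r1, "members"))
})

test_that("cluster config invariants", {
  expect_error(cluster_config(n_permutations = 0), class = "tractsa_config_error")
  expect_error(cluster_config(cluster_forming_p = 0), class = "tractsa_config_error")
  expect_error(cluster_config(cluster_forming_p = 1.2), class = "tractsa_config_error")
})
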