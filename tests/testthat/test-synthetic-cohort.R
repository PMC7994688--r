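# Synthetic cohort generator: skeleton geometry, demographics, planted
# effects, WMH allocation, score coupling.

test_that("generated skeletons honour the grid-triangulation contract", {
  sk <- generate_skeletons(c("CC", "CST_L"), resolution = 4, seed = 3)
  for (m in sk) {
    expect_equal(nrow(m$vertices), 16)
    expect_equal(nrow(m$triangles), 18)  # two per cell of the 3x3 quad grid
    expect_equal(sqrt(rowSums(m$normals^2)), rep(1, 16), tolerance = 1e-9)
    expect_true(all(m$half_thickness > 0))
    # connected: geodesic distances all finite
    expect_true(all(is.finite(geodesic_distances(m, 1))))
  }
})

test_that("skeleton generation is deterministic and rejects unknown tracts", {
  a <- generate_skeletons("CC", resolution = 5, seed = 11)$CC
  b <- generate_skeletons("CC", resolution = 5, seed = 11)$CC
  expect_identical(a$vertices, b$vertices)
  expect_identical(a$half_thickness, b$half_thickness)
  c2 <- generate_skeletons("CC", resolution = 5, seed = 12)$CC
  expect_false(identical(a$vertices, c2$vertices))
  err <- expect_error(generate_skeletons(c("CC", "XYZ")), class = "tractsa_tract_error")
  expect_match(conditionMessage(err), "XYZ")
  expect_error(generate_skeletons("CC", resolution = 3),
               class = "tractsa_config_error")
})

test_that("geodesic disks match an independent relaxation oracle", {
  for (seed in 1:3) {
    m <- toy_mesh(resolution = 7, seed = seed)
    d_or <- oracle_geodesic(m, 10)
    expect_equal(geodesic_distances(m, 10), d_or, tolerance = 1e-10)
    for (r in c(3, 8, 15))
      expect_identical(geodesic_disk(m, 10, r), which(d_or <= r))
  }
})

test_that("cohort has the study group sizes and valid FA fields", {
  sk <- generate_skeletons(c("CC", "UNC_R"), resolution = 6, seed = 1)
  co <- generate_cohort(cohort_config(seed = 4), sk)
  expect_equal(as.vector(table(co$records$group)), c(21, 26, 19))
  expect_equal(nrow(co$records), 66)
  expect_named(co$datasets, c("CC", "UNC_R"))
  for (d in co$datasets) {
    expect_true(all(d$values >= 0 & d$values <= 1))
    expect_equal(d$subjects, co$records$subject_id)
  }
  expect_true(all(co$records$age > 0))
  # female counts follow the configured fractions deterministically
  expect_equal(sum(co$records$sex[co$records$group == "CTL"] == "F"), 13)
  expect_equal(sum(co$records$sex[co$records$group == "SCD"] == "F"), 13)
  expect_equal(sum(co$records$sex[co$records$group == "ACTL"] == "F"), 8)
})

test_that("degenerate generator produces identical subject maps", {
  sk <- generate_skeletons("CC", resolution = 5, seed = 2)
  cfg <- cohort_config(effect_delta = 0, age_slope = 0, sex_offset = 0,
                       fa_sd = 0, seed = 7)
  co <- generate_cohort(cfg, sk)
  v <- co$datasets$CC$values
  expect_equal(max(v) - min(v), 0)
  expect_equal(unname(v[1, 1]), cfg$fa_baseline)
})

test_that("cohort generation is bit-for-bit reproducible", {
  sk <- generate_skeletons(c("CC", "IFO_L"), resolution = 5, seed = 2)
  a <- generate_cohort(cohort_config(seed = 31), sk)
  b <- generate_cohort(cohort_config(seed = 31), sk)
  expect_identical(a$records, b$records)
  expect_identical(a$datasets$IFO_L$values, b$datasets$IFO_L$values)
})

test_that("planted decrement hits exactly the geodesic disk", {
  sk <- generate_skeletons("CC", resolution = 8, seed = 3)
  cfg <- cohort_config(effect_delta = 0.1, age_slope = 0, sex_offset = 0,
                       fa_sd = 0, effect_radius = 8, seed = 9)
  co <- generate_cohort(cfg, sk)
  ev <- attr(co, "effect_vertices")$SCD$CC
  ctr <- tractsa:::default_effect_center(sk$CC)
  expect_identical(ev, which(oracle_geodesic(sk$CC, ctr) <= 8))
  grp <- co$records$group
  diffmap <- colMeans(co$datasets$CC$values[grp == "CTL", , drop = FALSE]) -
    colMeans(co$datasets$CC$values[grp == "SCD", , drop = FALSE])
  expect_equal(which(abs(diffmap) > 1e-12), ev)
  expect_equal(unname(diffmap[ev]), rep(0.1, length(ev)))
})

test_that("null group difference shrinks at the 1/sqrt(n) rate", {
  sk <- generate_skeletons("CC", resolution = 5, seed = 2)
  n <- 500
  cfg <- cohort_config(n_ctl = n, n_scd = n, n_actl = 2, effect_delta = 0,
                       age_slope = 0, sex_offset = 0, seed = 13)
  co <- generate_cohort(cfg, sk)
  grp <- co$records$group
  d <- mean(co$datasets$CC$values[grp == "CTL", ]) -
    mean(co$datasets$CC$values[grp == "SCD", ])
  V <- ncol(co$datasets$CC$values)
  se <- cfg$fa_sd * sqrt(2 / (n * V))  # vertex noise is iid across vertices
  expect_lt(abs(d), 3 * se)
})

test_that("score coupling recovers the target correlation (Monte Carlo)", {
  sk <- generate_skeletons("CC", resolution = 5, seed = 2)
  rbar <- mean(vapply(1:300, function(s) {
    co <- generate_cohort(cohort_config(n_ctl = 2, n_scd = 26, n_actl = 2,
                                        score_rho = 0.51, seed = s), sk)
    scd <- co$records$group == "SCD"
    cor(rowMeans(co$datasets$CC$values[scd, ]), co$records$score_1[scd])
  }, numeric(1)))
  # E[r] ~ rho (1 - (1 - rho^2)/(2n)) = 0.503 at n = 26
  expect_lt(abs(rbar - 0.51), 0.03)
})

test_that("config invariants are enforced", {
  expect_error(cohort_config(n_ctl = 1), class = "tractsa_config_error")
  expect_error(cohort_config(score_rho = 1), class = "tractsa_config_error")
  expect_error(cohort_config(female_fraction = c(0.5, 0.5, 1.2)),
               class = "tractsa_config_error")
  sk <- generate_skeletons("CC", resolution = 5, seed = 2)
  expect_error(
    generate_cohort(cohort_config(effect_center = list(CC = 999)), sk),
    class = "tractsa_config_error")
})

test_that("WMH allocation is exact, multinomial and flag-consistent", {
  sk <- generate_skeletons("CC", resolution = 4, seed = 2)
  co <- generate_cohort(cohort_config(seed = 3), sk)
  none <- generate_wmh(co$records, total_count = 0, seed = 5)
  expect_false(any(none$wmh_present))
  expect_equal(nrow(pool_lesions(none)), 0)

  rec <- generate_wmh(co$records, total_count = 132, seed = 5)
  les <- pool_lesions(rec)
  expect_equal(nrow(les), 132)
  expect_true(all(les$radius_mm >= 1.5 & les$radius_mm <= 2.5))
  expect_true(all(les$region %in% c("frontal", "parietal", "temporal", "other")))
  owners <- vapply(rec$wmh_lesions, nrow, integer(1))
  expect_identical(rec$wmh_present, owners > 0)

  big <- generate_wmh(co$records, total_count = 10000, seed = 6)
  share <- with(pool_lesions(big),
                mean(region == "parietal" & hemisphere == "L"))
  expect_lt(abs(share - 8 / 132), 0.01)

  w <- tractsa:::default_wmh_weights()
  w$weight[1] <- -0.1
  expect_error(generate_wmh(co$records, 10, region_weights = w),
               class = "tractsa_config_error")
})
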