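# Group comparisons: ANOVA, Wilcoxon rank-sum, demographics, WMH tables.

test_that("one-way ANOVA matches hand-computed sums of squares", {
  vals <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  grp <- rep(c("a", "b", "c"), each = 3)
  out <- group_anova(vals, grp)
  expect_equal(unname(out["F"]), 3.0)  # SSB = 6 (df 2), SSW = 6 (df 6)
  expect_equal(unname(out["p"]),
               pf(3, 2, 6, lower.tail = FALSE), tolerance = 1e-12)
  # identical groups -> F = 0
  same <- group_anova(rep(c(1, 2, 3), 3), grp)
  expect_equal(unname(same["F"]), 0)
  # two groups: F = t^2
  a <- c(1.2, 0.8, 1.5, 0.9); b <- c(2.0, 1.7, 2.4, 2.2)
  f2 <- group_anova(c(a, b), rep(c("a", "b"), each = 4))
  expect_equal(unname(f2["F"]), oracle_pooled_t(a, b)^2, tolerance = 1e-9)
  expect_error(group_anova(1:3, c("a", "a", "b")), class = "tractsa_stats_error")
})

test_that("per-tract and repeated-measures ANOVA run on cohort summaries", {
  sk <- generate_skeletons(c("CC", "SLF_L"), resolution = 5, seed = 2)
  co <- generate_cohort(cohort_config(seed = 14, effect_delta = 0.08,
                                      effect_radius = 30), sk)
  mfa <- tract_mean_fa_table(co$datasets)
  an <- anova_by_tract(mfa, co$records$group)
  expect_equal(an$tract, c("CC", "SLF_L"))
  expect_true(all(an$F >= 0))
  expect_lt(an$p[an$tract == "CC"], 0.05)  # broad planted decrement detected
  rm <- anova_by_tract(mfa, co$records$group, repeated = TRUE)
  expect_equal(nrow(rm), 1)
  expect_true(rm$F >= 0 && rm$p <= 1)
})

test_that("Wilcoxon rank-sum: exact enumeration and ties", {
  out <- wilcoxon_rank(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(unname(out["W"]), 6)
  expect_equal(unname(out["p"]), 0.05)  # most extreme of C(6,3) = 20 splits
  # identical multisets: W at its null mean, two-sided p near 1
  sym <- wilcoxon_rank(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(sym["W"]), 3 * 7 / 2)
  expect_gte(unname(sym["p"]), 0.9)
  tied <- wilcoxon_rank(c(2, 2, 2), c(2, 2, 2))
  expect_equal(unname(tied["p"]), 1)
  expect_true(isTRUE(attr(tied, "all_tied")))
  expect_error(wilcoxon_rank(1, c(1, 2)), class = "tractsa_stats_error")
})

test_that("large-sample Wilcoxon p agrees with a permutation oracle", {
  set.seed(31)
  a <- rnorm(20); b <- rnorm(20, 0.6)
  out <- wilcoxon_rank(a, b, alternative = "less")
  r <- rank(c(a, b))
  W_mc <- replicate(1e5, sum(r[sample(40, 20)]))
  p_mc <- mean(W_mc <= out["W"])
  expect_lt(abs(unname(out["p"]) - p_mc), 0.01)
  # and with heavy ties
  a2 <- sample(1:4, 15, TRUE); b2 <- sample(2:5, 15, TRUE)
  o2 <- wilcoxon_rank(a2, b2, alternative = "less")
  r2 <- rank(c(a2, b2))
  p2_mc <- mean(replicate(1e5, sum(r2[sample(30, 15)])) <= o2["W"])
  expect_lt(abs(unname(o2["p"]) - p2_mc), 0.01)
})

test_that("demographics table formats counts and applies Bonferroni", {
  rec <- data.frame(
    subject_id = sprintf("S%02d", 1:47),
    group = rep(c("CTL", "SCD"), c(21, 26)),
    age = c(rnorm(21, 22.6, 8.9), rnorm(26, 24.2, 9.7)),
    sex = c(rep(c("F", "M"), c(13, 8)), rep(c("F", "M"), c(13, 13))),
    wmh_present = rep(c(FALSE, TRUE), c(30, 17)),
    stringsAsFactors = FALSE)
  tab <- suppressMessages(demographics_table(rec, c("CTL", "SCD")))
  sexrow <- tab[tab$variable == "sex", ]
  expect_equal(sexrow$group1, "13 (62%)")
  expect_equal(sexrow$group2, "13 (50%)")
  expect_true(all(tab$p_bonferroni >= tab$p_raw - 1e-12))
  expect_true(all(tab$p_bonferroni <= 1))
  expect_equal(tab$p_bonferroni, pmin(1, tab$p_raw * nrow(tab)))
  # identical groups: t = 0, raw p = 1
  rec2 <- rec; rec2$age <- rep(rep(c(20, 30), length.out = 21), length.out = 47)
  rec2$age[rec2$group == "CTL"] <- rep(c(20, 30), length.out = 21)
  rec2$age[rec2$group == "SCD"] <- rep(c(20, 30), length.out = 26)
  t2 <- demographics_table(rec2[, 1:4], c("CTL", "SCD"),
                           continuous = "age", categorical = "sex")
  agerow <- t2[t2$variable == "age", ]
  expect_lt(abs(agerow$statistic), 0.45)  # near-identical groups
})

test_that("WMH distribution reproduces the tabulated percentages", {
  les <- data.frame(
    region = rep(c("frontal", "parietal", "temporal", "other"),
                 c(86, 18, 4, 24)),
    hemisphere = c(rep(c("L", "R"), c(47, 39)), rep(c("L", "R"), c(8, 10)),
                   rep(c("L", "R"), c(2, 2)), rep(c("L", "R"), c(12, 12))))
  out <- wmh_distribution(les)
  get <- function(r, h) out$percent[out$region == r & out$hemisphere == h]
  expect_equal(get("frontal", "L"), 35.6)   # 47/132
  expect_equal(get("frontal", "R"), 29.5)   # 39/132
  expect_equal(get("parietal", "L"), 6.0)   # 8/132 = 6.06, truncated
  expect_equal(get("parietal", "R"), 7.5)   # 10/132 = 7.58, truncated
  expect_equal(get("temporal", "L"), 1.5)
  expect_equal(get("temporal", "R"), 1.5)
  expect_lte(sum(out$percent), 100)
  expect_equal(sum(out$percent), 100, tolerance = 0.5)
  expect_equal(sum(out$count), 132)
  empty <- wmh_distribution(data.frame())
  expect_equal(nrow(empty), 0)
})
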