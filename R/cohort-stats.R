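# Group-level summary statistics: per-tract ANOVA on mean FA, Wilcoxon
# rank tests on neurocognitive scores, t / chi-squared demographics tables
# with Bonferroni correction, and WMH lesion distribution summaries.

#' One-way between-groups ANOVA
#'
#' @param values numeric outcome (e.g. per-subject tract mean FA).
#' @param group factor/character of group labels (>= 2 groups, each
#'   n >= 2).
#' @return named numeric `c(F, p, df1, df2)`.
#' @export
group_anova <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2 || any(table(group) < 2))
    abort("need >= 2 groups with >= 2 subjects each", "tractsa_stats_error")
  fit <- stats::anova(stats::lm(values ~ group))
  c(F = fit[1, "F value"], p = fit[1, "Pr(>F)"],
    df1 = fit[1, "Df"], df2 = fit[2, "Df"])
}

#' Per-tract ANOVA on mean FA across the three groups
#'
#' `repeated = FALSE` (default) runs an independent one-way ANOVA per
#' tract.  `repeated = TRUE` instead fits a mixed group x tract model with
#' a subject block (`aov(fa ~ group * tract + Error(subject))`) and
#' returns the between-subject group effect -- the groups themselves are
#' unpaired, so tract is the only within-subject factor.
#'
#' @param mean_fa matrix subjects x tracts (see [tract_mean_fa_table()]).
#' @param group group label per subject.
#' @param repeated use the mixed group x tract model.
#' @return data.frame (tract, F, p, df1, df2); a single row labelled
#'   `"(group)"` when `repeated = TRUE`.
#' @export
anova_by_tract <- function(mean_fa, group, repeated = FALSE) {
  mean_fa <- as.matrix(mean_fa)
  if (repeated) {
    long <- data.frame(
      fa = as.vector(mean_fa),
      tract = factor(rep(colnames(mean_fa), each = nrow(mean_fa))),
      subject = factor(rep(seq_len(nrow(mean_fa)), ncol(mean_fa))),
      group = factor(rep(group, ncol(mean_fa))))
    fit <- summary(stats::aov(fa ~ group * tract + Error(subject), data = long))
    tab <- fit[["Error: subject"]][[1]]
    return(data.frame(tract = "(group)", F = tab["group", "F value"],
                      p = tab["group", "Pr(>F)"], df1 = tab["group", "Df"],
                      df2 = tab["Residuals", "Df"], stringsAsFactors = FALSE))
  }
  out <- t(apply(mean_fa, 2, group_anova, group = group))
  data.frame(tract = colnames(mean_fa), out, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Wilcoxon rank-sum (Mann-Whitney) test with midranks
#'
#' Exact enumeration over all `choose(na + nb, na)` label splits when both
#' samples have n <= 10 (ties handled through midranks); otherwise the
#' normal approximation with tie-corrected variance and a 0.5 continuity
#' correction.  When every value is tied across both samples, p = 1 with
#' attribute `"all_tied"`.
#'
#' @param a,b numeric samples, each n >= 2.
#' @param alternative `"two.sided"` (default), `"less"` (a shifted below
#'   b) or `"greater"`.
#' @param exact force/forbid exact enumeration (default: automatic).
#' @return named numeric `c(W, p)`; `W` is the rank sum of sample `a`.
#' @export
wilcoxon_rank <- function(a, b, alternative = c("two.sided", "less", "greater"),
                          exact = NULL) {
  alternative <- match.arg(alternative)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    abort("each sample needs n >= 2", "tractsa_stats_error")
  pooled <- c(a, b)
  na <- length(a); nb <- length(b); N <- na + nb
  r <- rank(pooled)  # midranks
  W <- sum(r[seq_len(na)])
  if (length(unique(pooled)) == 1) {
    out <- c(W = W, p = 1)
    attr(out, "all_tied") <- TRUE
    return(out)
  }
  exact <- exact %||% (max(na, nb) <= 10)
  if (exact) {
    splits <- utils::combn(N, na)
    Wall <- colSums(matrix(r[splits], nrow = na))
    p_less <- mean(Wall <= W)
    p_greater <- mean(Wall >= W)
  } else {
    mu <- na * (N + 1) / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma <- sqrt(na * nb / 12 * ((N + 1) - tie_term))
    p_less <- stats::pnorm((W - mu + 0.5) / sigma)
    p_greater <- stats::pnorm((W - mu - 0.5) / sigma, lower.tail = FALSE)
  }
  p <- switch(alternative,
              less = p_less,
              greater = p_greater,
              two.sided = min(1, 2 * min(p_less, p_greater)))
  c(W = W, p = p)
}

fmt_count_pct <- function(count, total) {
  sprintf("%d (%d%%)", count, round(100 * count / total))
}

fmt_mean_sd <- function(x) sprintf("%.1f ± %.1f", mean(x), stats::sd(x))

#' Two-group demographics comparison table
#'
#' Continuous variables are compared by a two-sample t test (Welch by
#' default), categorical variables by Pearson's chi-squared; the Bonferroni
#' family is the full set of variables in one table.  Counts are reported
#' as `"13 (62%)"` with integer percentages; continuous summaries as
#' `mean +/- SD`.
#'
#' @param records subject data.frame.
#' @param groups length-2 character: the two groups compared.
#' @param continuous names of continuous columns (default `"age"` plus any
#'   score columns present).
#' @param categorical names of categorical columns (default sex and
#'   wmh_present when present); binary columns are summarised by their
#'   second level / `TRUE` / `"F"` count.
#' @param yates apply Yates continuity correction to 2x2 chi-squared
#'   tables (default FALSE).
#' @param var_equal pooled-variance t test (default TRUE, the classical
#'   two-sample t).
#' @return data.frame (variable, kind, statistic, p_raw, p_bonferroni,
#'   group1, group2).
#' @export
demographics_table <- function(records, groups = c("CTL", "SCD"),
                               continuous = NULL, categorical = NULL,
                               yates = FALSE, var_equal = TRUE) {
  continuous <- continuous %||%
    intersect(c("age", names(neurocognitive_measures())), names(records))
  categorical <- categorical %||%
    intersect(c("sex", "wmh_present"), names(records))
  g1 <- records[records$group == groups[1], , drop = FALSE]
  g2 <- records[records$group == groups[2], , drop = FALSE]
  if (!nrow(g1) || !nrow(g2))
    abort("empty group in demographics comparison", "tractsa_stats_error")
  rows <- list()
  for (v in continuous) {
    x1 <- g1[[v]]; x2 <- g2[[v]]
    tt <- stats::t.test(x1, x2, var.equal = var_equal)
    rows[[v]] <- data.frame(variable = v, kind = "t",
                            statistic = unname(tt$statistic),
                            p_raw = tt$p.value,
                            group1 = fmt_mean_sd(x1), group2 = fmt_mean_sd(x2),
                            stringsAsFactors = FALSE)
  }
  for (v in categorical) {
    x1 <- as.character(g1[[v]]); x2 <- as.character(g2[[v]])
    tab <- table(group = rep(groups, c(length(x1), length(x2))), value = c(x1, x2))
    lv <- colnames(tab)
    show <- if ("F" %in% lv) "F" else if ("TRUE" %in% lv) "TRUE" else lv[length(lv)]
    if (ncol(tab) < 2) {
      stat <- 0; p <- 1
    } else {
      if (any(tab == 0)) message(sprintf(
        "empty cell in chi-squared table for '%s'; asymptotic p unreliable", v))
      cs <- suppressWarnings(stats::chisq.test(tab, correct = yates))
      stat <- unname(cs$statistic); p <- cs$p.value
    }
    rows[[v]] <- data.frame(
      variable = v, kind = "chisq", statistic = stat, p_raw = p,
      group1 = fmt_count_pct(sum(x1 == show), length(x1)),
      group2 = fmt_count_pct(sum(x2 == show), length(x2)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  m <- nrow(out)
  out$p_bonferroni <- pmin(1, out$p_raw * m)
  out[, c("variable", "kind", "statistic", "p_raw", "p_bonferroni",
          "group1", "group2")]
}

#' WMH lesion distribution by region and hemisphere
#'
#' @param lesions data.frame with columns region and hemisphere (e.g. from
#'   [pool_lesions()]).
#' @param regions report order (default frontal, parietal, temporal,
#'   other).
#' @return data.frame (region, hemisphere, count, percent) with percent =
#'   100 * count / total, truncated to one decimal (the convention that
#'   reproduces published lesion-share tables, e.g. 8/132 -> 6.0); zero
#'   rows for empty input.
#' @export
wmh_distribution <- function(lesions,
                             regions = c("frontal", "parietal", "temporal",
                                         "other")) {
  if (is.null(lesions) || nrow(lesions) == 0) {
    return(data.frame(region = character(0), hemisphere = character(0),
                      count = integer(0), percent = numeric(0),
                      stringsAsFactors = FALSE))
  }
  total <- nrow(lesions)
  grid <- expand.grid(hemisphere = c("L", "R"), region = regions,
                      stringsAsFactors = FALSE)[, c("region", "hemisphere")]
  grid <- grid[grid$region %in% unique(lesions$region), , drop = FALSE]
  cnt <- mapply(function(r, h) sum(lesions$region == r & lesions$hemisphere == h),
                grid$region, grid$hemisphere)
  data.frame(region = grid$region, hemisphere = grid$hemisphere,
             count = as.integer(cnt),
             percent = floor(1000 * cnt / total) / 10,
             row.names = NULL, stringsAsFactors = FALSE)
}
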