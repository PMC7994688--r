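# Brain-behaviour association: Pearson correlation of per-tract mean FA
# with the nine neurocognitive scaled scores, with Benjamini-Hochberg
# step-up false-discovery-rate control over the full tract x measure
# family.

#' Pearson correlation with t-based p-value
#'
#' @param x,y numeric vectors, n >= 3, non-constant.
#' @return named numeric `c(r, p, n)`; two-sided p from the t transform
#'   with n - 2 degrees of freedom.
#' @export
pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("need n >= 3 complete pairs", "tractsa_stats_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    abort("constant input: correlation undefined", "tractsa_constant_input")
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  c(r = r, p = p, n = n)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted p-values are `min_{j >= i} min(1, m p_(j) / j)` over the
#' ascending order statistics; the rejection set at level `q` is every
#' test with adjusted p <= q (equivalent to the classical step-up rule).
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param q FDR level in (0, 1).
#' @return list(adjusted, reject) in the original order.
#' @export
bh_adjust <- function(p, q = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    abort("p-values must lie in [0, 1]", "tractsa_stats_error")
  if (q <= 0 || q >= 1) abort("q must be in (0, 1)", "tractsa_stats_error")
  m <- length(p)
  o <- order(p)
  adj_sorted <- rev(cummin(rev(pmin(1, m * p[o] / seq_len(m)))))
  adjusted <- numeric(m)
  adjusted[o] <- adj_sorted
  list(adjusted = adjusted, reject = adjusted <= q)
}

#' Correlate tract mean FA with neurocognitive measures
#'
#' Computes all tract x measure Pearson correlations within one group
#' (default SCD, following the study's within-patient analysis) and
#' applies Benjamini-Hochberg across the whole family (11 x 9 = 99 tests
#' for the full study layout).  Subjects with missing values are excluded
#' pairwise (logged via a message).
#'
#' @param mean_fa matrix subjects x tracts of per-subject tract mean FA
#'   (full cohort rows, see [tract_mean_fa_table()]).
#' @param records subject table aligned with `mean_fa` rows.
#' @param group group whose subjects are correlated.
#' @param q FDR level.
#' @param measures score column names (default `score_1..score_9`).
#' @return data.frame (tract, measure, n, r, p_raw, p_bh, significant)
#'   sorted by adjusted then raw p.
#' @export
correlate_tracts_measures <- function(mean_fa, records, group = "SCD",
                                      q = 0.05,
                                      measures = names(neurocognitive_measures())) {
  mean_fa <- as.matrix(mean_fa)
  if (nrow(mean_fa) != nrow(records))
    abort("mean_fa rows must match records", "tractsa_data_error")
  rows <- which(records$group == group)
  if (length(rows) < 3)
    abort("need n >= 3 subjects in the correlated group", "tractsa_stats_error")
  fa <- mean_fa[rows, , drop = FALSE]
  sc <- records[rows, measures, drop = FALSE]
  n_missing <- sum(!stats::complete.cases(sc))
  if (n_missing > 0)
    message(sprintf("%d subject(s) with missing scores excluded pairwise",
                    n_missing))
  grid <- expand.grid(measure = measures, tract = colnames(mean_fa),
                      stringsAsFactors = FALSE)[, c("tract", "measure")]
  res <- t(mapply(function(tn, mv) pearson_r(fa[, tn], sc[[mv]]),
                  grid$tract, grid$measure))
  bh <- bh_adjust(res[, "p"], q)
  out <- data.frame(tract = grid$tract, measure = grid$measure,
                    n = as.integer(res[, "n"]), r = res[, "r"],
                    p_raw = res[, "p"], p_bh = bh$adjusted,
                    significant = bh$reject,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p_bh, out$p_raw), ]
}
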