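# Vertex-wise general linear model: value ~ group + age + sex, returning
# the t statistic of the group coefficient at every skeleton vertex.

#' Build a two-group GLM design
#'
#' The design matrix has an intercept, an indicator of membership in
#' `groups[2]`, and optional age and sex nuisance covariates.  The group
#' coefficient therefore measures `groups[2] - groups[1]`; negative t means
#' the second group is lower.
#'
#' @param group factor/character of group labels.
#' @param groups length-2 character: the two levels to contrast, in order
#'   (group1, group2).
#' @param age optional numeric covariate (years).
#' @param sex optional factor/character; coded as an indicator of `"F"`.
#' @return object of class `glm_design` with fields `X` (design matrix),
#'   `group_col`, `df` (residual degrees of freedom), `groups`.
#' @export
glm_design <- function(group, groups = NULL, age = NULL, sex = NULL) {
  group <- as.character(group)
  groups <- groups %||% unique(group)
  if (length(groups) != 2)
    abort("exactly two group levels are contrasted", "tractsa_design_error")
  keep <- group %in% groups
  if (!all(keep))
    abort("subjects outside the contrasted groups; subset the data first",
          "tractsa_design_error")
  if (any(table(factor(group, levels = groups)) < 2))
    abort("each group needs n >= 2", "tractsa_design_error")
  X <- cbind(intercept = 1, group = as.numeric(group == groups[2]))
  if (!is.null(age)) X <- cbind(X, age = as.numeric(age))
  if (!is.null(sex)) X <- cbind(X, sexF = as.numeric(as.character(sex) == "F"))
  if (qr(X)$rank < ncol(X))
    abort("rank-deficient design matrix", "tractsa_design_error")
  structure(list(X = X, group_col = 2L, df = nrow(X) - ncol(X),
                 groups = groups),
            class = "glm_design")
}

# Precompute the closed-form pieces of the vertex-wise t statistic so that
# permutation loops only pay two small matrix products per draw:
#   beta_g = w Y,  SSR = colSums(Y^2) - colSums((Q'Y)^2),
#   t = beta_g / sqrt(cxx * SSR / df)
tstat_precompute <- function(design) {
  X <- design$X
  XtXi <- solve(crossprod(X))
  w <- (XtXi %*% t(X))[design$group_col, ]
  Q <- qr.Q(qr(X))
  list(w = w, Qt = t(Q), cxx = XtXi[design$group_col, design$group_col],
       df = design$df)
}

tstat_closed <- function(Y, pre) {
  beta <- drop(pre$w %*% Y)
  ssr <- pmax(0, colSums(Y^2) - colSums((pre$Qt %*% Y)^2))
  se <- sqrt(pre$cxx * ssr / pre$df)
  t <- ifelse(se > 0, beta / se, 0)
  attr(t, "zero_variance") <- which(se == 0)
  t
}

#' Vertex-wise t statistics for a group contrast
#'
#' Fits `value ~ group + covariates` at every vertex and returns the t
#' statistic of the group coefficient (positive when `groups[2]` is
#' higher).  Vertices with zero residual variance get t = 0 and are
#' listed in attribute `"zero_variance"`.
#'
#' @param dataset a [vertex_dataset()] or plain subjects x vertices matrix.
#' @param design a [glm_design()]; row order must match the dataset.
#' @return numeric vector of t values with attributes `"df"` and
#'   `"zero_variance"`.
#' @export
vertexwise_tstat <- function(dataset, design) {
  Y <- if (inherits(dataset, "vertex_dataset")) dataset$values else as.matrix(dataset)
  if (nrow(Y) != nrow(design$X))
    abort("dataset rows must match the design", "tractsa_design_error")
  t <- tstat_closed(Y, tstat_precompute(design))
  attr(t, "df") <- design$df
  t
}

#' Design from a subject table
#'
#' Convenience: subset records to two groups and build the matching design
#' and row index.
#'
#' @param records subject data.frame (columns group, age, sex).
#' @param groups length-2 character contrast, e.g. `c("CTL", "SCD")`.
#' @param covariates include age and sex as nuisance covariates.
#' @return list(design, rows) where `rows` indexes the retained subjects.
#' @export
design_from_records <- function(records, groups = c("CTL", "SCD"),
                                covariates = TRUE) {
  rows <- which(records$group %in% groups)
  r <- records[rows, , drop = FALSE]
  design <- if (covariates)
    glm_design(r$group, groups, age = r$age, sex = r$sex)
  else glm_design(r$group, groups)
  list(design = design, rows = rows)
}
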