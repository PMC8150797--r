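#' Levene's test of variance homogeneity
#'
#' Levene's test centered at the group mean (the convention of mainstream
#' statistical packages); `center = "median"` gives the Brown-Forsythe
#' variant.
#'
#' @param values_by_group Named list of numeric vectors, one per group.
#' @param center `"mean"` (default) or `"median"`.
#' @return List with `statistic`, `p`, `df1`, `df2`.
#' @export
levene_test <- function(values_by_group, center = c("mean", "median")) {
  center <- match.arg(center)
  check_groups(values_by_group, min_per_group = 2L)
  y <- unlist(values_by_group, use.names = FALSE)
  g <- factor(rep(names(values_by_group), lengths(values_by_group)))
  dev <- unlist(lapply(values_by_group, function(x)
    abs(x - if (center == "mean") mean(x) else median(x))))
  if (all(dev == 0))  # all groups constant: dispersions trivially equal
    return(list(statistic = 0, p = 1, df1 = length(values_by_group) - 1L,
                df2 = length(y) - length(values_by_group)))
  res <- car::leveneTest(y, g, center = if (center == "mean") mean else median)
  list(statistic = res[1, "F value"], p = res[1, "Pr(>F)"],
       df1 = res[1, "Df"], df2 = res[2, "Df"])
}

#' One-way analysis of variance
#'
#' Classical equal-variance one-way decomposition:
#' `F = (SSB/df1) / (SSW/df2)` with `df1 = k - 1`, `df2 = N - k`. Zero
#' within-group variance with unequal means yields `F = Inf`, `p = 0`.
#'
#' @inheritParams levene_test
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
anova_oneway <- function(values_by_group) {
  check_groups(values_by_group, min_per_group = 1L)
  k <- length(values_by_group)
  n <- sum(lengths(values_by_group))
  if (n <= k) stop("insufficient data: need total N > number of groups")
  df1 <- k - 1L; df2 <- n - k
  ssw <- sum(vapply(values_by_group,
                    function(x) sum((x - mean(x))^2), numeric(1)))
  gm <- mean(unlist(values_by_group, use.names = FALSE))
  ssb <- sum(vapply(values_by_group,
                    function(x) length(x) * (mean(x) - gm)^2, numeric(1)))
  if (ssw == 0) {
    if (ssb == 0) return(list(F = 0, df1 = df1, df2 = df2, p = 1))
    return(list(F = Inf, df1 = df1, df2 = df2, p = 0))
  }
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, df1 = df1, df2 = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Univariate Wilks' lambda
#'
#' `Lambda = SSW / SST`, the within-group share of the total sum of squares;
#' values near 0 indicate strong group-mean separation, and
#' `F = ((1 - Lambda)/Lambda) * (df2/df1)` recovers the one-way ANOVA F.
#' `SST = 0` returns 1 by convention (no information).
#'
#' @inheritParams levene_test
#' @return Wilks' lambda in (0, 1].
#' @export
wilks_lambda_univariate <- function(values_by_group) {
  check_groups(values_by_group, min_per_group = 1L)
  y <- unlist(values_by_group, use.names = FALSE)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(1)
  ssw <- sum(vapply(values_by_group,
                    function(x) sum((x - mean(x))^2), numeric(1)))
  ssw / sst
}

#' Screen peak variables for origin discrimination
#'
#' Two-stage statistical screening: every variable is first tested for
#' variance homogeneity across origin groups (Levene); only homogeneous
#' variables (`levene_p > alpha`) proceed to one-way ANOVA (with the
#' per-variable Wilks' lambda). A variable is flagged `significant` when it
#' is homogeneous and its ANOVA p-value is below `alpha`. Heterogeneous
#' variables are excluded from ANOVA entirely (no Welch fallback).
#'
#' @param table A labeled [peak_table] (>= 2 samples per origin).
#' @param alpha Significance level (default 0.05).
#' @param center Centering for Levene's test (see [levene_test]).
#' @param p_adjust `"none"` (default) or `"bonferroni"` adjustment of the
#'   ANOVA p-values.
#' @return A `screening_result`: data frame with one row per variable and
#'   columns `variable`, `levene_stat`, `levene_p`, `homogeneous`,
#'   `wilks_lambda`, `F`, `df1`, `df2`, `anova_p`, `significant`.
#' @export
screen_variables <- function(table, alpha = 0.05, center = "mean",
                             p_adjust = c("none", "bonferroni")) {
  p_adjust <- match.arg(p_adjust)
  table <- peak_table(table)
  if (anyNA(table$origin)) stop("screening requires origin labels on all rows")
  pv <- peak_vars(table)
  rows <- lapply(pv, function(v) {
    by_g <- split_by_origin(table, v)
    lev <- levene_test(by_g, center = center)
    hom <- lev$p > alpha
    if (hom) {
      aov1 <- anova_oneway(by_g)
      lam <- wilks_lambda_univariate(by_g)
    } else {
      aov1 <- list(F = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
                   p = NA_real_)
      lam <- NA_real_
    }
    data.frame(variable = v, levene_stat = lev$statistic, levene_p = lev$p,
               homogeneous = hom, wilks_lambda = lam, F = aov1$F,
               df1 = aov1$df1, df2 = aov1$df2, anova_p = aov1$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  p_use <- out$anova_p
  if (p_adjust == "bonferroni")
    p_use <- pmin(1, p_use * sum(!is.na(p_use)))
  out$significant <- out$homogeneous & !is.na(p_use) & p_use < alpha
  attr(out, "alpha") <- alpha
  class(out) <- c("screening_result", "data.frame")
  out
}

#' Variables flagged significant by [screen_variables]
#' @param screening A `screening_result`.
#' @return Character vector of variable labels.
#' @export
significant_variables <- function(screening) {
  screening$variable[screening$significant]
}

#' @export
print.screening_result <- function(x, digits = 4, ...) {
  cat(sprintf("Variable screening at alpha = %g\n", attr(x, "alpha")))
  cat(sprintf("  homogeneous: %d/%d; significant: %s\n",
              sum(x$homogeneous), nrow(x),
              paste(significant_variables(x), collapse = ", ")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Pearson correlation matrix of peak variables
#'
#' Descriptive correlations among variables across samples. Zero-variance
#' variables yield `NA` entries.
#'
#' @param table A [peak_table].
#' @param variables Variables to include (default all peak variables).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(table, variables = peak_vars(table)) {
  if (nrow(table) < 3L) stop("need at least 3 samples for correlations")
  x <- as.matrix(as.data.frame(table)[variables])
  suppressWarnings(stats::cor(x))
}

check_groups <- function(values_by_group, min_per_group = 2L) {
  if (!is.list(values_by_group) || length(values_by_group) < 2L)
    stop("need at least 2 groups")
  if (any(lengths(values_by_group) < min_per_group))
    stop(sprintf("insufficient data: every group needs >= %d values",
                 min_per_group))
  invisible(TRUE)
}
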