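#' One-way ANOVA F test
#'
#' Classic fixed-effects one-way ANOVA: `F = MS_between / MS_within` with
#' `(k - 1, N - k)` degrees of freedom.  When the within-group mean square
#' is exactly zero but group means differ, the sentinel `F = Inf, p = 0` is
#' returned; when all values are identical, `F = 0, p = 1`.
#'
#' @param values numeric vector.
#' @param groups group labels (coerced to factor); every level must have at
#'   least one observation.
#' @return list with `F`, `p`, `df1`, `df2`.
#' @export
#' @examples
#' anova_oneway(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
anova_oneway <- function(values, groups) {
  g <- if (is.factor(groups)) groups else factor(groups)
  if (any(table(g) == 0))
    stop("group with 0 observations: ",
         paste(levels(g)[table(g) == 0], collapse = ", "))
  k <- nlevels(g)
  if (k < 2) stop("need at least 2 groups")
  n <- length(values)
  if (n - k < 1) stop("need at least 1 residual degree of freedom")
  gm <- tapply(values, g, mean)
  ssb <- sum(table(g) * (gm - mean(values))^2)
  ssw <- sum((values - gm[g])^2)
  df1 <- k - 1; df2 <- n - k
  if (ssw == 0) {
    if (ssb == 0) return(list(F = 0, p = 1, df1 = df1, df2 = df2))
    return(list(F = Inf, p = 0, df1 = df1, df2 = df2))
  }
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, p = pf(f, df1, df2, lower.tail = FALSE), df1 = df1, df2 = df2)
}

#' Genotype and year contributions to trait variability
#'
#' Runs [anova_oneway()] per trait, once with genotype and once with
#' harvest year as the grouping factor.
#'
#' @param table trait table with `genotype` and `year` columns (each with
#'   at least 2 levels).
#' @param traits trait columns to test; defaults to the 16 texture traits.
#' @param alpha significance level for the flag.
#' @return data frame with columns `trait`, `factor`, `F`, `p`,
#'   `significant`.
#' @export
factor_contributions <- function(table, traits = NULL, alpha = 0.05) {
  if (is.null(traits))
    traits <- intersect(texture_trait_names(), names(table))
  if (length(unique(table$genotype)) < 2)
    stop("need at least 2 genotypes")
  if (length(unique(table$year)) < 2)
    stop("need at least 2 years")
  rows <- list()
  for (tr in traits) {
    for (fac in c("genotype", "year")) {
      a <- anova_oneway(table[[tr]], table[[fac]])
      rows[[length(rows) + 1L]] <- data.frame(
        trait = tr, factor = fac, F = a$F, p = a$p,
        significant = a$p < alpha, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
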