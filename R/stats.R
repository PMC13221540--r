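#' Inferential-statistics battery with effect sizes
#'
#' Thin, consistently-shaped wrappers around the classical tests the
#' pipeline reports — chi-square independence, one-way ANOVA with Tukey
#' HSD, pooled-variance t, Mann-Whitney U, Kruskal-Wallis H, Pearson r —
#' each augmented with the matching effect size (Cramer's V, eta squared,
#' Cohen's d, rank eta squared, r). No continuity correction is applied to
#' the chi-square statistic, and p-values are asymptotic throughout.
#'
#' @name stats-battery
NULL

new_test_result <- function(method, statistic, df, p_value, effect_size,
                            effect_type, extra = list()) {
  structure(
    c(list(method = method, statistic = unname(statistic), df = unname(df),
           p_value = unname(p_value), effect_size = unname(effect_size),
           effect_type = effect_type), extra),
    class = "dtc_test"
  )
}

#' @export
print.dtc_test <- function(x, ...) {
  df_txt <- paste(x$df, collapse = ", ")
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.3g, %s = %.4g\n",
              x$method, x$statistic, df_txt, x$p_value, x$effect_type,
              x$effect_size))
  invisible(x)
}

#' Cramer's V from a chi-square statistic
#'
#' `V = sqrt(chisq / (n * (min(r, c) - 1)))` — usable directly on printed
#' chi-square values.
#'
#' @param chisq Chi-square statistic (uncorrected).
#' @param n Total count.
#' @param nrow,ncol Table dimensions.
#' @return Cramer's V in \[0, 1\].
#' @export
cramers_v <- function(chisq, n, nrow = 2L, ncol = 2L) {
  sqrt(chisq / (n * (min(nrow, ncol) - 1L)))
}

#' Chi-square test of independence with Cramer's V
#'
#' @param table An r x c matrix/table of non-negative integer counts with
#'   positive row and column sums.
#' @return A `dtc_test` with effect type `"V"` and the expected-count
#'   matrix in `$expected`.
#' @export
chi_square_cramers_v <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || anyNA(table)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("degenerate table: zero row or column margin", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  v <- cramers_v(ht$statistic, sum(table), nrow(table), ncol(table))
  new_test_result("chi-square independence", ht$statistic, ht$parameter,
                  ht$p.value, v, "V",
                  extra = list(expected = ht$expected, n = sum(table)))
}

#' One-way ANOVA with eta squared and Tukey HSD
#'
#' `F = MSB/MSW`, `eta^2 = SSB/SST`; pairwise adjusted p-values from the
#' studentized-range distribution.
#'
#' @param groups List of numeric vectors, each of length >= 2.
#' @return A `dtc_test` with effect type `"eta_squared"` and the Tukey
#'   table in `$tukey`.
#' @export
anova_eta_tukey <- function(groups) {
  if (length(groups) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(lengths(groups) < 2L)) stop("every group needs n >= 2", call. = FALSE)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)))
  )
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  ssb <- tab["group", "Sum Sq"]
  ssw <- tab["Residuals", "Sum Sq"]
  eta2 <- ssb / (ssb + ssw)
  tukey <- as.data.frame(stats::TukeyHSD(fit)$group)
  new_test_result("one-way ANOVA", tab["group", "F value"],
                  c(tab["group", "Df"], tab["Residuals", "Df"]),
                  tab["group", "Pr(>F)"], eta2, "eta_squared",
                  extra = list(tukey = tukey))
}

#' Pooled-variance two-sample t-test with Cohen's d
#'
#' Student (pooled-variance) t; `d = (mean(a) - mean(b)) / pooled SD`.
#'
#' @param a,b Numeric samples, each n >= 2.
#' @return A `dtc_test` with effect type `"d"` (signed, a minus b).
#' @export
ttest_cohens_d <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("both samples need n >= 2", call. = FALSE)
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 == 0) stop("zero pooled variance", call. = FALSE)
  ht <- stats::t.test(a, b, var.equal = TRUE)
  d <- (mean(a) - mean(b)) / sqrt(sp2)
  new_test_result("pooled t-test", ht$statistic, ht$parameter, ht$p.value,
                  d, "d")
}

#' Mann-Whitney U test
#'
#' Tie-corrected normal-approximation p-value (no continuity correction);
#' the statistic is U for the first sample.
#'
#' @param a,b Non-empty numeric samples.
#' @return A `dtc_test` with effect type `"r"` (rank-biserial correlation
#'   `2U/(n_a n_b) - 1`).
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b)) stop("groups must be non-empty", call. = FALSE)
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
  )
  u <- unname(ht$statistic)
  rbc <- 2 * u / (length(a) * length(b)) - 1
  new_test_result("Mann-Whitney U", u, NA_integer_, ht$p.value, rbc, "r")
}

#' Kruskal-Wallis H test with rank eta squared
#'
#' Tie-corrected H with `eta^2_H = (H - k + 1) / (n - k)`.
#'
#' @param groups List of non-empty numeric vectors.
#' @return A `dtc_test` with effect type `"eta_squared_H"`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(lengths(groups) == 0L)) stop("groups must be non-empty", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1L) {
    stop("all values identical: H undefined", call. = FALSE)
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- stats::kruskal.test(values, g)
  k <- length(groups)
  n <- length(values)
  eta2 <- (unname(ht$statistic) - k + 1) / (n - k)
  new_test_result("Kruskal-Wallis H", ht$statistic, ht$parameter,
                  ht$p.value, eta2, "eta_squared_H")
}

#' Pearson correlation
#'
#' @param x,y Numeric vectors of equal length, n >= 3, nonzero variance.
#' @return A `dtc_test` with effect type `"r"`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance", call. = FALSE)
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  new_test_result("Pearson correlation", ht$statistic, ht$parameter,
                  ht$p.value, unname(ht$estimate), "r")
}
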