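# Longhand direct-definition oracles, kept independent of the wrappers.

oracle_chisq <- function(tab) {
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  x2 <- sum((tab - e)^2 / e)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(x2 = x2, df = df, p = stats::pchisq(x2, df, lower.tail = FALSE),
       v = sqrt(x2 / (n * (min(dim(tab)) - 1))))
}

oracle_anova <- function(groups) {
  all_v <- unlist(groups)
  gm <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  dfb <- length(groups) - 1
  dfw <- length(all_v) - length(groups)
  f <- (ssb / dfb) / (ssw / dfw)
  list(f = f, eta2 = ssb / (ssb + ssw),
       p = stats::pf(f, dfb, dfw, lower.tail = FALSE))
}

oracle_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, d = (mean(a) - mean(b)) / sqrt(sp2),
       p = 2 * stats::pt(-abs(t), na + nb - 2))
}

oracle_u <- function(a, b) {
  # brute-force pair counting with half-credit ties
  u <- 0
  for (x in a) u <- u + sum(x > b) + 0.5 * sum(x == b)
  n <- length(a) + length(b)
  ties <- table(c(a, b))
  sigma2 <- length(a) * length(b) / 12 *
    ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (u - length(a) * length(b) / 2) / sqrt(sigma2)
  list(u = u, p = 2 * stats::pnorm(-abs(z)))
}

oracle_h <- function(groups) {
  values <- unlist(groups)
  n <- length(values)
  r <- rank(values)
  idx <- rep(seq_along(groups), lengths(groups))
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, idx, sum)^2 / lengths(groups)) - 3 * (n + 1)
  ties <- table(values)
  h <- h / (1 - sum(ties^3 - ties) / (n^3 - n))
  k <- length(groups)
  list(h = h, p = stats::pchisq(h, k - 1, lower.tail = FALSE),
       eta2 = (h - k + 1) / (n - k))
}

oracle_r <- function(x, y) {
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((length(x) - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), length(x) - 2))
}

test_that("chi-square wrapper matches the direct-definition oracle", {
  # perfectly independent table: outer product -> zero statistic
  tab <- outer(c(20, 30), c(10, 40)) / 50
  res <- chi_square_cramers_v(tab)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$effect_size, 0, tolerance = 1e-9)

  set.seed(101)
  for (rep in 1:100) {
    tab <- matrix(stats::rpois(6, 20) + 1, 3, 2)
    res <- chi_square_cramers_v(tab)
    orc <- oracle_chisq(tab)
    expect_equal(res$statistic, orc$x2, tolerance = 1e-9)
    expect_equal(res$df, orc$df)
    expect_equal(res$p_value, orc$p, tolerance = 1e-9)
    expect_equal(res$effect_size, orc$v, tolerance = 1e-9)
  }
  expect_error(chi_square_cramers_v(matrix(c(0, 0, 3, 4), 2)), "degenerate")
})

test_that("Cramer's V equals |phi| on 2x2 tables", {
  set.seed(7)
  for (rep in 1:50) {
    tab <- matrix(stats::rpois(4, 15) + 1, 2, 2)
    v <- chi_square_cramers_v(tab)$effect_size
    phi <- (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1]) /
      sqrt(prod(rowSums(tab)) * prod(colSums(tab)))
    expect_equal(v, abs(phi), tolerance = 1e-9)
  }
})

test_that("ANOVA wrapper matches explicit sums of squares", {
  groups <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  res <- anova_eta_tukey(groups)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$effect_size, 0, tolerance = 1e-12)

  set.seed(33)
  for (rep in 1:100) {
    groups <- lapply(1:3, function(i) stats::rnorm(sample(5:15, 1), mean = i / 2))
    res <- anova_eta_tukey(groups)
    orc <- oracle_anova(groups)
    expect_equal(res$statistic, orc$f, tolerance = 1e-9)
    expect_equal(res$effect_size, orc$eta2, tolerance = 1e-9)
    expect_equal(res$p_value, orc$p, tolerance = 1e-9)
  }
  expect_error(anova_eta_tukey(list(1, c(1, 2))), "n >= 2")
  # Tukey table covers all pairs
  res <- anova_eta_tukey(list(a = rnorm(5), b = rnorm(5), c = rnorm(5)))
  expect_equal(nrow(res$tukey), 3L)
})

test_that("eta squared from the published F and df reproduces 0.004", {
  eta2 <- 2 * 128.94 / (2 * 128.94 + 58130)
  expect_equal(round(eta2, 3), 0.004)
})

test_that("pooled t wrapper matches the textbook formula", {
  expect_error(ttest_cohens_d(c(2, 2, 2), c(2, 2, 2)), "zero pooled variance")
  # identical samples: t = 0, d = 0
  a <- c(1, 2, 3, 4)
  res <- ttest_cohens_d(a, a)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$effect_size, 0, tolerance = 1e-12)

  # shift by exactly one pooled SD (constructed): |d| = 1
  a <- c(1, 2, 3, 4, 5)
  sp <- sqrt(stats::var(a))  # pooled SD of a and a-shift is var(a)
  res <- ttest_cohens_d(a + sp, a)
  expect_equal(res$effect_size, 1, tolerance = 1e-9)

  set.seed(44)
  for (rep in 1:100) {
    a <- stats::rnorm(sample(5:20, 1))
    b <- stats::rnorm(sample(5:20, 1), 0.3)
    res <- ttest_cohens_d(a, b)
    orc <- oracle_t(a, b)
    expect_equal(res$statistic, orc$t, tolerance = 1e-9)
    expect_equal(res$effect_size, orc$d, tolerance = 1e-9)
    expect_equal(res$p_value, orc$p, tolerance = 1e-9)
  }
})

test_that("Mann-Whitney matches brute-force pair counting", {
  a <- c(1, 3, 5, 7)
  expect_equal(mann_whitney(a, a)$statistic, length(a)^2 / 2)
  expect_equal(mann_whitney(c(1, 2, 3), c(10, 11))$statistic, 0)
  expect_equal(mann_whitney(c(10, 11), c(1, 2, 3))$statistic, 6)

  set.seed(55)
  for (rep in 1:100) {
    a <- sample(1:10, sample(4:12, 1), replace = TRUE)  # ties on purpose
    b <- sample(1:10, sample(4:12, 1), replace = TRUE)
    res <- mann_whitney(a, b)
    orc <- oracle_u(a, b)
    expect_equal(res$statistic, orc$u, tolerance = 1e-9)
    expect_equal(res$p_value, orc$p, tolerance = 1e-9)
  }
})

test_that("Kruskal-Wallis matches explicit ranking and errors on constants", {
  set.seed(66)
  for (rep in 1:100) {
    groups <- lapply(1:3, function(i) sample(1:15, sample(4:10, 1),
                                             replace = TRUE))
    res <- kruskal_wallis(groups)
    orc <- oracle_h(groups)
    expect_equal(res$statistic, orc$h, tolerance = 1e-9)
    expect_equal(res$p_value, orc$p, tolerance = 1e-9)
    expect_equal(res$effect_size, orc$eta2, tolerance = 1e-9)
  }
  expect_error(kruskal_wallis(list(c(2, 2), c(2, 2))), "identical")
})

test_that("two-group rank tests agree and F equals t squared", {
  set.seed(77)
  for (rep in 1:30) {
    a <- stats::rnorm(12)
    b <- stats::rnorm(15, 0.4)
    # tie-free data: Kruskal-Wallis p equals the Mann-Whitney normal p
    expect_equal(kruskal_wallis(list(a, b))$p_value,
                 mann_whitney(a, b)$p_value, tolerance = 1e-6)
    # exact identity between pooled t and one-way ANOVA
    expect_equal(anova_eta_tukey(list(a, b))$statistic,
                 ttest_cohens_d(a, b)$statistic^2, tolerance = 1e-9)
  }
})

test_that("Pearson wrapper matches the covariance formula", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, 2 * x + 1)$effect_size, 1, tolerance = 1e-12)
  expect_equal(pearson_r(x, -x)$effect_size, -1, tolerance = 1e-12)
  expect_error(pearson_r(x, rep(2, 5)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "n >= 3")

  set.seed(88)
  for (rep in 1:100) {
    x <- stats::rnorm(30)
    y <- 0.5 * x + stats::rnorm(30)
    res <- pearson_r(x, y)
    orc <- oracle_r(x, y)
    expect_equal(res$effect_size, orc$r, tolerance = 1e-9)
    expect_equal(res$p_value, orc$p, tolerance = 1e-9)
  }
})
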