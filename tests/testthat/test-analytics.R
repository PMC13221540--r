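rlex <- defaultReactionLexicon()

test_that("reaction prevalence uses all posts as denominator", {
  g <- suppressMessages(generate_corpus(generator_config(n_posts = 10, seed = 4,
    reaction_rates = c(surprise = 0, dispute = 0.3, acceptance = 0,
                       disappointment = 0, identity_crisis = 0,
                       excitement = 0))))
  corp <- annotate_reactions(g$corpus, rlex)
  prev <- reaction_prevalence(corp)
  n_disp <- sum(flags_matrix(corp)[, "dispute"])
  expect_equal(prev$percent[prev$reaction == "dispute"], 100 * n_disp / 10)
  expect_equal(sum(prev$n[prev$reaction != "dispute"]), 0L)
  # the published worked ratio
  expect_equal(round(100 * 5546 / 58133, 1), 9.5)
  expect_equal(nrow(reaction_prevalence(corp[0, ])), 0L)

  by_pf <- reaction_prevalence(corp, by_platform = TRUE)
  agg <- by_pf |> dplyr::group_by(reaction) |> dplyr::summarise(n = sum(n))
  expect_equal(sort(agg$n), sort(prev$n))
})

test_that("company mentions use whole-token alias matching", {
  expect_equal(company_mentions("my 23andme kit arrived"), "23andMe")
  expect_equal(company_mentions("tried 23 and me last year"), "23andMe")
  expect_equal(company_mentions("the ancestry of the word"), character())
  expect_setequal(company_mentions("MyHeritage vs 23andMe"),
                  c("23andMe", "MyHeritage"))
  prev <- company_prevalence(tiny_corpus())
  expect_equal(prev$n[prev$company == "23andMe"], 1L)
})

test_that("dispute rates are post-level, thresholded and sorted", {
  # build a corpus where dispute flags and mentions are fully controlled
  n <- 120
  texts <- character(n)
  for (i in 1:n) {
    parts <- c()
    if (i <= 100) parts <- c(parts, "Turkish 40%")
    if (i <= 100 && i %% 2 == 0) parts <- c(parts, "Turkish: 10%")  # duplicate category
    if (i <= 25) parts <- c(parts, "German 20%")
    if (i <= 20) parts <- c(parts, "this is wrong")                 # dispute keyword
    if (i > 100) parts <- c(parts, "Cherokee 15%")                  # 20 posts, none disputed
    texts[i] <- paste(parts, collapse = ". ")
  }
  corp <- annotate_reactions(as_corpus(tibble::tibble(
    id = sprintf("d%03d", 1:n), platform = "synthetic", text = texts
  )), rlex)
  ann <- annotate_ancestry(corp)
  dr <- dispute_rate_by_ancestry(corp, ann$mentions, min_mentions = 20)
  # turkish: 100 posts (duplicates collapse), 20 disputed -> 20%
  expect_equal(dr$total[dr$category == "turkish"], 100L)
  expect_equal(dr$rate[dr$category == "turkish"], 20)
  # german: 25 posts, 20 disputed -> 80%
  expect_equal(dr$rate[dr$category == "german"], 80)
  # native_american: 20 posts, 0 disputed -> 0%
  expect_equal(dr$rate[dr$category == "native_american"], 0)
  expect_identical(dr$rate, sort(dr$rate, decreasing = TRUE))
  expect_true(all(dr$disputed <= dr$total))
  expect_true(all(dr$rate >= 0 & dr$rate <= 100))
  # raising the threshold drops german (25 < 30) but keeps turkish
  dr30 <- dispute_rate_by_ancestry(corp, ann$mentions, min_mentions = 30)
  expect_false("german" %in% dr30$category)
  # re-filtering the unthresholded table reproduces the thresholded one
  dr0 <- dispute_rate_by_ancestry(corp, ann$mentions, min_mentions = 1)
  refiltered <- dr0[dr0$total >= 20, ]
  expect_equal(as.data.frame(refiltered), as.data.frame(dr))
  # the published worked ratio
  expect_equal(round(100 * 20 / 85, 1), 23.5)
})

test_that("concordance uses set intersection with exclusion of one-sided posts", {
  self <- tibble::tibble(id = c("a", "a", "b", "d"),
                         category = c("irish", "german", "german", "han"))
  genetic <- tibble::tibble(id = c("a", "a", "b", "c"),
                            category = c("irish", "italian", "british", "irish"))
  out <- concordance_analysis(self, genetic)
  expect_equal(out$summary$n, 2L)      # c and d lack one side
  expect_equal(out$summary$matches, 1L)
  expect_equal(out$summary$percent, 50)
  recs <- out$records
  expect_equal(recs$match[recs$id == "a"], 1L)
  expect_equal(recs$match[recs$id == "b"], 0L)
  expect_equal(out$summary$percent,
               100 * out$summary$matches / out$summary$n)
})

test_that("concordance on generated data tracks the configured probability", {
  g <- suppressMessages(generate_corpus(generator_config(
    n_posts = 3000, seed = 31, p_self_given_ancestry = 0.6)))
  ann <- annotate_ancestry(g$corpus)
  out <- concordance_analysis(ann$self_reported, ann$mentions)
  p <- 0.618
  se <- sqrt(p * (1 - p) / out$summary$n)
  expect_lt(abs(out$summary$percent / 100 - p), 3 * se)
  # and the analysis agrees with the generator's own record
  expect_equal(out$summary$matches, sum(g$truth$concordance$concordant))
})
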