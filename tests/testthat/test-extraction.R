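lex <- defaultEthnicityLexicon()

test_that("the three percentage formats are extracted", {
  out <- extract_ancestry_percentages("I got 45% Irish and 30% Italian")
  expect_equal(out$raw_term, c("Irish", "Italian"))
  expect_equal(out$percent, c(45, 30))

  out <- extract_ancestry_percentages("Scandinavian: 18.5% overall")
  expect_equal(out$raw_term, "Scandinavian")
  expect_equal(out$percent, 18.5)

  out <- extract_ancestry_percentages("Native American 25% on my mother's side")
  expect_equal(out$raw_term, "Native American")
  expect_equal(out$percent, 25)

  expect_equal(nrow(extract_ancestry_percentages("we are 110% sure")), 0L)
  expect_equal(nrow(extract_ancestry_percentages("no numbers here")), 0L)
  expect_equal(nrow(extract_ancestry_percentages("")), 0L)
})

test_that("percent grammar handles decimals, ranges and leading <", {
  expect_equal(extract_ancestry_percentages("German 12.75%")$percent, 12.75)
  expect_equal(extract_ancestry_percentages("Irish 20-30%")$percent, 25)
  expect_equal(extract_ancestry_percentages("<5% Basque")$percent, 5)
  expect_equal(extract_ancestry_percentages("Basque <5%")$percent, 5)
})

test_that("extracted percents lie in (0, 100] with non-overlapping spans", {
  texts <- c(
    "0% Irish and 101% Welsh and 100% Han",
    "45% Irish, Italian: 30% and German 12%.",
    "The report shows 33.3% Ashkenazi Jewish and Cherokee 10%.",
    "50%% weird 20 % Thai"
  )
  for (tx in texts) {
    out <- extract_ancestry_percentages(tx)
    expect_true(all(out$percent > 0 & out$percent <= 100))
  }
})

test_that("normalization is case-insensitive, trimmed and idempotent", {
  expect_equal(normalize_ethnicity("Yoruba", lex), "nigerian")
  expect_equal(normalize_ethnicity("welsh", lex), "british")
  expect_equal(normalize_ethnicity("  Persian ", lex), "iranian")
  expect_true(is.na(normalize_ethnicity("Klingon", lex)))
  # idempotence through category ids
  for (cat_id in lex$categories$category) {
    expect_equal(normalize_ethnicity(cat_id, lex), cat_id)
  }
})

test_that("profiles collapse duplicate categories but sum all percents", {
  p <- build_profile(tibble::tibble(category = c("irish", "italian"),
                                    percent = c(45, 30)))
  expect_equal(p$n_categories, 2L)
  expect_equal(p$total_percent, 75)
  expect_equal(p$top_percent, 45)

  p <- build_profile(tibble::tibble(category = character(),
                                    percent = numeric()))
  expect_equal(unlist(p), c(n_categories = 0, total_percent = 0,
                            top_percent = 0))

  # collapse rule against a brute-force distinct-count oracle
  set.seed(7)
  for (rep in 1:20) {
    cats <- sample(c("irish", "german", "han", NA), sample(1:6, 1),
                   replace = TRUE)
    pct <- round(runif(length(cats), 1, 60), 1)
    p <- build_profile(tibble::tibble(category = cats, percent = pct))
    expect_equal(p$n_categories, length(unique(cats[!is.na(cats)])))
    expect_equal(p$total_percent, sum(pct))
    expect_equal(p$top_percent, max(pct))
  }
  p <- build_profile(tibble::tibble(category = c("irish", "irish"),
                                    percent = c(40, 10)))
  expect_equal(p$n_categories, 1L)
  expect_equal(p$total_percent, 50)
  expect_equal(p$top_percent, 40)
})

test_that("the six self-identity patterns extract and normalize", {
  expect_equal(extract_self_reported("I'm Irish and Italian", lex),
               c("irish", "italian"))
  expect_equal(extract_self_reported("I identify as Persian", lex), "iranian")
  expect_equal(extract_self_reported("My family were Yoruba.", lex),
               "nigerian")
  expect_equal(extract_self_reported("I was born in Turkey.", lex), "turkish")
  expect_equal(extract_self_reported("My heritage is Ashkenazi Jewish", lex),
               "jewish")
  expect_equal(extract_self_reported("I'm Italian American.", lex), "italian")
  expect_equal(extract_self_reported("The weather is Irish-ish", lex),
               character())
  expect_equal(extract_self_reported("I'm excited about all of it", lex),
               character())
})

test_that("annotate_ancestry zero-fills profiles for mention-free posts", {
  ann <- annotate_ancestry(tiny_corpus(), lex)
  expect_equal(nrow(ann$profiles), 5L)
  p4 <- ann$profiles[ann$profiles$id == "p4", ]
  expect_equal(p4$n_categories, 0L)
  expect_equal(p4$top_percent, 0)
  p1 <- ann$profiles[ann$profiles$id == "p1", ]
  expect_equal(p1$n_categories, 2L)
  expect_equal(p1$total_percent, 75)
  expect_true(all(c("irish", "italian") %in%
                    ann$self_reported$category[ann$self_reported$id == "p3"]))
})

test_that("extraction recovers all planted mentions and identities", {
  g <- suppressMessages(generate_corpus(generator_config(n_posts = 600,
                                                         seed = 12)))
  ann <- annotate_ancestry(g$corpus, lex)
  key <- function(d) paste(d$id, d$category, d$percent)
  expect_true(all(key(g$truth$mentions) %in% key(ann$mentions)))
  keyS <- function(d) paste(d$id, d$category)
  expect_true(all(keyS(g$truth$self_reported) %in% keyS(ann$self_reported)))
  # and nothing spurious is normalized
  expect_true(all(keyS(ann$self_reported) %in% keyS(g$truth$self_reported)))
})
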