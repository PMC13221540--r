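rlex <- defaultReactionLexicon()

test_that("keyword classification flags the right categories", {
  f <- classify_reactions("I was shocked - no way this is right", rlex)
  expect_equal(unname(f[c("surprise", "dispute")]), c(1L, 1L))
  expect_equal(sum(f), 2L)

  f <- classify_reactions("makes sense, exactly what I expected", rlex)
  expect_equal(unname(f[["acceptance"]]), 1L)
  expect_equal(sum(f), 1L)

  expect_equal(sum(classify_reactions("Bought a kit yesterday", rlex)), 0L)
  # word-boundary rule: "scam" must not fire inside "scampi"
  expect_equal(sum(classify_reactions("scampi recipe", rlex)), 0L)
})

test_that("classification is invariant to case and surrounding whitespace", {
  texts <- c("ShOcKeD  by it", "  shocked by it  ", "shocked\nby it")
  flags <- lapply(texts, classify_reactions, lexicon = rlex)
  for (f in flags) expect_equal(f, flags[[1]])
})

test_that("apostrophe variants both match", {
  expect_equal(classify_reactions("i don't believe this", rlex)[["dispute"]], 1L)
  expect_equal(classify_reactions("i dont believe this", rlex)[["dispute"]], 1L)
  expect_equal(classify_reactions("i don’t believe this", rlex)[["dispute"]], 1L)
})

test_that("co-occurrence summary matches brute-force pairwise counts", {
  corp <- annotate_reactions(tiny_corpus(), rlex)
  co <- reaction_cooccurrence(corp)
  expect_equal(co$mean_per_post, sum(flags_matrix(corp)) / nrow(corp))

  g <- suppressMessages(generate_corpus(generator_config(n_posts = 10, seed = 2,
    reaction_rates = c(surprise = .5, dispute = .5, acceptance = .5,
                       disappointment = .5, identity_crisis = .5,
                       excitement = .5))))
  corp <- annotate_reactions(g$corpus, rlex)
  m <- flags_matrix(corp)
  co <- reaction_cooccurrence(corp)
  brute <- matrix(0L, 6, 6)
  for (i in 1:6) for (j in 1:6) brute[i, j] <- sum(m[, i] * m[, j])
  expect_equal(unname(as.matrix(co$cooccurrence)), brute)
  expect_true(isSymmetric(unname(as.matrix(co$cooccurrence))))

  empty <- annotate_reactions(tiny_corpus()[4, ], rlex)
  expect_equal(reaction_cooccurrence(empty)$mean_per_post, 0)
})

test_that("stratified sampling is deterministic, capped and topped up", {
  g <- suppressMessages(generate_corpus(generator_config(n_posts = 2000, seed = 3,
    reaction_rates = c(surprise = .05, dispute = .05, acceptance = .05,
                       disappointment = .05, identity_crisis = .005,
                       excitement = .05))))
  corp <- annotate_reactions(g$corpus, rlex)
  s1 <- suppressMessages(stratified_validation_sample(corp, seed = 9))
  s2 <- suppressMessages(stratified_validation_sample(corp, seed = 9))
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 300L)
  expect_false(anyDuplicated(s1$id) > 0)
  # thin stratum is taken in full, with a logged shortfall
  n_ic <- sum(flags_matrix(corp)[, "identity_crisis"])
  if (n_ic < 35) {
    expect_message(
      s <- stratified_validation_sample(corp, seed = 9),
      "identity_crisis"
    )
    expect_lte(sum(s$stratum == "identity_crisis"), n_ic)
  }
  expect_error(stratified_validation_sample(corp[0, ], seed = 1), "empty")
})

test_that("confusion metrics match the published worked examples", {
  m <- confusion_metrics(51, 3, 2, 243)
  expect_equal(round(m$precision, 3), 0.944)
  expect_equal(round(m$recall, 3), 0.962)
  expect_equal(round(m$f1, 3), 0.953)
  expect_equal(round(m$kappa, 3), 0.943)

  m <- confusion_metrics(58, 17, 2, 222)
  expect_equal(round(m$kappa, 3), 0.819)
  expect_equal(round(m$f1, 3), 0.859)
})

test_that("degenerate confusion counts return undefined sentinels", {
  m <- confusion_metrics(0, 0, 0, 10)
  expect_true(is.na(m$precision))
  expect_true(is.na(m$kappa))
  expect_equal(m$accuracy, 1)
  expect_error(confusion_metrics(0, 0, 0, 0), "zero")
})

test_that("kappa never exceeds accuracy when chance agreement is positive", {
  set.seed(11)
  for (rep in 1:200) {
    counts <- as.list(stats::rpois(4, 8))
    names(counts) <- c("tp", "fp", "fn", "tn")
    if (sum(unlist(counts)) == 0) next
    m <- do.call(confusion_metrics, counts)
    if (!is.na(m$kappa)) expect_lte(m$kappa, m$accuracy + 1e-12)
  }
})

test_that("micro metrics equal the metrics of the summed confusion matrix", {
  set.seed(21)
  for (rep in 1:20) {
    counts <- tibble::tibble(
      category = reactionCategories(),
      tp = stats::rpois(6, 30), fp = stats::rpois(6, 8),
      fn = stats::rpois(6, 5), tn = 0L
    )
    counts$tn <- pmax(0L, 300L - counts$tp - counts$fp - counts$fn)
    rep_out <- suppressMessages(validation_report(counts))
    pooled <- confusion_metrics(sum(counts$tp), sum(counts$fp),
                                sum(counts$fn), sum(counts$tn))
    expect_equal(rep_out$micro$precision, pooled$precision)
    expect_equal(rep_out$micro$f1, pooled$f1)
    expect_equal(rep_out$overall_accuracy, pooled$accuracy)
    # macro = unweighted means of the defined per-category metrics
    expect_equal(rep_out$macro$f1, mean(rep_out$per_category$f1, na.rm = TRUE))
  }
})

test_that("validation_report rejects inconsistent sample sizes", {
  counts <- published_validation_counts()
  counts$tn[1] <- counts$tn[1] + 1L
  expect_error(validation_report(counts), "inconsistent")
})

test_that("annotation files drop incomplete rows", {
  path <- tempfile(fileext = ".csv")
  df <- tibble::tibble(id = c("a", "b", "c"))
  for (cat_id in reactionCategories()) df[[cat_id]] <- c(1L, NA, 0L)
  readr::write_csv(df, path)
  expect_message(ann <- read_annotations(path), "1 incomplete")
  expect_equal(ann$id, c("a", "c"))
})

test_that("classifier validation against noise-free labels is perfect", {
  g <- suppressMessages(generate_corpus(generator_config(n_posts = 400, seed = 5)))
  corp <- annotate_reactions(g$corpus, rlex)
  labels <- generate_annotation_labels(g$truth$flags, noise = 0, seed = 1)
  rep_out <- suppressMessages(validate_classifier(corp, labels))
  defined <- !is.na(rep_out$per_category$kappa)
  expect_true(all(rep_out$per_category$precision[defined] == 1))
  expect_true(all(rep_out$per_category$recall[defined] == 1))
  expect_equal(rep_out$overall_accuracy, 1)
})
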