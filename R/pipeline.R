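#' End-to-end pipeline
#'
#' Chains the analysis stages in dependency order — extraction,
#' classification, sentiment, descriptive analytics, inferential
#' statistics, topic modeling, dispute modeling — over an ingested or
#' generated corpus, returning every result table and optionally writing
#' them to disk with a provenance header (config and lexicon hashes).
#' Rerunning with identical inputs and seeds reproduces deterministic
#' stages bit-identically.
#'
#' @name pipeline
NULL

#' Write a result table with a provenance header
#'
#' The header is a single `#`-prefixed comment line carrying the pipeline
#' provenance hashes; [read_result_table()] skips it.
#'
#' @param df Data frame to write.
#' @param path Output CSV path.
#' @param provenance Named list hashed into the header.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path, provenance = list()) {
  header <- sprintf("# dtcreactions provenance %s",
                    paste(sprintf("%s=%s", names(provenance),
                                  unlist(provenance)), collapse = " "))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con), add = TRUE)
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  tibble::as_tibble(utils::read.csv(path, comment.char = "#",
                                    stringsAsFactors = FALSE))
}

#' Run the full pipeline
#'
#' @param corpus A `dtc_corpus` (e.g. from [read_corpus()] or
#'   [generate_corpus()]).
#' @param out_dir Optional output directory for result tables; created if
#'   missing. Partial outputs are preserved when a stage fails.
#' @param ethnicity_lexicon,reaction_lexicon,company_lexicon Lexicon
#'   resources (defaults: the shipped lexicons).
#' @param seed Integer seed driving the stochastic stages (topic
#'   initialization, fold assignment).
#' @param k,lda_iterations Topic model hyperparameters.
#' @param min_mentions Dispute-rate table threshold.
#' @param min_df Minimum document frequency for the topic-model DTM
#'   (lowered automatically for very small corpora).
#' @param folds Cross-validation folds for the dispute model.
#' @return List of class `pipeline_result` with the annotated corpus and
#'   every stage's tables.
#' @export
run_pipeline <- function(corpus, out_dir = NULL,
                         ethnicity_lexicon = defaultEthnicityLexicon(),
                         reaction_lexicon = defaultReactionLexicon(),
                         company_lexicon = defaultCompanyLexicon(),
                         seed = 1L, k = 8L, lda_iterations = 15L,
                         min_mentions = 20L, min_df = 10L, folds = 5L) {
  stopifnot(inherits(corpus, "dtc_corpus"))
  provenance <- list(
    config = object_hash(list(seed = seed, k = k, lda_iterations = lda_iterations,
                              min_mentions = min_mentions, folds = folds)),
    ethnicity_lexicon = object_hash(ethnicity_lexicon),
    reaction_lexicon = object_hash(reaction_lexicon)
  )
  results <- list(provenance = provenance)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(df, name) {
    if (!is.null(out_dir)) {
      write_result_table(df, file.path(out_dir, paste0(name, ".csv")),
                         provenance)
    }
    df
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  results$composition <- run_stage("ingest", emit(corpus_composition(corpus),
                                                  "composition"))
  run_stage("extract", {
    anc <- annotate_ancestry(corpus, ethnicity_lexicon)
    results$mentions <- emit(anc$mentions, "mentions")
    results$profiles <- emit(anc$profiles, "profiles")
    results$self_reported <- emit(anc$self_reported, "self_reported")
  })
  run_stage("classify", {
    corpus <- annotate_reactions(corpus, reaction_lexicon)
  })
  run_stage("sentiment", {
    corpus <- annotate_sentiment(corpus)
  })
  run_stage("analytics", {
    results$prevalence <- emit(reaction_prevalence(corpus), "prevalence")
    results$prevalence_by_platform <-
      emit(reaction_prevalence(corpus, by_platform = TRUE),
           "prevalence_by_platform")
    results$companies <- emit(company_prevalence(corpus, company_lexicon),
                               "companies")
    results$dispute_rates <-
      emit(dispute_rate_by_ancestry(corpus, results$mentions, min_mentions),
           "dispute_rates")
    conc <- concordance_analysis(results$self_reported, results$mentions)
    results$concordance <- conc$summary
    results$cooccurrence <- reaction_cooccurrence(corpus)
  })
  run_stage("stats", {
    results$stat_tests <- emit(pipeline_stat_battery(corpus, results$profiles),
                                "stat_tests")
    results$triangulation <- sentiment_triangulation(corpus)
  })
  run_stage("topics", {
    eff_min_df <- min(min_df, max(2L, nrow(corpus) %/% 50L))
    dtm <- build_dtm(corpus$text, min_df = eff_min_df)
    model <- fit_lda(dtm$dtm, k = k, iterations = lda_iterations, seed = seed)
    results$topic_model <- model
    results$topic_terms <- emit(top_terms(model), "topic_terms")
    results$sentiment_by_topic <-
      emit(sentiment_by_topic(model, corpus$compound), "sentiment_by_topic")
  })
  run_stage("model", {
    feats <- build_features(corpus, results$profiles)
    has_anc <- results$profiles$id[results$profiles$n_categories > 0]
    sel <- feats$id %in% has_anc
    labels <- reaction_flag_matrix(corpus)[, "dispute"][sel]
    if (sum(labels == 1L) >= folds && sum(labels == 0L) >= folds) {
      results$dispute_model <- fit_dispute_model(feats[sel, ], labels,
                                                  folds = folds, seed = seed)
    } else {
      log_info("dispute model skipped: too few labelled posts per class")
    }
  })
  results$corpus <- corpus
  structure(results, class = "pipeline_result")
}

# The standard inferential battery over an annotated corpus: platform x
# reaction chi-squares, ancestry-presence chi-squares, platform sentiment
# ANOVA, per-reaction sentiment t/Mann-Whitney, and sentiment-measure
# correlations, in one tidy table.
pipeline_stat_battery <- function(corpus, profiles) {
  rows <- list()
  add <- function(test, grouping, res) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      test = test, grouping = grouping,
      statistic = res$statistic, df = paste(res$df, collapse = ";"),
      p_value = res$p_value, effect_size = res$effect_size,
      effect_type = res$effect_type
    )
  }
  m <- reaction_flag_matrix(corpus)
  has_anc <- as.integer(profiles$n_categories[match(corpus$id, profiles$id)] > 0)
  for (cat_id in c("surprise", "dispute")) {
    tab <- table(factor(has_anc, levels = 0:1), factor(m[, cat_id], levels = 0:1))
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      add("chi_square", paste0("ancestry_x_", cat_id), chi_square_cramers_v(tab))
    }
  }
  platforms <- unique(corpus$platform)
  if (length(platforms) > 1) {
    for (cat_id in REACTION_CATEGORIES) {
      tab <- table(corpus$platform, factor(m[, cat_id], levels = 0:1))
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
        add("chi_square", paste0("platform_x_", cat_id),
            chi_square_cramers_v(tab))
      }
    }
    groups <- split(corpus$compound, corpus$platform)
    if (all(lengths(groups) >= 2)) {
      add("anova", "compound_by_platform", anova_eta_tukey(groups))
    }
  }
  for (cat_id in REACTION_CATEGORIES) {
    a <- corpus$compound[m[, cat_id] == 1L]
    b <- corpus$compound[m[, cat_id] == 0L]
    if (length(a) >= 2 && length(b) >= 2 && (stats::sd(a) > 0 || stats::sd(b) > 0)) {
      add("t_test", paste0("compound_by_", cat_id), ttest_cohens_d(a, b))
      add("mann_whitney", paste0("compound_by_", cat_id), mann_whitney(a, b))
    }
  }
  if (stats::sd(corpus$compound) > 0 && stats::sd(corpus$polarity) > 0) {
    add("pearson", "compound_vs_polarity",
        pearson_r(corpus$compound, corpus$polarity))
  }
  dplyr::bind_rows(rows)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  posts:", nrow(x$corpus), "\n")
  cat("  tables:", paste(setdiff(names(x), c("corpus", "provenance")),
                         collapse = ", "), "\n")
  invisible(x)
}
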