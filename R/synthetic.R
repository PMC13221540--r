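#' Synthetic corpus generation with known ground truth
#'
#' Generates corpora that emulate consumer posts about DTC ancestry
#' results — planted reaction keywords, ancestry percentages rendered in
#' the three extraction formats, identity statements in the six self-ID
#' formats, a platform mix, concordance structure between self-reported
#' and genetic categories, and sentiment-valence coupling — with every
#' planted fact recorded, so each pipeline stage can be tested against
#' ground truth. Filler text is screened against all lexicons so planted
#' labels are exact.
#'
#' @name synthetic
NULL

FILLER_BANK <- c(
  "The kit arrived after about two weeks.",
  "I sent the sample back the same day.",
  "Waiting for the lab to process everything took a while.",
  "My cousin took the same test last year.",
  "The app updated the report again this month.",
  "I uploaded the raw data for another look.",
  "The regional map has more detail than before.",
  "Customer support replied within a few days.",
  "The family tree tool keeps suggesting new records.",
  "I spent the weekend going through old census pages.",
  "The breakdown changed slightly after the update.",
  "My sister has slightly different numbers than me.",
  "The video walkthrough explains each section of the report.",
  "I compared notes with a friend who tested elsewhere.",
  "The subscription renews next month.",
  "Reading through the forum threads took all evening.",
  "The report groups the regions by continent.",
  "I printed the summary for my grandparents.",
  "The estimate updates as the reference panels grow.",
  "Logging in on the new phone took a few tries."
)

POSITIVE_FILLER <- c(
  "Overall this was a great experience and I enjoyed the process.",
  "The whole thing felt pleasant and the report was helpful.",
  "What a nice touch that summary page is, truly great work.",
  "I felt grateful and pleased reading through it.",
  "Such fun to explore, a genuinely good product."
)

NEGATIVE_FILLER <- c(
  "The wait felt terrible and the site kept freezing.",
  "Honestly a frustrating and stressful process from start to finish.",
  "The awful interface made the evening worse.",
  "It left me sad and upset for days.",
  "What a bad experience with the upload step."
)

REACTION_TEMPLATES <- c(
  "Honestly %s about all this.",
  "That part left me %s for sure.",
  "Reading it felt %s to me.",
  "Still %s days later."
)

# Country/location surface terms usable by the born/raised-in identity
# pattern, keyed by category.
SELF_LOCATIONS <- c(
  irish = "Ireland", german = "Germany", italian = "Italy",
  turkish = "Turkey", greek = "Greece", chinese = "China",
  indian = "India", nigerian = "Nigeria", iranian = "Iran",
  mexican = "Mexico", japanese = "Japan", korean = "Korea",
  vietnamese = "Vietnam", brazilian = "Brazil", french = "France",
  spanish = "Spain", portuguese = "Portugal"
)

default_ancestry_weights <- function(lexicon = defaultEthnicityLexicon()) {
  cats <- lexicon$categories$category
  w <- stats::setNames(rep(20, length(cats)), cats)
  named <- c(british = 621, native_american = 374, scandinavian = 356,
             italian = 300, irish = 298, jewish = 289, german = 219,
             middle_eastern = 149, indian = 132, chinese = 107,
             turkish = 85, greek = 76)
  w[names(named)] <- named
  w / sum(w)
}

default_dispute_boost <- function(lexicon = defaultEthnicityLexicon()) {
  cats <- lexicon$categories$category
  b <- stats::setNames(rep(1, length(cats)), cats)
  named <- c(turkish = 2.73, greek = 2.29, scandinavian = 2.15,
             middle_eastern = 2.10, irish = 2.02, italian = 1.90,
             german = 1.76, british = 1.60, indian = 1.23, chinese = 0.87)
  b[names(named)] <- named
  b
}

#' Generator configuration
#'
#' Defaults encode the study conditions the pipeline is meant to emulate:
#' the observed platform mix, per-category reaction base rates, a 7.5%
#' rate of posts carrying percentage results with a mean of 2.3 mentioned
#' categories summing to roughly 94% per post, a 1.7% marginal
#' self-report rate concentrated on result posts, 61.8% concordance
#' between self-reported and genetic categories, and per-ancestry dispute
#' multipliers shaped like the observed dispute-rate table.
#'
#' @param n_posts Number of posts to generate.
#' @param seed Integer RNG seed; generation is deterministic per seed.
#' @param platform_mix Named probabilities over platforms, summing to 1.
#' @param reaction_rates Named per-category Bernoulli rates.
#' @param p_ancestry Probability a post carries percentage results.
#' @param ancestry_distribution Named weights over the 42 categories.
#' @param mean_extra_categories Poisson mean for categories beyond the
#'   first in a result post (1 + Poisson gives the per-post count).
#' @param percent_total_mean,percent_total_sd Target mean/SD of a result
#'   post's summed percentages.
#' @param p_self_report Marginal probability of an identity statement.
#' @param p_self_given_ancestry Conditional self-report probability for
#'   result posts (concentrates the self-report/result overlap).
#' @param p_concordant Probability the self set intersects the genetic
#'   set, for posts carrying both.
#' @param dispute_ancestry_boost Named per-category multipliers on the
#'   dispute rate (`NULL` for no boost).
#' @param p_company Probability a post mentions a testing company.
#' @param sentiment_coupling Insert positive/negative filler so that
#'   excitement posts score above dispute posts.
#' @param lexicon Ethnicity lexicon used for category ids and display
#'   terms.
#' @param reaction_lexicon Reaction lexicon phrases are planted from.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_posts = 5000L,
                             seed = 1L,
                             platform_mix = c(reddit = 40000, youtube = 17133,
                                              googleplay = 1000) / 58133,
                             reaction_rates = c(surprise = 0.053,
                                                dispute = 0.086,
                                                acceptance = 0.095,
                                                disappointment = 0.036,
                                                identity_crisis = 0.023,
                                                excitement = 0.094),
                             p_ancestry = 0.075,
                             ancestry_distribution = NULL,
                             mean_extra_categories = 1.3,
                             percent_total_mean = 94.2,
                             percent_total_sd = 4,
                             p_self_report = 0.017,
                             p_self_given_ancestry = 0.04,
                             p_concordant = 0.618,
                             dispute_ancestry_boost = NULL,
                             p_company = 0.09,
                             sentiment_coupling = TRUE,
                             lexicon = defaultEthnicityLexicon(),
                             reaction_lexicon = defaultReactionLexicon()) {
  if (is.null(ancestry_distribution)) {
    ancestry_distribution <- default_ancestry_weights(lexicon)
  }
  if (is.null(dispute_ancestry_boost)) {
    dispute_ancestry_boost <- default_dispute_boost(lexicon)
  }
  cfg <- list(
    n_posts = as.integer(n_posts), seed = as.integer(seed),
    platform_mix = platform_mix, reaction_rates = reaction_rates,
    p_ancestry = p_ancestry, ancestry_distribution = ancestry_distribution,
    mean_extra_categories = mean_extra_categories,
    percent_total_mean = percent_total_mean,
    percent_total_sd = percent_total_sd,
    p_self_report = p_self_report,
    p_self_given_ancestry = p_self_given_ancestry,
    p_concordant = p_concordant,
    dispute_ancestry_boost = dispute_ancestry_boost,
    p_company = p_company,
    sentiment_coupling = isTRUE(sentiment_coupling),
    lexicon = lexicon, reaction_lexicon = reaction_lexicon
  )
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  probs <- c(cfg$p_ancestry, cfg$p_self_report, cfg$p_self_given_ancestry,
             cfg$p_concordant, cfg$p_company, cfg$reaction_rates,
             cfg$platform_mix)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(cfg$platform_mix) - 1) > 1e-9) {
    stop("platform_mix must sum to 1", call. = FALSE)
  }
  if (!setequal(names(cfg$reaction_rates), REACTION_CATEGORIES)) {
    stop("reaction_rates must name the six categories", call. = FALSE)
  }
  if (cfg$n_posts < 1L) stop("n_posts must be positive", call. = FALSE)
  bad <- setdiff(names(cfg$ancestry_distribution),
                 cfg$lexicon$categories$category)
  if (length(bad)) stop("unknown ancestry categories in distribution", call. = FALSE)
  invisible(cfg)
}

# Phrases safe to plant for a category: those the classifier maps to
# exactly that category (e.g. "never expected" also triggers acceptance's
# "expected" and is excluded from the planting bank).
planting_banks <- function(reaction_lexicon) {
  lapply(stats::setNames(REACTION_CATEGORIES, REACTION_CATEGORIES), function(cat_id) {
    phrases <- reaction_lexicon[[cat_id]]
    keep <- vapply(phrases, function(p) {
      flags <- classify_reactions(p, reaction_lexicon)
      sum(flags) == 1L && flags[[cat_id]] == 1L
    }, logical(1))
    phrases[keep]
  })
}

# Display variants a category can be rendered with (title-cased surface
# terms of <= 2 tokens that normalize back to the category; the canonical
# display name always included).
display_variants <- function(lexicon) {
  cats <- lexicon$categories
  lapply(stats::setNames(cats$category, cats$category), function(cat_id) {
    terms <- names(lexicon$terms)[lexicon$terms == cat_id]
    terms <- terms[lengths(strsplit(terms, " ")) <= 2]
    disp <- cats$display[cats$category == cat_id]
    unique(c(disp, tools::toTitleCase(terms)))
  })
}

render_percent <- function(value, decimal) {
  if (decimal) sprintf("%.1f", value) else sprintf("%d", as.integer(round(value)))
}

# Render a set of (term, percent) mentions in the three reporting formats.
render_mentions <- function(terms, pct_strings, formats) {
  clause <- vapply(seq_along(terms), function(i) {
    switch(formats[i],
           sprintf("%s%% %s", pct_strings[i], terms[i]),
           sprintf("%s: %s%%", terms[i], pct_strings[i]),
           sprintf("%s %s%%", terms[i], pct_strings[i]))
  }, character(1))
  body <- if (length(clause) > 1) {
    paste0(paste(clause[-length(clause)], collapse = ", "), " and ",
           clause[length(clause)])
  } else clause
  paste0("The report shows ", body, ".")
}

render_self_statement <- function(categories, variants, pattern_id) {
  term_of <- function(cat_id) sample(variants[[cat_id]], 1)
  first <- categories[1]
  switch(pattern_id,
    { # I'm / I am [ethnicity] (possibly multi-identity)
      terms <- vapply(categories, term_of, character(1))
      joined <- paste(terms, collapse = " and ")
      sample(c(sprintf("I'm %s.", joined), sprintf("I am %s.", joined)), 1)
    },
    sprintf("I identify as %s.", term_of(first)),
    sample(c(sprintf("My family are %s.", term_of(first)),
             sprintf("My family were %s.", term_of(first))), 1),
    sample(c(sprintf("I was born in %s.", SELF_LOCATIONS[[first]]),
             sprintf("I was raised in %s.", SELF_LOCATIONS[[first]])), 1),
    sample(c(sprintf("My heritage is %s.", term_of(first)),
             sprintf("My ethnicity is %s.", term_of(first))), 1),
    { # I'm [ethnicity] American (single-token display only)
      disp <- term_of(first)
      sprintf("I'm %s American.", disp)
    }
  )
}

#' Generate a synthetic corpus with ground truth
#'
#' @param config A `generator_config`.
#' @return List with `corpus` (a `dtc_corpus`, platform tag from the
#'   configured mix) and `truth`: `flags` (tibble id x six reaction
#'   columns), `mentions` (id, category, percent), `self_reported`
#'   (id, category), `concordance` (id, concordant) for posts carrying
#'   both, and `config`.
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  lex <- config$lexicon
  banks <- planting_banks(config$reaction_lexicon)
  if (any(lengths(banks) == 0L)) {
    stop("a reaction category has no plantable phrase", call. = FALSE)
  }
  variants <- display_variants(lex)
  cats_all <- lex$categories$category
  weights <- stats::setNames(rep(0, length(cats_all)), cats_all)
  weights[names(config$ancestry_distribution)] <- config$ancestry_distribution
  boost <- stats::setNames(rep(1, length(cats_all)), cats_all)
  boost[names(config$dispute_ancestry_boost)] <- config$dispute_ancestry_boost
  # categories renderable by the suffix pattern ("I'm Irish American.")
  single_word_disp <- cats_all[vapply(cats_all, function(cc) {
    !grepl(" ", lex$categories$display[lex$categories$category == cc])
  }, logical(1))]
  p_self_no_anc <- if (config$p_ancestry < 1) {
    max(0, min(1, (config$p_self_report -
                     config$p_ancestry * config$p_self_given_ancestry) /
                 (1 - config$p_ancestry)))
  } else config$p_self_given_ancestry

  n <- config$n_posts
  base_time <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC")

  out <- with_local_seed(config$seed, {
    platforms <- sample(names(config$platform_mix), n, replace = TRUE,
                        prob = config$platform_mix)
    texts <- character(n)
    flags_m <- matrix(0L, n, 6, dimnames = list(NULL, REACTION_CATEGORIES))
    mention_rows <- vector("list", n)
    self_rows <- vector("list", n)
    conc_rows <- vector("list", n)
    engagement <- stats::rpois(n, 5)

    for (i in seq_len(n)) {
      pieces <- sample(FILLER_BANK, sample(1:2, 1))
      has_anc <- stats::runif(1) < config$p_ancestry
      anc_cats <- character()
      if (has_anc) {
        n_cat <- min(1L + stats::rpois(1, config$mean_extra_categories), 8L)
        anc_cats <- sample(cats_all, n_cat, prob = weights)
        total <- min(100, max(30, stats::rnorm(1, config$percent_total_mean,
                                               config$percent_total_sd)))
        raw <- stats::rgamma(n_cat, 5, 1)
        pcts <- raw / sum(raw) * total
        decimal <- stats::runif(n_cat) < 0.2
        pct_str <- vapply(seq_len(n_cat), function(j) {
          render_percent(max(pcts[j], if (decimal[j]) 0.5 else 1), decimal[j])
        }, character(1))
        pct_val <- as.numeric(pct_str)
        terms <- vapply(anc_cats, function(cc) sample(variants[[cc]], 1),
                        character(1))
        formats <- sample(1:3, n_cat, replace = TRUE)
        pieces <- c(pieces, render_mentions(terms, pct_str, formats))
        mention_rows[[i]] <- tibble::tibble(
          id = sprintf("syn%06d", i), category = anc_cats, percent = pct_val
        )
      }
      p_self <- if (has_anc) config$p_self_given_ancestry else p_self_no_anc
      if (stats::runif(1) < p_self) {
        if (has_anc) {
          concordant <- stats::runif(1) < config$p_concordant
          self_cats <- if (concordant) {
            base <- sample(anc_cats, 1)
            if (stats::runif(1) < 0.3) {
              c(base, sample(setdiff(cats_all, anc_cats), 1))
            } else base
          } else {
            sample(setdiff(cats_all, anc_cats),
                   1L + (stats::runif(1) < 0.3))
          }
          conc_rows[[i]] <- tibble::tibble(id = sprintf("syn%06d", i),
                                           concordant = as.integer(concordant))
        } else {
          self_cats <- sample(cats_all, 1L + (stats::runif(1) < 0.3),
                              prob = weights)
        }
        pattern_pool <- c(1L, 2L, 3L, 5L)
        if (length(self_cats) == 1L) {
          if (self_cats[1] %in% names(SELF_LOCATIONS)) {
            pattern_pool <- c(pattern_pool, 4L)
          }
          if (self_cats[1] %in% single_word_disp) {
            pattern_pool <- c(pattern_pool, 6L)
          }
        } else {
          pattern_pool <- 1L  # multi-identity renders through I'm/I am
        }
        pattern_id <- if (length(pattern_pool) == 1L) pattern_pool else {
          sample(pattern_pool, 1)
        }
        stmt <- if (pattern_id == 6L) {
          sprintf("I'm %s American.",
                  lex$categories$display[lex$categories$category == self_cats[1]])
        } else {
          render_self_statement(self_cats, variants, pattern_id)
        }
        pieces <- c(pieces, stmt)
        self_rows[[i]] <- tibble::tibble(id = sprintf("syn%06d", i),
                                         category = self_cats)
      }
      # reactions: dispute rate boosted through one focal mentioned
      # ancestry (uniformly drawn), so each category's marginal dispute
      # rate stays monotone in its configured boost despite co-mentions
      p_dispute <- config$reaction_rates[["dispute"]]
      if (length(anc_cats)) {
        focal <- if (length(anc_cats) == 1L) anc_cats else sample(anc_cats, 1)
        p_dispute <- min(0.95, p_dispute * boost[[focal]])
      }
      rates <- config$reaction_rates[REACTION_CATEGORIES]
      rates[["dispute"]] <- p_dispute
      planted <- stats::runif(6) < rates
      flags_m[i, ] <- as.integer(planted)
      for (cat_id in REACTION_CATEGORIES[planted]) {
        phrase <- sample(banks[[cat_id]], 1)
        pieces <- c(pieces, sprintf(sample(REACTION_TEMPLATES, 1), phrase))
      }
      if (config$sentiment_coupling) {
        if (planted[match("excitement", REACTION_CATEGORIES)]) {
          pieces <- c(pieces, sample(POSITIVE_FILLER, 1))
        }
        if (planted[match("dispute", REACTION_CATEGORIES)] ||
            planted[match("disappointment", REACTION_CATEGORIES)]) {
          pieces <- c(pieces, sample(NEGATIVE_FILLER, 1))
        }
      }
      if (stats::runif(1) < config$p_company) {
        company <- sample(names(defaultCompanyLexicon()), 1)
        pieces <- c(pieces, sprintf("I tested with %s this time.", company))
      }
      texts[i] <- paste(pieces, collapse = " ")
    }

    corpus <- as_corpus(
      tibble::tibble(
        id = sprintf("syn%06d", seq_len(n)),
        platform = platforms,
        text = texts,
        author = sprintf("user%04d", 1L + (seq_len(n) %% 997L)),
        timestamp = base_time + 60 * seq_len(n),
        engagement = as.integer(engagement)
      ),
      provenance = list(generator = "dtcreactions synthetic_data",
                        seed = config$seed, n_posts = n)
    )
    flags <- tibble::as_tibble(flags_m)
    flags <- tibble::add_column(flags, id = corpus$id, .before = 1)
    list(
      corpus = corpus,
      truth = list(
        flags = flags,
        mentions = dplyr::bind_rows(mention_rows),
        self_reported = dplyr::bind_rows(self_rows),
        concordance = dplyr::bind_rows(conc_rows),
        config = config
      )
    )
  })
  out
}

#' Generate surrogate human annotation labels
#'
#' Human-label surrogate: the true reaction flags with independent
#' per-category flips at the given noise rates. With zero noise, the
#' validation harness reports perfect agreement by construction.
#'
#' @param truth_flags Tibble (`id` + six 0/1 columns) as produced in the
#'   `truth$flags` slot of [generate_corpus()].
#' @param noise Single flip probability or named per-category vector.
#' @param seed Integer RNG seed.
#' @return Tibble with the same shape as `truth_flags`.
#' @export
generate_annotation_labels <- function(truth_flags, noise = 0, seed = 1L) {
  if (length(noise) == 1L) {
    noise <- stats::setNames(rep(noise, 6), REACTION_CATEGORIES)
  }
  stopifnot(all(REACTION_CATEGORIES %in% names(truth_flags)))
  out <- truth_flags
  with_local_seed(seed, {
    for (cat_id in REACTION_CATEGORIES) {
      flip <- stats::runif(nrow(out)) < noise[[cat_id]]
      out[[cat_id]] <- ifelse(flip, 1L - out[[cat_id]], out[[cat_id]])
    }
  })
  out
}
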