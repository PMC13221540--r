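#' Corpus-level descriptive analytics
#'
#' Reaction prevalence (overall and by platform), company mentions,
#' dispute-rate-by-ancestry with a minimum-mention threshold, and
#' self-reported versus genetic ancestry concordance.
#'
#' @name analytics
NULL

#' Reaction prevalence
#'
#' Percentages use all posts as the denominator, not only flagged posts.
#'
#' @param corpus A corpus annotated with reaction flags.
#' @param by_platform Split counts by source platform.
#' @return Tibble with `reaction`, `n`, `percent` (plus `platform` when
#'   split). Empty corpus gives an empty table.
#' @export
reaction_prevalence <- function(corpus, by_platform = FALSE) {
  if (!nrow(corpus)) {
    return(tibble::tibble(reaction = character(), n = integer(),
                          percent = numeric()))
  }
  m <- reaction_flag_matrix(corpus)
  if (!by_platform) {
    return(tibble::tibble(
      reaction = REACTION_CATEGORIES,
      n = as.integer(colSums(m)),
      percent = as.numeric(100 * colSums(m) / nrow(corpus))
    ))
  }
  out <- lapply(unique(corpus$platform), function(pf) {
    sel <- corpus$platform == pf
    tibble::tibble(
      platform = pf,
      reaction = REACTION_CATEGORIES,
      n = as.integer(colSums(m[sel, , drop = FALSE])),
      percent = as.numeric(100 * colSums(m[sel, , drop = FALSE]) / sum(sel))
    )
  })
  dplyr::bind_rows(out)
}

#' Companies mentioned in a text
#'
#' Case-insensitive whole-token alias matching (multi-word aliases such as
#' "23 and me" match across single spaces).
#'
#' @param text A single string.
#' @param lexicon A `company_lexicon`.
#' @return Character vector of canonical company names mentioned.
#' @export
company_mentions <- function(text, lexicon = defaultCompanyLexicon()) {
  if (is.na(text) || !nzchar(text)) return(character())
  prepped <- prepare_match_text(text)
  hits <- vapply(lexicon, function(aliases) {
    pattern <- paste0("(?:", paste(vapply(aliases, compile_phrase, character(1)),
                                   collapse = "|"), ")")
    grepl(pattern, prepped, perl = TRUE)
  }, logical(1))
  names(lexicon)[hits]
}

#' Company mention counts over a corpus
#'
#' @param corpus A `dtc_corpus`.
#' @param lexicon A `company_lexicon`.
#' @return Tibble with `company`, `n`, `percent` of all posts.
#' @export
company_prevalence <- function(corpus, lexicon = defaultCompanyLexicon()) {
  prepped <- prepare_match_text(corpus$text)
  counts <- vapply(lexicon, function(aliases) {
    pattern <- paste0("(?:", paste(vapply(aliases, compile_phrase, character(1)),
                                   collapse = "|"), ")")
    sum(grepl(pattern, prepped, perl = TRUE))
  }, integer(1))
  tibble::tibble(
    company = names(lexicon),
    n = as.integer(counts),
    percent = if (nrow(corpus)) 100 * counts / nrow(corpus) else numeric(length(counts))
  ) |>
    dplyr::arrange(dplyr::desc(.data$n))
}

#' Dispute rate by ancestry category
#'
#' For each normalized ancestry category mentioned in at least
#' `min_mentions` posts, the percentage of those posts that also carry the
#' dispute flag. A post counts once per distinct category it mentions,
#' regardless of how many percentages it reports for that category.
#'
#' @param corpus A corpus annotated with reaction flags.
#' @param mentions Mention table (`id`, `category`, ...) from
#'   [annotate_ancestry()].
#' @param min_mentions Minimum mentioning posts for a row (default 20).
#' @return Tibble with `category`, `total`, `disputed`, `rate` (percent),
#'   sorted by rate descending.
#' @export
dispute_rate_by_ancestry <- function(corpus, mentions, min_mentions = 20L) {
  empty <- tibble::tibble(category = character(), total = integer(),
                          disputed = integer(), rate = numeric())
  if (!nrow(mentions)) return(empty)
  dispute <- tibble::tibble(
    id = corpus$id,
    dispute = reaction_flag_matrix(corpus)[, "dispute"]
  )
  post_cat <- mentions |>
    dplyr::filter(!is.na(.data$category)) |>
    dplyr::distinct(.data$id, .data$category)
  if (!nrow(post_cat)) return(empty)
  post_cat |>
    dplyr::left_join(dispute, by = "id") |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(total = dplyr::n(),
                     disputed = sum(.data$dispute), .groups = "drop") |>
    dplyr::filter(.data$total >= min_mentions) |>
    dplyr::mutate(rate = 100 * .data$disputed / .data$total) |>
    dplyr::arrange(dplyr::desc(.data$rate))
}

#' Self-reported versus genetic ancestry concordance
#'
#' Restricted to posts with both a non-empty self-reported category set
#' and a non-empty genetic (extracted-mention) category set; a post is
#' concordant iff the two sets intersect. Reported percentages are
#' ignored; only category presence matters.
#'
#' @param self_reported Tibble (`id`, `category`) of self-reported
#'   categories.
#' @param mentions Tibble (`id`, `category`, ...) of extracted genetic
#'   mentions.
#' @return List with `records` (tibble: id, self, genetic, match) and
#'   `summary` (list: n, matches, percent).
#' @export
concordance_analysis <- function(self_reported, mentions) {
  genetic <- mentions |>
    dplyr::filter(!is.na(.data$category)) |>
    dplyr::distinct(.data$id, .data$category)
  self <- self_reported |>
    dplyr::filter(!is.na(.data$category)) |>
    dplyr::distinct(.data$id, .data$category)
  both <- intersect(unique(self$id), unique(genetic$id))
  if (!length(both)) {
    return(list(
      records = tibble::tibble(id = character(), self = list(),
                               genetic = list(), match = integer()),
      summary = list(n = 0L, matches = 0L, percent = NA_real_)
    ))
  }
  records <- lapply(both, function(pid) {
    s <- self$category[self$id == pid]
    g <- genetic$category[genetic$id == pid]
    tibble::tibble(id = pid, self = list(sort(s)), genetic = list(sort(g)),
                   match = as.integer(length(intersect(s, g)) > 0))
  })
  records <- dplyr::bind_rows(records)
  list(
    records = records,
    summary = list(
      n = nrow(records),
      matches = sum(records$match),
      percent = 100 * sum(records$match) / nrow(records)
    )
  )
}
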