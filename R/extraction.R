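#' Ancestry percentage and self-reported ethnicity extraction
#'
#' Three pattern variants capture the common formats in which consumers
#' report DTC ancestry results — `"[percentage]% [ethnicity]"`,
#' `"[ethnicity]: [percentage]%"`, and `"[ethnicity] [percentage]%"` —
#' and six anchored patterns capture explicit self-identity statements.
#' Extracted surface terms are normalized into the 42 standardized
#' ethnicity categories via the normalization lexicon.
#'
#' @name extraction
NULL

# Function words that can never be (part of) an ethnicity term. Used to
# stop the 1-3-token ethnicity capture at conjunctions, pronouns, verbs
# and common result-talk nouns, so "I got 45% Irish and 30% Italian"
# yields "Irish" and "Italian" rather than clause fragments.
ETHNICITY_STOPWORDS <- c(
  "i", "we", "you", "they", "he", "she", "it", "me", "us", "them",
  "am", "is", "are", "was", "were", "be", "been", "being",
  "a", "an", "the", "and", "or", "but", "of", "in", "on", "at", "to",
  "for", "with", "my", "your", "our", "their", "his", "her", "its",
  "got", "get", "gets", "have", "has", "had", "came", "come", "went",
  "show", "shows", "showed", "showing", "say", "says", "said",
  "report", "reported", "scored", "about", "around", "roughly",
  "approximately", "nearly", "almost", "exactly", "only", "just",
  "like", "than", "that", "this", "these", "those", "as", "so", "not",
  "no", "over", "under", "up", "out", "down", "back", "sure", "now",
  "then", "there", "here", "some", "more", "less", "most", "least",
  "total", "overall", "percent", "percentage", "result", "results",
  "dna", "test", "tests", "ancestry", "heritage", "blood", "descent",
  "roots", "side", "genes", "ethnicity", "background", "from", "by",
  "all", "also", "even", "still", "which", "what", "when", "where"
)

PCT_PATTERN <- "<?\\s*([0-9]{1,3}(?:\\.[0-9]+)?)(?:\\s*-\\s*([0-9]{1,3}(?:\\.[0-9]+)?))?\\s*%"

ALPHA_TOKEN_PATTERN <- "[A-Za-z][A-Za-z]+|[A-Za-z]"

# Parse the numeric value of a matched percent span: plain number,
# "<number" treated as the bare number, "lo-hi" ranges as the midpoint.
parse_percent <- function(span) {
  span <- gsub("[<%\\s]", "", span, perl = TRUE)
  if (grepl("-", span, fixed = TRUE)) {
    parts <- suppressWarnings(as.numeric(strsplit(span, "-", fixed = TRUE)[[1]]))
    return(mean(parts))
  }
  suppressWarnings(as.numeric(span))
}

# Tokenize text into alphabetic tokens with character positions.
alpha_tokens <- function(text) {
  regex_scan(text, ALPHA_TOKEN_PATTERN, ignore_case = TRUE)
}

#' Extract reported ancestry percentages from free text
#'
#' Scans percent tokens left to right and, for each, attempts the three
#' format variants in a longest/most-specific-first order: ethnicity before
#' a colon, ethnicity immediately before the percent, ethnicity after the
#' percent. The ethnicity capture takes one to three word tokens, stopping
#' at punctuation, conjunctions and other function words. Overlapping
#' candidates are resolved left to right (consumed spans are not reused).
#' Percent values support decimals, a leading `<` (treated as the bare
#' number) and `lo-hi` ranges (midpoint); values outside (0, 100] are
#' discarded.
#'
#' @param text A single string (may be empty).
#' @return Tibble with `raw_term` and `percent`, one row per extracted
#'   mention, empty when there is no match.
#' @export
extract_ancestry_percentages <- function(text) {
  empty <- tibble::tibble(raw_term = character(), percent = numeric())
  if (is.na(text) || !nzchar(text) || !grepl("%", text, fixed = TRUE)) {
    return(empty)
  }
  pcts <- regex_scan(text, PCT_PATTERN)
  if (!nrow(pcts)) return(empty)
  toks <- alpha_tokens(text)
  tok_text <- if (nrow(toks)) substring(text, toks$start, toks$end) else character()
  tok_low <- tolower(tok_text)
  is_stop <- tok_low %in% ETHNICITY_STOPWORDS
  consumed_until <- 0L  # rightmost text position already claimed

  # Gap between two positions must be pure spacing for tokens to chain.
  plain_gap <- function(a, b) {
    if (b <= a + 1L) return(TRUE)
    grepl("^[ \t]*$", substring(text, a + 1L, b - 1L))
  }

  results <- list()
  for (i in seq_len(nrow(pcts))) {
    p_start <- pcts$start[i]
    p_end <- pcts$end[i]
    if (p_start <= consumed_until) next
    value <- parse_percent(substring(text, p_start, p_end))
    if (is.na(value) || value <= 0 || value > 100) {
      consumed_until <- max(consumed_until, p_end)
      next
    }
    term <- NULL
    span_start <- p_start
    span_end <- p_end

    # Variant "[ethnicity]: [percentage]%": a colon directly precedes.
    pre <- sub("\\s+$", "", substring(text, 1, p_start - 1L))
    if (grepl(":$", pre)) {
      colon_pos <- nchar(pre)
      got <- collect_tokens_backward(toks, tok_low, is_stop, colon_pos,
                                     consumed_until, text)
      if (length(got$idx)) {
        term <- paste(tok_text[got$idx], collapse = " ")
        span_start <- toks$start[got$idx[1]]
      }
    }
    # Variant "[ethnicity] [percentage]%": tokens directly before, spaces only.
    if (is.null(term)) {
      got <- collect_tokens_backward(toks, tok_low, is_stop, p_start,
                                     consumed_until, text)
      if (length(got$idx) &&
          plain_gap(toks$end[got$idx[length(got$idx)]], p_start)) {
        term <- paste(tok_text[got$idx], collapse = " ")
        span_start <- toks$start[got$idx[1]]
      }
    }
    # Variant "[percentage]% [ethnicity]": tokens directly after.
    if (is.null(term)) {
      got <- collect_tokens_forward(toks, tok_low, is_stop, p_end, text)
      if (length(got$idx)) {
        term <- paste(tok_text[got$idx], collapse = " ")
        span_end <- toks$end[got$idx[length(got$idx)]]
      }
    }
    if (!is.null(term)) {
      results[[length(results) + 1L]] <-
        tibble::tibble(raw_term = term, percent = value)
      consumed_until <- max(consumed_until, span_end)
    } else {
      consumed_until <- max(consumed_until, p_end)
    }
  }
  if (!length(results)) return(empty)
  dplyr::bind_rows(results)
}

# Collect up to 3 chainable non-stopword tokens ending just before `pos`
# (scanning right to left); tokens must be separated by spaces only and lie
# beyond the already-consumed region.
collect_tokens_backward <- function(toks, tok_low, is_stop, pos,
                                    consumed_until, text) {
  idx <- integer()
  limit <- pos
  cand <- which(toks$end < pos)
  for (step in seq_len(3L)) {
    j <- cand[toks$end[cand] < limit]
    if (!length(j)) break
    j <- j[length(j)]
    gap <- substring(text, toks$end[j] + 1L, limit - 1L)
    if (!grepl("^[ \t]*$", gap)) break
    if (is_stop[j] || toks$start[j] <= consumed_until) break
    idx <- c(j, idx)
    limit <- toks$start[j]
  }
  list(idx = idx)
}

# Collect up to 3 chainable non-stopword tokens starting just after `pos`.
collect_tokens_forward <- function(toks, tok_low, is_stop, pos, text) {
  idx <- integer()
  limit <- pos
  for (step in seq_len(3L)) {
    j <- which(toks$start > limit)
    if (!length(j)) break
    j <- j[1]
    gap <- substring(text, limit + 1L, toks$start[j] - 1L)
    if (!grepl("^[ \t]*$", gap)) break
    if (is_stop[j]) break
    idx <- c(idx, j)
    limit <- toks$end[j]
  }
  list(idx = idx)
}

#' Normalize an ethnicity surface term
#'
#' Whole-term case-insensitive lookup (after trimming and whitespace
#' collapsing) in the normalization lexicon; unknown terms give `NA`.
#' Normalization is idempotent through category ids: a category's
#' canonical name normalizes to itself.
#'
#' @param raw_term Character vector of surface terms.
#' @param lexicon An `ethnicity_lexicon`.
#' @return Character vector of category ids (`NA` where unknown).
#' @export
normalize_ethnicity <- function(raw_term, lexicon = defaultEthnicityLexicon()) {
  key <- tolower(squish(raw_term))
  out <- unname(lexicon$terms[key])
  # canonical ids normalize to themselves even if absent as surface terms
  miss <- is.na(out) & key %in% lexicon$categories$category
  out[miss] <- key[miss]
  out
}

#' Extract and normalize ancestry mentions from one post
#'
#' @param text A single string.
#' @param lexicon An `ethnicity_lexicon`.
#' @return Tibble with `raw_term`, `category` (`NA` when normalization
#'   failed), and `percent`.
#' @export
extract_ancestry_mentions <- function(text, lexicon = defaultEthnicityLexicon()) {
  out <- extract_ancestry_percentages(text)
  out$category <- if (nrow(out)) normalize_ethnicity(out$raw_term, lexicon) else character()
  out[, c("raw_term", "category", "percent")]
}

#' Build an ancestry profile from normalized mentions
#'
#' Duplicate categories within one post are collapsed for the category
#' count, but every mention's percent contributes to the total;
#' `top_percent` is the maximum single-mention percent (0 when there are
#' no mentions).
#'
#' @param mentions Tibble with `category` and `percent` columns (as from
#'   [extract_ancestry_mentions()]).
#' @return List with `n_categories`, `total_percent`, `top_percent`.
#' @export
build_profile <- function(mentions) {
  if (is.null(mentions) || !nrow(mentions)) {
    return(list(n_categories = 0L, total_percent = 0, top_percent = 0))
  }
  cats <- mentions$category[!is.na(mentions$category)]
  list(
    n_categories = length(unique(cats)),
    total_percent = sum(mentions$percent),
    top_percent = max(mentions$percent)
  )
}

# -- self-reported ethnicity --------------------------------------------------

SELF_ID_ANCHORS <- c(
  first_person  = "\\bI(?:'m|\\s+am)\\s+",
  identify      = "\\bI\\s+identify\\s+as\\s+",
  family        = "\\bmy\\s+family\\s+(?:are|were|is|was)\\s+",
  born_raised   = "\\b(?:born|raised|grew\\s+up)\\s+in\\s+",
  heritage      = "\\bmy\\s+(?:ethnicity|heritage)\\s+is\\s+"
)

# Suffix nationalities stripped by the hyphenated-identity pattern
# ("I'm [ethnicity] American/Canadian/British").
IDENTITY_SUFFIXES <- c("american", "canadian", "british")

# Words dropped from the front of a captured identity segment.
SEGMENT_LEAD_FILLER <- c(
  "a", "an", "the", "also", "half", "part", "partly", "mostly", "mainly",
  "fully", "proudly", "originally", "ethnically", "very", "really", "all"
)

#' Extract self-reported ethnicity categories from free text
#'
#' Applies six anchored identity patterns — "I'm/I am [ethnicity]",
#' "I identify as [ethnicity]", "my family are/were [ethnicity]",
#' "born/raised in [location]", "my ethnicity/heritage is [ethnicity]",
#' and "I'm [ethnicity] American/Canadian/British" — captures the
#' candidate terms, normalizes each through the lexicon (locations map
#' through the same lexicon's country terms), and returns the union of
#' successful normalizations. Multi-identity statements ("I'm Irish and
#' Italian") yield multiple categories.
#'
#' @param text A single string.
#' @param lexicon An `ethnicity_lexicon`.
#' @return Sorted character vector of unique category ids (possibly empty).
#' @export
extract_self_reported <- function(text, lexicon = defaultEthnicityLexicon()) {
  if (is.na(text) || !nzchar(text)) return(character())
  text <- normalize_apostrophes(text)
  found <- character()
  for (anchor in SELF_ID_ANCHORS) {
    hits <- regex_scan(text, anchor)
    for (i in seq_len(nrow(hits))) {
      seg <- substring(text, hits$end[i] + 1L, nchar(text))
      seg <- sub("[.,;!?\n\r].*$", "", seg, perl = TRUE)
      seg_words <- strsplit(squish(seg), " ")[[1]]
      seg <- paste(utils::head(seg_words, 8L), collapse = " ")
      found <- c(found, segment_categories(seg, lexicon))
    }
  }
  sort(unique(found))
}

# Split a captured identity segment on conjunctions/commas, trim filler,
# and normalize each part; parts ending in a nationality suffix retry with
# the suffix stripped ("Italian American" -> "Italian").
segment_categories <- function(segment, lexicon) {
  parts <- strsplit(segment, "(?i)\\s*(?:,|&|\\band\\b|/)\\s*", perl = TRUE)[[1]]
  parts <- parts[nzchar(trimws(parts))]
  out <- character()
  for (part in parts) {
    toks <- strsplit(tolower(squish(part)), " ")[[1]]
    while (length(toks) && toks[1] %in% SEGMENT_LEAD_FILLER) toks <- toks[-1]
    if (!length(toks)) next
    hit <- NA_character_
    # longest prefix (up to 3 tokens) that normalizes wins
    for (len in rev(seq_len(min(3L, length(toks))))) {
      cand <- paste(toks[seq_len(len)], collapse = " ")
      val <- normalize_ethnicity(cand, lexicon)
      if (!is.na(val)) { hit <- val; break }
      # hyphenated-nationality form: strip a trailing suffix token
      if (len >= 2L && toks[len] %in% IDENTITY_SUFFIXES) {
        cand2 <- paste(toks[seq_len(len - 1L)], collapse = " ")
        val2 <- normalize_ethnicity(cand2, lexicon)
        if (!is.na(val2)) { hit <- val2; break }
      }
    }
    if (!is.na(hit)) out <- c(out, hit)
  }
  out
}

#' Annotate a corpus with ancestry extraction results
#'
#' Runs percentage extraction, normalization, profile construction and
#' self-report extraction over every post.
#'
#' @param corpus A `dtc_corpus`.
#' @param lexicon An `ethnicity_lexicon`.
#' @return List with `mentions` (tibble: id, raw_term, category, percent),
#'   `profiles` (tibble: id, n_categories, total_percent, top_percent —
#'   one row per post, zero-filled), and `self_reported` (tibble: id,
#'   category; one row per extracted category).
#' @export
annotate_ancestry <- function(corpus, lexicon = defaultEthnicityLexicon()) {
  mention_list <- lapply(seq_len(nrow(corpus)), function(i) {
    m <- extract_ancestry_mentions(corpus$text[i], lexicon)
    if (nrow(m)) m$id <- corpus$id[i]
    m
  })
  mentions <- dplyr::bind_rows(mention_list)
  if (!nrow(mentions)) {
    mentions <- tibble::tibble(id = character(), raw_term = character(),
                               category = character(), percent = numeric())
  } else {
    mentions <- mentions[, c("id", "raw_term", "category", "percent")]
  }
  prof <- mentions |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      n_categories = dplyr::n_distinct(.data$category[!is.na(.data$category)]),
      total_percent = sum(.data$percent),
      top_percent = max(.data$percent),
      .groups = "drop"
    )
  profiles <- tibble::tibble(id = corpus$id) |>
    dplyr::left_join(prof, by = "id") |>
    dplyr::mutate(
      n_categories = ifelse(is.na(.data$n_categories), 0L, .data$n_categories),
      total_percent = ifelse(is.na(.data$total_percent), 0, .data$total_percent),
      top_percent = ifelse(is.na(.data$top_percent), 0, .data$top_percent)
    )
  self_list <- lapply(seq_len(nrow(corpus)), function(i) {
    cats <- extract_self_reported(corpus$text[i], lexicon)
    if (!length(cats)) return(NULL)
    tibble::tibble(id = corpus$id[i], category = cats)
  })
  self_reported <- dplyr::bind_rows(self_list)
  if (!nrow(self_reported)) {
    self_reported <- tibble::tibble(id = character(), category = character())
  }
  list(mentions = mentions, profiles = profiles, self_reported = self_reported)
}
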