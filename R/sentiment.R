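#' Lexicon sentiment scoring and categorization
#'
#' Each post is scored by two pluggable lexicon scorers behind a common
#' contract (`function(text) -> named numeric scores`): a social-media
#' valence scorer producing a compound score in \[-1, 1\] plus
#' positive/negative/neutral component fractions, and a
#' polarity/subjectivity scorer producing polarity in \[-1, 1\] and
#' subjectivity in \[0, 1\]. Compound scores are categorized as positive
#' (> 0.05), neutral (\[-0.05, 0.05\]) or negative (< -0.05).
#'
#' @name sentiment
NULL

NEGATORS <- c(
  "not", "no", "never", "none", "nothing", "neither", "nor", "cannot",
  "hardly", "barely", "dont", "don't", "cant", "can't", "wont", "won't",
  "isnt", "isn't", "wasnt", "wasn't", "didnt", "didn't", "doesnt",
  "doesn't", "aint", "ain't", "couldnt", "couldn't", "wouldnt",
  "wouldn't", "shouldnt", "shouldn't", "havent", "haven't", "hasnt",
  "hasn't", "werent", "weren't", "arent", "aren't"
)

BOOSTERS <- c(
  "very", "really", "so", "extremely", "absolutely", "totally", "super",
  "incredibly", "completely", "utterly", "quite"
)

NEGATION_DAMP <- -0.74   # a negated word flips and damps its valence
BOOST_INCREMENT <- 0.293 # each booster word scales valence toward extremes

sentiment_tokens <- function(text) {
  text <- tolower(normalize_apostrophes(text))
  toks <- regmatches(text, gregexpr("[a-z0-9']+", text, perl = TRUE))[[1]]
  toks
}

#' Build the social-media valence scorer
#'
#' A deterministic lexicon scorer for short informal text: word valences
#' are summed with simple negation flipping (a negator within the three
#' preceding tokens flips and damps the valence) and booster amplification
#' ("very", "extremely", ...), and the sum is normalized to a compound
#' score in \[-1, 1\] via `s / sqrt(s^2 + 15)`. Component scores `pos`,
#' `neg`, `neu` are the fractions of summed positive magnitude, negative
#' magnitude, and unscored tokens.
#'
#' @param lexicon Data frame with columns `word` and `valence` (defaults to
#'   the lexicon shipped with the package).
#' @return A scorer `function(text)` returning a named list with
#'   `compound`, `pos`, `neg`, `neu`.
#' @export
valence_scorer <- function(lexicon = NULL) {
  if (is.null(lexicon)) {
    lexicon <- utils::read.csv(path_extdata("valence_lexicon.csv"),
                               stringsAsFactors = FALSE)
  }
  values <- stats::setNames(lexicon$valence, lexicon$word)
  function(text) {
    if (is.na(text) || !nzchar(trimws(text))) {
      return(list(compound = 0, pos = 0, neg = 0, neu = 0))
    }
    toks <- sentiment_tokens(text)
    if (!length(toks)) {
      return(list(compound = 0, pos = 0, neg = 0, neu = 0))
    }
    v <- unname(values[toks])
    adj <- numeric(length(toks))
    for (i in seq_along(toks)) {
      if (is.na(v[i])) next
      val <- v[i]
      ctx <- toks[max(1L, i - 3L):max(1L, i - 1L)]
      if (i > 1L) {
        n_boost <- sum(ctx %in% BOOSTERS)
        if (n_boost > 0) val <- val + sign(val) * BOOST_INCREMENT * n_boost
        if (any(ctx %in% NEGATORS)) val <- val * NEGATION_DAMP
      }
      adj[i] <- val
    }
    s <- sum(adj)
    compound <- s / sqrt(s^2 + 15)
    compound <- max(-1, min(1, compound))
    p <- sum(adj[adj > 0])
    ngt <- -sum(adj[adj < 0])
    u <- sum(is.na(v) | adj == 0)
    denom <- p + ngt + u
    if (denom == 0) {
      return(list(compound = 0, pos = 0, neg = 0, neu = 0))
    }
    list(compound = compound, pos = p / denom, neg = ngt / denom,
         neu = u / denom)
  }
}

#' Build the polarity/subjectivity scorer
#'
#' Averages per-word polarity and subjectivity over lexicon matches, with
#' negation flipping polarity at half strength. Texts with no lexicon
#' match score polarity 0, subjectivity 0.
#'
#' @param lexicon Data frame with columns `word`, `polarity`,
#'   `subjectivity` (defaults to the shipped lexicon).
#' @return A scorer `function(text)` returning `polarity`, `subjectivity`.
#' @export
polarity_scorer <- function(lexicon = NULL) {
  if (is.null(lexicon)) {
    lexicon <- utils::read.csv(path_extdata("polarity_lexicon.csv"),
                               stringsAsFactors = FALSE)
  }
  pol <- stats::setNames(lexicon$polarity, lexicon$word)
  subj <- stats::setNames(lexicon$subjectivity, lexicon$word)
  function(text) {
    if (is.na(text) || !nzchar(trimws(text))) {
      return(list(polarity = 0, subjectivity = 0))
    }
    toks <- sentiment_tokens(text)
    hit <- which(toks %in% names(pol))
    if (!length(hit)) return(list(polarity = 0, subjectivity = 0))
    p <- unname(pol[toks[hit]])
    for (j in seq_along(hit)) {
      i <- hit[j]
      ctx <- toks[max(1L, i - 3L):max(1L, i - 1L)]
      if (i > 1L && any(ctx %in% NEGATORS)) p[j] <- -0.5 * p[j]
    }
    list(polarity = mean(p), subjectivity = mean(unname(subj[toks[hit]])))
  }
}

#' Score one text with both sentiment scorers
#'
#' A scorer failure on a post yields neutral scores with a warning rather
#' than aborting the pipeline.
#'
#' @param text A single string.
#' @param scorerA Compound scorer (defaults to [valence_scorer()]).
#' @param scorerB Polarity scorer (defaults to [polarity_scorer()]).
#' @return Named list: `compound`, `pos`, `neg`, `neu`, `polarity`,
#'   `subjectivity`.
#' @export
score_sentiment <- function(text, scorerA = valence_scorer(),
                            scorerB = polarity_scorer()) {
  a <- tryCatch(scorerA(text), error = function(e) {
    warning("valence scorer failed; neutral scores substituted: ",
            conditionMessage(e), call. = FALSE)
    list(compound = 0, pos = 0, neg = 0, neu = 0)
  })
  b <- tryCatch(scorerB(text), error = function(e) {
    warning("polarity scorer failed; neutral scores substituted: ",
            conditionMessage(e), call. = FALSE)
    list(polarity = 0, subjectivity = 0)
  })
  c(a, b)
}

#' Attach sentiment scores and categories to a corpus
#'
#' @param corpus A `dtc_corpus`.
#' @inheritParams score_sentiment
#' @return The corpus with added columns `compound`, `pos`, `neg`, `neu`,
#'   `polarity`, `subjectivity`, `sentiment_category`.
#' @export
annotate_sentiment <- function(corpus, scorerA = valence_scorer(),
                               scorerB = polarity_scorer()) {
  scores <- lapply(corpus$text, score_sentiment, scorerA = scorerA,
                   scorerB = scorerB)
  for (field in c("compound", "pos", "neg", "neu", "polarity", "subjectivity")) {
    corpus[[field]] <- vapply(scores, function(s) s[[field]], numeric(1))
  }
  corpus$sentiment_category <- categorize_sentiment(corpus$compound)
  corpus
}

#' Categorize a compound sentiment score
#'
#' Positive above 0.05, negative below -0.05, neutral on the closed
#' interval \[-0.05, 0.05\] (boundary values are neutral). The three
#' categories partition \[-1, 1\] exactly.
#'
#' @param compound Numeric vector in \[-1, 1\].
#' @return Character vector: `"positive"`, `"neutral"` or `"negative"`.
#' @export
categorize_sentiment <- function(compound) {
  if (anyNA(compound) || any(compound < -1 | compound > 1)) {
    stop("compound scores must lie in [-1, 1]", call. = FALSE)
  }
  out <- rep("neutral", length(compound))
  out[compound > 0.05] <- "positive"
  out[compound < -0.05] <- "negative"
  out
}

#' Pairwise correlations among sentiment measures
#'
#' Pearson correlations among compound, polarity and subjectivity over a
#' scored corpus — the triangulation check that the two scorers capture
#' related but distinct dimensions.
#'
#' @param scored A data frame with columns `compound`, `polarity`,
#'   `subjectivity` (e.g. an [annotate_sentiment()] result).
#' @return Symmetric 3x3 correlation matrix with unit diagonal; cells for
#'   zero-variance measures are `NA` with a warning.
#' @export
sentiment_triangulation <- function(scored) {
  cols <- c("compound", "polarity", "subjectivity")
  stopifnot(all(cols %in% names(scored)))
  m <- as.matrix(tibble::as_tibble(scored)[, cols])
  if (nrow(m) < 3) stop("need at least 3 scored posts", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  out <- matrix(NA_real_, 3, 3, dimnames = list(cols, cols))
  diag(out) <- 1
  if (any(sds == 0)) {
    warning("zero-variance measure(s): ",
            paste(cols[sds == 0], collapse = ", "), call. = FALSE)
  }
  for (i in 1:2) {
    for (j in (i + 1):3) {
      if (sds[i] > 0 && sds[j] > 0) {
        out[i, j] <- out[j, i] <- stats::cor(m[, i], m[, j])
      }
    }
  }
  out
}
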