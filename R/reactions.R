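#' Keyword reaction classification and validation harness
#'
#' Posts are classified into six non-exclusive reaction categories
#' (surprise, dispute, acceptance, disappointment, identity crisis,
#' excitement) by whole-word/phrase keyword matching, and the classifier is
#' validated against human annotations via per-category confusion counts
#' and precision/recall/F1/Cohen's kappa/accuracy.
#'
#' @name reactions
NULL

# Compile one keyword phrase into a boundary-anchored perl regex:
# whitespace-tolerant between words, apostrophes optional so that
# "don't"/"dont" both match.
compile_phrase <- function(phrase) {
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", phrase)
  esc <- gsub("'", "'?", esc, fixed = TRUE)
  esc <- gsub("\\s+", "\\\\s+", esc)
  paste0("\\b", esc, "\\b")
}

compile_reaction_patterns <- function(lexicon) {
  lapply(lexicon, function(phrases) {
    paste0("(?:", paste(vapply(phrases, compile_phrase, character(1)),
                        collapse = "|"), ")")
  })
}

prepare_match_text <- function(text) {
  squish(tolower(normalize_apostrophes(text)))
}

#' Classify reactions in text
#'
#' A category flag is 1 iff at least one of its phrases occurs in the
#' lowercased, whitespace-normalized text as a whole-word (phrase-boundary)
#' match. Flags are independent (no mutual exclusivity). Matching is
#' invariant to case and leading/trailing whitespace; apostrophe variants
#' both match; substring hits inside longer words (e.g. "scam" in
#' "scampi") do not count.
#'
#' @param text Character vector of post texts.
#' @param lexicon A `reaction_lexicon`.
#' @return For a single text, a named integer vector of six 0/1 flags; for
#'   a vector, a tibble with one flag column per category.
#' @export
classify_reactions <- function(text, lexicon = defaultReactionLexicon()) {
  patterns <- compile_reaction_patterns(lexicon)
  prepped <- prepare_match_text(text)
  flags <- lapply(patterns, function(p) {
    as.integer(grepl(p, prepped, perl = TRUE))
  })
  if (length(text) == 1L) {
    return(vapply(flags, identity, integer(1)))
  }
  tibble::as_tibble(flags)
}

#' Attach reaction flags to a corpus
#'
#' @param corpus A `dtc_corpus`.
#' @param lexicon A `reaction_lexicon`.
#' @return The corpus with six added columns `reaction_<category>`.
#' @export
annotate_reactions <- function(corpus, lexicon = defaultReactionLexicon()) {
  if (inherits(lexicon, "reaction_lexicon")) validate_reaction_lexicon(lexicon)
  flags <- classify_reactions(corpus$text, lexicon)
  names(flags) <- paste0("reaction_", names(flags))
  for (nm in names(flags)) corpus[[nm]] <- flags[[nm]]
  corpus
}

reaction_flag_matrix <- function(corpus) {
  cols <- paste0("reaction_", REACTION_CATEGORIES)
  missing <- setdiff(cols, names(corpus))
  if (length(missing)) {
    stop("corpus lacks reaction flags; run annotate_reactions() first",
         call. = FALSE)
  }
  m <- as.matrix(tibble::as_tibble(corpus)[, cols])
  colnames(m) <- REACTION_CATEGORIES
  m
}

#' Reaction co-occurrence summary
#'
#' @param corpus A corpus annotated with reaction flags.
#' @return List with `mean_per_post` (total flags divided by total posts)
#'   and `cooccurrence` (symmetric category-by-category count matrix;
#'   diagonal holds per-category totals).
#' @export
reaction_cooccurrence <- function(corpus) {
  if (!nrow(corpus)) {
    return(list(mean_per_post = 0,
                cooccurrence = matrix(0L, 0, 0)))
  }
  m <- reaction_flag_matrix(corpus)
  co <- t(m) %*% m
  list(mean_per_post = sum(m) / nrow(m), cooccurrence = co)
}

#' Stratified validation sampling plan
#'
#' Draws the annotation sample used to validate the keyword classifier:
#' for each reaction category (in the fixed category order) up to
#' `per_reaction` flagged posts, then up to `no_reaction` posts with no
#' detected reaction, then uniform random top-up to `target`. Sampling is
#' without replacement; a post flagged for multiple reactions can satisfy
#' only the first stratum it is drawn for. Shortfalls in a stratum are
#' logged. Deterministic for a fixed seed.
#'
#' @param corpus A corpus annotated with reaction flags.
#' @param per_reaction Target positives per category (default 35).
#' @param no_reaction Target posts with no detected reaction (default 60).
#' @param target Total sample size (default 300).
#' @param seed Integer RNG seed.
#' @return Tibble with `id` and `stratum`.
#' @export
stratified_validation_sample <- function(corpus, per_reaction = 35L,
                                         no_reaction = 60L, target = 300L,
                                         seed = 1L) {
  if (!nrow(corpus)) stop("cannot sample from an empty corpus", call. = FALSE)
  m <- reaction_flag_matrix(corpus)
  ids <- corpus$id
  with_local_seed(seed, {
    taken <- character()
    strata <- character()
    for (cat_id in REACTION_CATEGORIES) {
      pool <- ids[m[, cat_id] == 1L & !(ids %in% taken)]
      k <- min(per_reaction, length(pool))
      if (k < per_reaction) {
        log_info("stratum '%s': only %d of %d available", cat_id, k, per_reaction)
      }
      pick <- if (k > 0) sample(pool, k) else character()
      taken <- c(taken, pick)
      strata <- c(strata, rep(cat_id, k))
    }
    pool <- ids[rowSums(m) == 0L & !(ids %in% taken)]
    k <- min(no_reaction, length(pool))
    if (k < no_reaction) {
      log_info("stratum 'no_reaction': only %d of %d available", k, no_reaction)
    }
    pick <- if (k > 0) sample(pool, k) else character()
    taken <- c(taken, pick)
    strata <- c(strata, rep("no_reaction", k))
    n_fill <- max(0L, min(target, length(ids)) - length(taken))
    pool <- ids[!(ids %in% taken)]
    pick <- if (n_fill > 0) sample(pool, min(n_fill, length(pool))) else character()
    taken <- c(taken, pick)
    strata <- c(strata, rep("random", length(pick)))
    tibble::tibble(id = taken, stratum = strata)
  })
}

#' Agreement metrics from one confusion matrix
#'
#' Computes precision, recall, F1, Cohen's kappa and accuracy from the
#' TP/FP/FN/TN counts of one reaction category against human annotation.
#' Kappa uses chance agreement from the marginal products,
#' `p_e = ((tp+fp)(tp+fn) + (fn+tn)(fp+tn)) / n^2`, and
#' `kappa = (p_o - p_e) / (1 - p_e)`. Zero-denominator metrics return `NA`
#' (the undefined sentinel), distinct from 0.
#'
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @return Named list: `precision`, `recall`, `f1`, `kappa`, `accuracy`,
#'   `n`.
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  counts <- c(tp, fp, fn, tn)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  n <- sum(counts)
  if (n == 0) stop("all counts are zero", call. = FALSE)
  precision <- if ((tp + fp) > 0) tp / (tp + fp) else NA_real_
  recall <- if ((tp + fn) > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && (precision + recall) > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  accuracy <- (tp + tn) / n
  p_o <- accuracy
  p_e <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (p_e < 1) (p_o - p_e) / (1 - p_e) else NA_real_
  list(precision = precision, recall = recall, f1 = f1,
       kappa = kappa, accuracy = accuracy, n = n)
}

#' Confusion counts from predicted and human labels
#'
#' @param predicted,truth Binary 0/1 vectors of equal length.
#' @return Named list with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  predicted <- as.integer(predicted)
  truth <- as.integer(truth)
  list(
    tp = sum(predicted == 1L & truth == 1L),
    fp = sum(predicted == 1L & truth == 0L),
    fn = sum(predicted == 0L & truth == 1L),
    tn = sum(predicted == 0L & truth == 0L)
  )
}

#' Validation report across the six reaction categories
#'
#' Micro-averaged metrics are computed from the pooled (summed) confusion
#' counts; macro averages are unweighted means over per-category metrics,
#' excluding undefined (`NA`) values with a logged count; overall accuracy
#' comes from the pooled counts.
#'
#' @param counts A data frame / tibble with columns `category`, `tp`, `fp`,
#'   `fn`, `tn` — one row per reaction category.
#' @return List of class `validation_report` with `per_category` (tibble of
#'   metrics), `micro` (metrics of the summed confusion matrix), `macro`
#'   (unweighted means), and `overall_accuracy`.
#' @export
validation_report <- function(counts) {
  counts <- tibble::as_tibble(counts)
  stopifnot(all(c("category", "tp", "fp", "fn", "tn") %in% names(counts)))
  ns <- counts$tp + counts$fp + counts$fn + counts$tn
  if (length(unique(ns)) != 1L) {
    stop("inconsistent annotated-post counts across categories", call. = FALSE)
  }
  per <- lapply(seq_len(nrow(counts)), function(i) {
    m <- confusion_metrics(counts$tp[i], counts$fp[i], counts$fn[i], counts$tn[i])
    tibble::tibble(category = counts$category[i],
                   precision = m$precision, recall = m$recall, f1 = m$f1,
                   kappa = m$kappa, accuracy = m$accuracy)
  })
  per <- dplyr::bind_rows(per)
  micro <- confusion_metrics(sum(counts$tp), sum(counts$fp),
                             sum(counts$fn), sum(counts$tn))
  macro_mean <- function(x) {
    n_undef <- sum(is.na(x))
    if (n_undef > 0) log_info("%d undefined value(s) excluded from macro average", n_undef)
    mean(x, na.rm = TRUE)
  }
  macro <- list(
    precision = macro_mean(per$precision),
    recall = macro_mean(per$recall),
    f1 = macro_mean(per$f1),
    kappa = macro_mean(per$kappa)
  )
  structure(
    list(per_category = per, micro = micro, macro = macro,
         overall_accuracy = micro$accuracy),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  print(as.data.frame(x$per_category), digits = 3)
  cat(sprintf("macro F1 %.3f | mean kappa %.3f | overall accuracy %.3f\n",
              x$macro$f1, x$macro$kappa, x$overall_accuracy))
  invisible(x)
}

#' Read a human annotation file
#'
#' CSV with an `id` column plus one 0/1 column per reaction category. Rows
#' with any missing label (incomplete annotation) are dropped with a
#' logged count.
#'
#' @param path CSV file path.
#' @return Tibble with `id` and the six label columns.
#' @export
read_annotations <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("id", REACTION_CATEGORIES), names(df))
  if (length(missing)) {
    stop("annotation file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, c("id", REACTION_CATEGORIES)]
  complete <- stats::complete.cases(df)
  if (any(!complete)) {
    log_info("%d incomplete annotation row(s) dropped", sum(!complete))
  }
  tibble::as_tibble(df[complete, ])
}

#' Validate classifier flags against human annotations
#'
#' @param corpus A corpus annotated with reaction flags.
#' @param annotations Tibble from [read_annotations()] (or equivalent).
#' @return A `validation_report`.
#' @export
validate_classifier <- function(corpus, annotations) {
  m <- reaction_flag_matrix(corpus)
  keep <- match(annotations$id, corpus$id)
  if (anyNA(keep)) stop("annotation ids not found in corpus", call. = FALSE)
  counts <- lapply(REACTION_CATEGORIES, function(cat_id) {
    cc <- confusion_counts(m[keep, cat_id], annotations[[cat_id]])
    tibble::tibble(category = cat_id, tp = cc$tp, fp = cc$fp,
                   fn = cc$fn, tn = cc$tn)
  })
  validation_report(dplyr::bind_rows(counts))
}
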