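#' Topic modeling
#'
#' Text preprocessing, document-term matrix construction with document
#' frequency filters and a vocabulary cap, and latent Dirichlet allocation
#' fit by variational-Bayes coordinate ascent, plus a per-topic sentiment
#' summary under hard (argmax) topic assignment.
#'
#' @name topics
NULL

#' Preprocess text for topic modeling
#'
#' URL tokens (http/https/www) are deleted first, then every character
#' outside the alphabet is replaced by a space, then the text is
#' lowercased and whitespace-collapsed. Idempotent.
#'
#' @param text Character vector.
#' @return Cleaned character vector.
#' @export
preprocess_text <- function(text) {
  text[is.na(text)] <- ""
  text <- gsub("(?:https?://|www\\.)\\S+", " ", text, perl = TRUE)
  text <- gsub("[^A-Za-z]+", " ", text, perl = TRUE)
  squish(tolower(text))
}

#' Build a document-term matrix
#'
#' Filters are applied in a fixed order: stopword removal, then document
#' frequency filters (terms in more than `max_df` of documents or fewer
#' than `min_df` documents are dropped), then the vocabulary is capped at
#' the `max_features` most frequent remaining terms (ties broken
#' alphabetically for determinism).
#'
#' @param texts Character vector of preprocessed documents (see
#'   [preprocess_text()]); raw text is preprocessed on the fly.
#' @param max_df Maximum document-frequency proportion (default 0.95).
#' @param min_df Minimum document count (default 10).
#' @param max_features Vocabulary cap (default 5000).
#' @param stopwords Stopword list (default the shipped English list).
#' @return List with `dtm` (sparse document x term count matrix) and
#'   `vocabulary` (ordered term vector).
#' @export
build_dtm <- function(texts, max_df = 0.95, min_df = 10L,
                      max_features = 5000L, stopwords = defaultStopwords()) {
  texts <- preprocess_text(texts)
  n_docs <- length(texts)
  if (n_docs < min_df) {
    stop("need at least min_df (= ", min_df, ") documents", call. = FALSE)
  }
  token_list <- strsplit(texts, " ", fixed = TRUE)
  token_list <- lapply(token_list, function(x) x[nzchar(x) & !(x %in% stopwords)])
  # per-document term counts in triplet form
  triplets <- lapply(seq_along(token_list), function(d) {
    toks <- token_list[[d]]
    if (!length(toks)) return(NULL)
    tab <- table(toks)
    data.frame(doc = d, term = names(tab), count = as.integer(tab),
               stringsAsFactors = FALSE)
  })
  trip <- dplyr::bind_rows(triplets)
  if (!nrow(trip)) stop("empty vocabulary after filtering", call. = FALSE)
  stats_tab <- trip |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(df = dplyr::n(), tf = sum(.data$count), .groups = "drop")
  keep <- stats_tab |>
    dplyr::filter(.data$df >= min_df, .data$df <= max_df * n_docs) |>
    dplyr::arrange(dplyr::desc(.data$tf), .data$term) |>
    utils::head(max_features)
  if (!nrow(keep)) stop("empty vocabulary after filtering", call. = FALSE)
  vocabulary <- sort(keep$term)
  trip <- trip[trip$term %in% vocabulary, ]
  dtm <- Matrix::sparseMatrix(
    i = trip$doc,
    j = match(trip$term, vocabulary),
    x = trip$count,
    dims = c(n_docs, length(vocabulary)),
    dimnames = list(NULL, vocabulary)
  )
  list(dtm = dtm, vocabulary = vocabulary)
}

#' Fit latent Dirichlet allocation by variational Bayes
#'
#' Batch variational-Bayes coordinate ascent with symmetric Dirichlet
#' priors (`alpha = eta = 1/k`). Each of the `iterations` passes runs the
#' per-document E-step to convergence and then updates the topic-term
#' variational parameters; the evidence lower bound is recorded per pass
#' and is non-decreasing. Deterministic for a fixed seed.
#'
#' @param dtm Sparse document x term count matrix (from [build_dtm()]).
#' @param k Number of topics (default 8).
#' @param iterations Variational EM passes over the corpus (default 15).
#' @param seed Integer RNG seed for the topic initialization.
#' @return An object of class `lda_model`: list with `k`, `topic_term`
#'   (k x V variational parameters; rows normalizable to topic-word
#'   distributions), `doc_topic` (D x k, rows summing to 1),
#'   `vocabulary`, and `bound` (ELBO trace).
#' @export
fit_lda <- function(dtm, k = 8L, iterations = 15L, seed = 1L) {
  if (is.list(dtm) && !is.null(dtm$dtm)) dtm <- dtm$dtm
  n_docs <- nrow(dtm)
  n_terms <- ncol(dtm)
  if (!n_docs || !n_terms) stop("empty document-term matrix", call. = FALSE)
  if (k > n_docs) stop("k exceeds the number of documents", call. = FALSE)
  alpha <- 1 / k
  eta <- 1 / k
  dtm <- methods::as(dtm, "CsparseMatrix")
  # row-wise (document) access to the sparse counts
  dtm_t <- Matrix::t(dtm)
  doc_ids <- lapply(seq_len(n_docs), function(d) {
    p <- dtm_t@p
    idx <- seq.int(p[d] + 1L, p[d + 1L])
    if (p[d + 1L] == p[d]) return(NULL)
    list(ids = dtm_t@i[idx] + 1L, cts = dtm_t@x[idx])
  })

  lambda <- with_local_seed(seed, {
    matrix(stats::rgamma(k * n_terms, 100, 100), k, n_terms)
  })
  gamma_mat <- matrix(alpha + Matrix::rowSums(dtm) / k, n_docs, k)
  bound <- numeric(iterations)

  dirichlet_expectation <- function(x) {
    if (is.matrix(x)) digamma(x) - digamma(rowSums(x))
    else digamma(x) - digamma(sum(x))
  }

  for (it in seq_len(iterations)) {
    elog_beta <- dirichlet_expectation(lambda)
    exp_elog_beta <- exp(elog_beta)
    sstats <- matrix(0, k, n_terms)
    score_docs <- 0
    for (d in seq_len(n_docs)) {
      slot_d <- doc_ids[[d]]
      if (is.null(slot_d)) next
      ids <- slot_d$ids
      cts <- slot_d$cts
      gammad <- gamma_mat[d, ]
      elog_theta <- dirichlet_expectation(gammad)
      exp_elog_theta <- exp(elog_theta)
      beta_d <- exp_elog_beta[, ids, drop = FALSE]
      phinorm <- as.numeric(exp_elog_theta %*% beta_d) + 1e-100
      for (inner in seq_len(100L)) {
        last <- gammad
        gammad <- alpha + exp_elog_theta *
          as.numeric(beta_d %*% (cts / phinorm))
        elog_theta <- dirichlet_expectation(gammad)
        exp_elog_theta <- exp(elog_theta)
        phinorm <- as.numeric(exp_elog_theta %*% beta_d) + 1e-100
        if (mean(abs(gammad - last)) < 1e-6) break
      }
      gamma_mat[d, ] <- gammad
      sstats[, ids] <- sstats[, ids] +
        outer(exp_elog_theta, cts / phinorm)
      # per-document ELBO pieces (Hoffman-style bound)
      score_docs <- score_docs + sum(cts * log(phinorm)) +
        sum((alpha - gammad) * elog_theta) +
        sum(lgamma(gammad)) - lgamma(sum(gammad)) +
        lgamma(k * alpha) - k * lgamma(alpha)
    }
    sstats <- sstats * exp_elog_beta
    lambda <- eta + sstats
    elog_beta_new <- dirichlet_expectation(lambda)
    score_topics <- sum((eta - lambda) * elog_beta_new) +
      sum(lgamma(lambda)) - sum(lgamma(rowSums(lambda))) +
      k * (lgamma(n_terms * eta) - n_terms * lgamma(eta))
    bound[it] <- score_docs + score_topics
  }

  structure(
    list(
      k = k,
      topic_term = lambda,
      doc_topic = gamma_mat / rowSums(gamma_mat),
      vocabulary = colnames(dtm) %||% as.character(seq_len(n_terms)),
      bound = bound,
      alpha = alpha,
      eta = eta,
      seed = seed
    ),
    class = "lda_model"
  )
}

#' @export
print.lda_model <- function(x, ...) {
  cat("<lda_model> k =", x$k, "| vocabulary:", length(x$vocabulary),
      "terms | final bound:", format(utils::tail(x$bound, 1)), "\n")
  invisible(x)
}

#' Top terms per topic
#'
#' @param model An `lda_model`.
#' @param n Terms per topic (default 10).
#' @return Tibble with `topic`, `rank`, `term`, `weight` (normalized
#'   topic-word probability).
#' @export
top_terms <- function(model, n = 10L) {
  beta <- model$topic_term / rowSums(model$topic_term)
  out <- lapply(seq_len(model$k), function(t) {
    ord <- order(beta[t, ], decreasing = TRUE)[seq_len(min(n, ncol(beta)))]
    tibble::tibble(topic = t, rank = seq_along(ord),
                   term = model$vocabulary[ord], weight = beta[t, ord])
  })
  dplyr::bind_rows(out)
}

#' Hard topic assignment
#'
#' Argmax over the document-topic distribution; ties break toward the
#' lowest topic index.
#'
#' @param model An `lda_model`.
#' @return Integer vector of topic indices, one per document.
#' @export
assign_topics <- function(model) {
  apply(model$doc_topic, 1, which.max)
}

#' Sentiment summary by topic
#'
#' Mean and SD of the compound sentiment score per hard-assigned topic.
#' Topics with no assigned documents are reported with `NA` mean.
#'
#' @param model An `lda_model`.
#' @param compound Numeric vector of compound scores, one per document in
#'   the same order as the DTM rows.
#' @return Tibble with `topic`, `n`, `mean_compound`, `sd_compound`.
#' @export
sentiment_by_topic <- function(model, compound) {
  if (length(compound) != nrow(model$doc_topic)) {
    stop("compound length must match the number of documents", call. = FALSE)
  }
  assignment <- assign_topics(model)
  out <- lapply(seq_len(model$k), function(t) {
    sel <- assignment == t
    tibble::tibble(
      topic = t,
      n = sum(sel),
      mean_compound = if (any(sel)) mean(compound[sel]) else NA_real_,
      sd_compound = if (sum(sel) > 1) stats::sd(compound[sel]) else NA_real_
    )
  })
  dplyr::bind_rows(out)
}
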