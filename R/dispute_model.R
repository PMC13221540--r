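#' Logistic-regression dispute prediction
#'
#' Models the probability that a post expresses dispute from four
#' post-level features — text length (characters), compound sentiment,
#' number of distinct ancestries mentioned, and top ancestry percentage —
#' with z-scored features, stratified 5-fold cross-validated AUC, and
#' standardized coefficients from a full-data fit. The modeling population
#' is posts with extractable ancestry results (top percentage is undefined
#' elsewhere).
#'
#' @name dispute-model
NULL

FEATURE_NAMES <- c("text_length", "compound", "n_ancestries", "top_percent")

#' Build the feature table for the dispute model
#'
#' @param corpus A corpus annotated with sentiment (for `compound`).
#' @param profiles Per-post ancestry profile table from
#'   [annotate_ancestry()] (absent profiles zero-fill `n_ancestries` and
#'   `top_percent`).
#' @return Tibble with `id` and the four feature columns; no missing
#'   values.
#' @export
build_features <- function(corpus, profiles = NULL) {
  if (!"compound" %in% names(corpus)) {
    stop("corpus lacks sentiment scores; run annotate_sentiment() first",
         call. = FALSE)
  }
  out <- tibble::tibble(
    id = corpus$id,
    text_length = nchar(corpus$text),
    compound = corpus$compound
  )
  if (is.null(profiles)) {
    out$n_ancestries <- 0L
    out$top_percent <- 0
  } else {
    out <- out |>
      dplyr::left_join(profiles[, c("id", "n_categories", "top_percent")],
                       by = "id") |>
      dplyr::rename(n_ancestries = "n_categories")
    out$n_ancestries[is.na(out$n_ancestries)] <- 0L
    out$top_percent[is.na(out$top_percent)] <- 0
  }
  out
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with midrank tie handling.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary 0/1 labels.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("need both classes for AUC", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

zscore_fit <- function(x) {
  list(mean = colMeans(x), sd = apply(x, 2, stats::sd))
}

zscore_apply <- function(x, z) {
  sd <- ifelse(z$sd > 0, z$sd, 1)
  sweep(sweep(x, 2, z$mean, "-"), 2, sd, "/")
}

#' Fit the cross-validated dispute model
#'
#' Stratified k-fold cross-validation with z-scoring fit on each training
#' fold and applied to its test fold (no leakage); plain logistic
#' regression with intercept. The reported coefficient set comes from a
#' fit on all data z-scored globally; per-fold AUCs, their mean and SD,
#' and the training AUC of the final fit are reported alongside.
#'
#' @param features Tibble/data frame with the four feature columns (an
#'   `id` column is ignored), or a numeric matrix.
#' @param labels Binary 0/1 vector (1 = dispute expressed).
#' @param folds Number of stratified folds (default 5).
#' @param seed Integer RNG seed for fold assignment.
#' @return Object of class `dispute_model_report`: list with
#'   `coefficients` (standardized, named), `intercept`, `fold_auc`,
#'   `mean_auc`, `sd_auc`, `training_auc`, `folds`, `seed`, `n`.
#' @export
fit_dispute_model <- function(features, labels, folds = 5L, seed = 1L) {
  x <- as.matrix(tibble::as_tibble(features)[,
    intersect(c(FEATURE_NAMES), colnames(as.data.frame(features))), drop = FALSE])
  if (!ncol(x)) x <- as.matrix(features)
  labels <- as.integer(labels)
  if (length(labels) != nrow(x)) stop("labels/features length mismatch", call. = FALSE)
  if (length(unique(labels)) < 2L) stop("labels are single-class", call. = FALSE)
  if (sum(labels == 1L) < folds || sum(labels == 0L) < folds) {
    stop("need at least `folds` cases of each class", call. = FALSE)
  }
  fold_of <- integer(length(labels))
  with_local_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- sample(which(labels == cls))
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold_auc <- vapply(seq_len(folds), function(f) {
    tr <- fold_of != f
    z <- zscore_fit(x[tr, , drop = FALSE])
    xtr <- zscore_apply(x[tr, , drop = FALSE], z)
    xte <- zscore_apply(x[!tr, , drop = FALSE], z)
    fit <- stats::glm.fit(cbind(1, xtr), labels[tr],
                          family = stats::binomial())
    scores <- as.numeric(cbind(1, xte) %*% fit$coefficients)
    roc_auc(scores, labels[!tr])
  }, numeric(1))
  z <- zscore_fit(x)
  xz <- zscore_apply(x, z)
  final <- stats::glm.fit(cbind(1, xz), labels, family = stats::binomial())
  coefs <- final$coefficients
  names(coefs) <- c("(Intercept)", colnames(x))
  training_auc <- roc_auc(as.numeric(cbind(1, xz) %*% final$coefficients),
                          labels)
  structure(
    list(
      coefficients = coefs[-1],
      intercept = unname(coefs[1]),
      fold_auc = fold_auc,
      mean_auc = mean(fold_auc),
      sd_auc = stats::sd(fold_auc),
      training_auc = training_auc,
      folds = folds,
      seed = seed,
      n = nrow(x)
    ),
    class = "dispute_model_report"
  )
}

#' @export
print.dispute_model_report <- function(x, ...) {
  cat("<dispute_model_report> n =", x$n, "|", x$folds, "folds\n")
  cat("standardized coefficients:\n")
  print(round(x$coefficients, 4))
  cat(sprintf("mean CV AUC %.3f (SD %.3f), training AUC %.3f\n",
              x$mean_auc, x$sd_auc, x$training_auc))
  invisible(x)
}
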