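#' The common post schema and corpus container
#'
#' Every platform's raw records are normalized into one schema: a unique
#' `id`, a `platform` tag, free `text` (never missing; empty allowed), an
#' optional `author`, an optional UTC `timestamp`, and an optional
#' non-negative integer `engagement` count. A corpus is a tibble of such
#' posts (one row per post, extra columns carry downstream annotations)
#' with a `provenance` attribute recording where it came from.
#'
#' @name corpus
NULL

PLATFORM_LEVELS <- c("reddit", "youtube", "googleplay", "synthetic")

CORE_COLUMNS <- c("id", "platform", "text", "author", "timestamp", "engagement")

#' Construct a corpus from a data frame of posts
#'
#' Validates the schema invariants: unique non-missing ids, platform drawn
#' from the closed enum, text never missing (empty string allowed),
#' non-negative engagement where present.
#'
#' @param posts Data frame with at least `id`, `platform`, `text`; optional
#'   `author`, `timestamp` (POSIXct, UTC), `engagement`.
#' @param provenance Free-form list of metadata (source files, lexicon
#'   versions, generator seed).
#' @return A tibble with class `dtc_corpus`.
#' @export
as_corpus <- function(posts, provenance = list()) {
  posts <- tibble::as_tibble(posts)
  for (col in c("author", "timestamp", "engagement")) {
    if (!col %in% names(posts)) {
      posts[[col]] <- if (col == "timestamp") {
        as.POSIXct(NA_real_, origin = "1970-01-01", tz = "UTC")
      } else if (col == "engagement") NA_integer_ else NA_character_
    }
  }
  missing <- setdiff(c("id", "platform", "text"), names(posts))
  if (length(missing)) {
    stop("corpus lacks required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  posts$id <- as.character(posts$id)
  posts$platform <- as.character(posts$platform)
  posts$text <- as.character(posts$text)
  posts$engagement <- as.integer(posts$engagement)
  if (anyNA(posts$id)) stop("post id may not be missing", call. = FALSE)
  if (anyDuplicated(posts$id)) {
    stop("duplicate post id(s): ",
         paste(utils::head(unique(posts$id[duplicated(posts$id)]), 3), collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(posts$platform), PLATFORM_LEVELS)
  if (length(bad)) {
    stop("unknown platform tag(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyNA(posts$text)) stop("text may not be missing (use \"\")", call. = FALSE)
  if (any(!is.na(posts$engagement) & posts$engagement < 0L)) {
    stop("engagement must be non-negative", call. = FALSE)
  }
  posts <- posts[, c(CORE_COLUMNS, setdiff(names(posts), CORE_COLUMNS))]
  structure(posts, provenance = provenance,
            class = c("dtc_corpus", class(tibble::tibble())))
}

#' @rdname as_corpus
#' @param corpus A `dtc_corpus`.
#' @export
corpusProvenance <- function(corpus) attr(corpus, "provenance")

#' @export
print.dtc_corpus <- function(x, ...) {
  cat("<dtc_corpus> ", nrow(x), " posts (",
      paste(sprintf("%s: %d", names(table(x$platform)), as.integer(table(x$platform))),
            collapse = ", "), ")\n", sep = "")
  NextMethod()
}

# Key aliases searched, in order, when normalizing raw records.
DEFAULT_FIELD_KEYS <- list(
  id = c("id", "post_id", "comment_id", "review_id", "reviewId", "uid", "name"),
  title = c("title"),
  body = c("selftext", "body", "text", "comment", "content", "review", "snippet"),
  author = c("author", "user", "userName", "channel"),
  timestamp = c("timestamp", "created_utc", "created", "date", "at", "publishedAt"),
  engagement = c("engagement", "score", "likes", "like_count", "thumbsUpCount", "ups", "votes")
)

first_key <- function(raw, keys) {
  for (k in keys) {
    v <- raw[[k]]
    if (!is.null(v) && length(v) == 1 && !is.na(v) && nzchar(as.character(v))) {
      return(v)
    }
  }
  NULL
}

parse_timestamp <- function(x) {
  if (is.null(x)) return(as.POSIXct(NA_real_, origin = "1970-01-01", tz = "UTC"))
  if (is.numeric(x)) return(as.POSIXct(as.numeric(x), origin = "1970-01-01", tz = "UTC"))
  out <- suppressWarnings(as.POSIXct(as.character(x), tz = "UTC",
                                     tryFormats = c("%Y-%m-%dT%H:%M:%SZ",
                                                    "%Y-%m-%dT%H:%M:%S",
                                                    "%Y-%m-%d %H:%M:%S",
                                                    "%Y-%m-%d")))
  out
}

#' Normalize one raw platform record into the common schema
#'
#' Reddit-style records may carry both a title and a body; when both are
#' present they are concatenated with a single newline so both surfaces
#' stay available for keyword matching. Missing author/timestamp/engagement
#' become absent values, not errors; a record with no recognizable id or no
#' text-like field is rejected (`NULL`) with a logged reason.
#'
#' @param raw Named list (one record).
#' @param platform One of `"reddit"`, `"youtube"`, `"googleplay"`,
#'   `"synthetic"`.
#' @param field_keys Per-field key-alias lists; see `DEFAULT_FIELD_KEYS` in
#'   the package source. Override to map non-standard exports.
#' @return One-row tibble in the common schema, or `NULL` if rejected.
#' @export
normalize_record <- function(raw, platform, field_keys = DEFAULT_FIELD_KEYS) {
  platform <- match.arg(platform, PLATFORM_LEVELS)
  id <- first_key(raw, field_keys$id)
  title <- first_key(raw, field_keys$title)
  body <- first_key(raw, field_keys$body)
  if (is.null(id)) {
    log_info("record rejected: no id-like field")
    return(NULL)
  }
  if (is.null(title) && is.null(body)) {
    log_info("record %s rejected: no text-like field", as.character(id))
    return(NULL)
  }
  text <- if (!is.null(title) && !is.null(body)) {
    paste(as.character(title), as.character(body), sep = "\n")
  } else {
    as.character(title %||% body)
  }
  author <- first_key(raw, field_keys$author)
  engagement <- first_key(raw, field_keys$engagement)
  tibble::tibble(
    id = as.character(id),
    platform = platform,
    text = text,
    author = if (is.null(author)) NA_character_ else as.character(author),
    timestamp = parse_timestamp(first_key(raw, field_keys$timestamp)),
    engagement = if (is.null(engagement)) NA_integer_ else as.integer(engagement)
  )
}

#' Ingest a list of raw records into a corpus
#'
#' @param records List of named lists.
#' @inheritParams normalize_record
#' @return A `dtc_corpus`; rejected records are logged and counted in the
#'   provenance.
#' @export
ingest_records <- function(records, platform, field_keys = DEFAULT_FIELD_KEYS) {
  rows <- lapply(records, normalize_record, platform = platform,
                 field_keys = field_keys)
  kept <- rows[!vapply(rows, is.null, logical(1))]
  n_rejected <- length(records) - length(kept)
  if (n_rejected > 0) log_info("%d record(s) rejected during ingest", n_rejected)
  as_corpus(dplyr::bind_rows(kept),
            provenance = list(platform = platform, n_rejected = n_rejected))
}

iso8601 <- function(x) {
  out <- format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  out[is.na(x)] <- NA_character_
  out
}

#' Read / write a serialized corpus
#'
#' JSONL stores one post object per line with absent optional fields
#' dropped; CSV stores a header plus one row per post with `NA` markers for
#' absent values (so an empty-string author stays distinct from an absent
#' one). Write-then-read is the identity on every field, including absent
#' optionals, and preserves row order. Malformed JSONL lines are skipped
#' with a logged count; a duplicate id is an error.
#'
#' @param path File path.
#' @param format `"jsonl"` or `"csv"`; default guessed from the extension.
#' @return `read_corpus()`: a `dtc_corpus`. `write_corpus()`: `path`,
#'   invisibly.
#' @export
read_corpus <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    parsed <- lapply(lines, function(l) {
      tryCatch(jsonlite::fromJSON(l, simplifyVector = TRUE), error = function(e) NULL)
    })
    bad <- vapply(parsed, is.null, logical(1))
    if (any(bad)) log_info("%d malformed line(s) skipped", sum(bad))
    rows <- lapply(parsed[!bad], function(p) {
      p <- lapply(p, function(v) if (length(v) == 0) NA else v)
      tibble::as_tibble(p)
    })
    df <- dplyr::bind_rows(rows)
    if (!nrow(df)) stop("no parseable posts in ", path, call. = FALSE)
    if ("timestamp" %in% names(df)) {
      df$timestamp <- parse_timestamp(df$timestamp)
    }
  } else {
    df <- readr::read_csv(path, na = "NA", show_col_types = FALSE,
                          progress = FALSE)
    if ("timestamp" %in% names(df) && !inherits(df$timestamp, "POSIXct")) {
      df$timestamp <- parse_timestamp(df$timestamp)
    }
  }
  if ("timestamp" %in% names(df)) {
    attr(df$timestamp, "tzone") <- "UTC"
  }
  as_corpus(df, provenance = list(source = path, format = format))
}

#' @rdname read_corpus
#' @param corpus A `dtc_corpus`.
#' @export
write_corpus <- function(corpus, path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  df <- tibble::as_tibble(corpus)
  if (format == "jsonl") {
    df$timestamp <- iso8601(df$timestamp)
    lines <- vapply(seq_len(nrow(df)), function(i) {
      row <- as.list(df[i, ])
      row <- row[!vapply(row, function(v) length(v) == 1 && is.na(v), logical(1))]
      jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    readr::write_csv(df, path, na = "NA", progress = FALSE)
  }
  invisible(path)
}

#' Per-platform composition of a corpus
#'
#' @param corpus A `dtc_corpus`.
#' @return Tibble with `platform`, `n`, `percent` (percent of all posts,
#'   summing to 100 within rounding). Empty corpus gives an empty table.
#' @export
corpus_composition <- function(corpus) {
  if (!nrow(corpus)) {
    return(tibble::tibble(platform = character(), n = integer(),
                          percent = numeric()))
  }
  corpus |>
    dplyr::count(.data$platform, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n)) |>
    dplyr::mutate(percent = 100 * .data$n / sum(.data$n))
}
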