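# Internal helpers shared across modules.

#' @importFrom rlang .data
#' @importFrom stats sd setNames
NULL

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_local_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Stable hash of an R object (serialized, md5 via tools::md5sum).
object_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  saveRDS(x, tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}

# Collapse runs of whitespace and trim.
squish <- function(x) {
  x <- gsub("\\s+", " ", x, perl = TRUE)
  trimws(x)
}

# Replace typographic apostrophes with ASCII ones.
normalize_apostrophes <- function(x) {
  gsub("[‘’ʼ]", "'", x, perl = TRUE)
}

# Locate every match of a perl regex, returning a data.frame of start/end
# positions for the full match and each capture group.
regex_scan <- function(text, pattern, ignore_case = TRUE) {
  m <- gregexpr(pattern, text, perl = TRUE, ignore.case = ignore_case)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(), end = integer()))
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  out <- data.frame(start = starts, end = starts + lens - 1L)
  cs <- attr(m, "capture.start")
  if (!is.null(cs)) {
    cl <- attr(m, "capture.length")
    for (j in seq_len(ncol(cs))) {
      nm <- colnames(cs)[j]
      if (is.null(nm) || nm == "") nm <- paste0("g", j)
      out[[paste0(nm, "_start")]] <- as.integer(cs[, j])
      out[[paste0(nm, "_end")]] <- as.integer(cs[, j]) + as.integer(cl[, j]) - 1L
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Informational logging used by ingest/sampling paths; routed through
# message() so callers and tests can suppress or capture it.
log_info <- function(fmt, ...) {
  message(sprintf(fmt, ...))
}

path_extdata <- function(file) {
  system.file("extdata", file, package = "dtcreactions", mustWork = TRUE)
}
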