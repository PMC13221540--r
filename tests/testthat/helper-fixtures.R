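# Shared fixtures built in code.

# A tiny hand-written corpus exercising every annotation path.
tiny_corpus <- function() {
  as_corpus(tibble::tibble(
    id = c("p1", "p2", "p3", "p4", "p5"),
    platform = c("reddit", "reddit", "youtube", "googleplay", "synthetic"),
    text = c(
      "I got 45% Irish and 30% Italian. I was shocked - no way this is right",
      "Scandinavian: 18.5% overall. Makes sense, exactly what I expected.",
      "I'm Irish and Italian. My 23andme kit arrived today.",
      "Bought a kit yesterday",
      ""
    ),
    author = c("alice", "bob", NA, "dee", ""),
    timestamp = as.POSIXct(c("2024-01-01 10:00:00", NA, "2024-03-05 00:30:00",
                             "2024-06-01 12:00:00", NA), tz = "UTC"),
    engagement = c(10L, NA, 3L, 0L, NA)
  ))
}

# The six published per-category confusion counts used as a worked example
# for the agreement metrics (annotated sample of 299 posts).
published_validation_counts <- function() {
  tibble::tibble(
    category = c("surprise", "dispute", "acceptance", "disappointment",
                 "identity_crisis", "excitement"),
    tp = c(51L, 58L, 70L, 46L, 38L, 50L),
    fp = c(3L, 17L, 13L, 10L, 8L, 15L),
    fn = c(2L, 2L, 1L, 0L, 1L, 1L),
    tn = c(243L, 222L, 215L, 243L, 252L, 233L)
  )
}

# Uniform-weight generator config concentrated on a handful of categories,
# handy for recovery tests.
small_gen_config <- function(n_posts, seed, ...) {
  generator_config(n_posts = n_posts, seed = seed, ...)
}

flags_matrix <- function(corpus) {
  m <- as.matrix(tibble::as_tibble(corpus)[, paste0("reaction_",
                                                    reactionCategories())])
  colnames(m) <- reactionCategories()
  m
}

expect_tibble_equal <- function(a, b) {
  expect_equal(as.data.frame(a), as.data.frame(b))
}
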