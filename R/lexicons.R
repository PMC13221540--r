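#' Lexicon resources
#'
#' Loaders and validators for the configuration resources that drive
#' extraction and classification: the ethnicity normalization lexicon
#' (42 standardized categories across six geographic regions), the
#' six-category reaction keyword lexicon, and the company alias lexicon.
#' Each ships with the package and can be replaced by a user-edited YAML
#' file with the same structure.
#'
#' @name lexicons
NULL

REACTION_CATEGORIES <- c(
  "surprise", "dispute", "acceptance",
  "disappointment", "identity_crisis", "excitement"
)

REGION_LEVELS <- c(
  "European", "African", "Asian", "Americas", "Middle Eastern", "Oceania"
)

# Expected number of categories per region in the shipped lexicon.
REGION_CATEGORY_COUNTS <- c(
  European = 12L, African = 7L, Asian = 9L, Americas = 8L,
  `Middle Eastern` = 3L, Oceania = 3L
)

#' Reaction category identifiers
#'
#' The six reaction categories in their fixed order (used, for example, as
#' the stratum fill order in [stratified_validation_sample()]).
#'
#' @return Character vector of six category ids.
#' @export
reactionCategories <- function() REACTION_CATEGORIES

#' Read and validate an ethnicity normalization lexicon
#'
#' The YAML file maps each normalized category id to a geographic region, a
#' display name, and a list of lowercase surface terms (including country
#' names used by the born/raised-in identity pattern). Validation enforces
#' the lexicon invariants: 42 categories with regional counts 12/7/9/8/3/3,
#' every region one of the six recognized regions, and surface terms unique
#' across the lexicon (each term maps to exactly one category).
#'
#' @param path Path to a YAML lexicon file.
#' @param check_counts Enforce the 42-category regional layout (disable for
#'   user-extended lexicons that add or reorganize categories).
#' @return An object of class `ethnicity_lexicon`: a list with `categories`
#'   (tibble: category, region, display) and `terms` (named character vector
#'   mapping lowercase surface term to category id).
#' @export
read_ethnicity_lexicon <- function(path, check_counts = TRUE) {
  raw <- yaml::read_yaml(path)
  cats <- raw$categories
  if (is.null(cats) || !length(cats)) {
    stop("ethnicity lexicon has no 'categories' entry", call. = FALSE)
  }
  categories <- tibble::tibble(
    category = names(cats),
    region = vapply(cats, function(x) x$region, character(1)),
    display = vapply(cats, function(x) x$display %||% NA_character_, character(1))
  )
  term_list <- lapply(cats, function(x) tolower(trimws(unlist(x$terms))))
  terms <- stats::setNames(
    rep(names(term_list), lengths(term_list)),
    unlist(term_list, use.names = FALSE)
  )
  lex <- structure(
    list(categories = categories, terms = terms),
    class = "ethnicity_lexicon"
  )
  validate_ethnicity_lexicon(lex, check_counts = check_counts)
  lex
}

#' @rdname read_ethnicity_lexicon
#' @param lexicon An `ethnicity_lexicon` object.
#' @export
validate_ethnicity_lexicon <- function(lexicon, check_counts = TRUE) {
  stopifnot(inherits(lexicon, "ethnicity_lexicon"))
  cats <- lexicon$categories
  if (anyDuplicated(cats$category)) {
    stop("duplicate category ids in ethnicity lexicon", call. = FALSE)
  }
  bad_region <- setdiff(unique(cats$region), REGION_LEVELS)
  if (length(bad_region)) {
    stop("unknown region(s): ", paste(bad_region, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(names(lexicon$terms))) {
    dups <- unique(names(lexicon$terms)[duplicated(names(lexicon$terms))])
    stop("surface term(s) mapped to more than one category: ",
         paste(dups, collapse = ", "), call. = FALSE)
  }
  if (!all(lexicon$terms %in% cats$category)) {
    stop("term target not among declared categories", call. = FALSE)
  }
  if (check_counts) {
    if (nrow(cats) != 42L) {
      stop("expected 42 categories, found ", nrow(cats), call. = FALSE)
    }
    counts <- table(factor(cats$region, levels = REGION_LEVELS))
    if (!all(as.integer(counts) == as.integer(REGION_CATEGORY_COUNTS[names(counts)]))) {
      stop("regional category counts do not match the 12/7/9/8/3/3 layout",
           call. = FALSE)
    }
  }
  invisible(lexicon)
}

#' @rdname read_ethnicity_lexicon
#' @export
defaultEthnicityLexicon <- function() {
  read_ethnicity_lexicon(path_extdata("ethnicity_lexicon.yml"))
}

#' @export
print.ethnicity_lexicon <- function(x, ...) {
  cat("<ethnicity_lexicon>", nrow(x$categories), "categories,",
      length(x$terms), "surface terms\n")
  print(table(factor(x$categories$region, levels = REGION_LEVELS)))
  invisible(x)
}

#' Read and validate a reaction keyword lexicon
#'
#' The YAML file maps each of the six reaction categories to a non-empty
#' list of lowercase keyword phrases. Validation enforces that all six
#' categories are present and non-empty, phrases are stored lowercase, and
#' no phrase appears under more than one category.
#'
#' @param path Path to a YAML keyword file.
#' @return An object of class `reaction_lexicon`: a named list of character
#'   vectors, one per category, in the fixed category order.
#' @export
read_reaction_lexicon <- function(path) {
  raw <- yaml::read_yaml(path)
  missing <- setdiff(REACTION_CATEGORIES, names(raw))
  if (length(missing)) {
    stop("reaction lexicon missing categories: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lex <- lapply(raw[REACTION_CATEGORIES], function(x) {
    tolower(trimws(unlist(x)))
  })
  lex <- structure(lex, class = "reaction_lexicon")
  validate_reaction_lexicon(lex)
  lex
}

#' @rdname read_reaction_lexicon
#' @param lexicon A `reaction_lexicon` object.
#' @export
validate_reaction_lexicon <- function(lexicon) {
  stopifnot(inherits(lexicon, "reaction_lexicon"))
  if (!identical(names(lexicon), REACTION_CATEGORIES)) {
    stop("reaction lexicon categories must be exactly the six known ids",
         call. = FALSE)
  }
  if (any(lengths(lexicon) == 0L)) {
    stop("every reaction category must have at least one phrase", call. = FALSE)
  }
  all_phrases <- unlist(lexicon, use.names = FALSE)
  if (any(all_phrases != tolower(all_phrases))) {
    stop("phrases must be stored lowercase", call. = FALSE)
  }
  if (anyDuplicated(all_phrases)) {
    dups <- unique(all_phrases[duplicated(all_phrases)])
    stop("phrase(s) under more than one category: ",
         paste(dups, collapse = ", "), call. = FALSE)
  }
  invisible(lexicon)
}

#' @rdname read_reaction_lexicon
#' @export
defaultReactionLexicon <- function() {
  read_reaction_lexicon(path_extdata("reaction_keywords.yml"))
}

#' @export
print.reaction_lexicon <- function(x, ...) {
  cat("<reaction_lexicon>\n")
  for (cat_id in names(x)) {
    cat(" ", cat_id, ": ", length(x[[cat_id]]), " phrases\n", sep = "")
  }
  invisible(x)
}

#' Read a company alias lexicon
#'
#' Maps each canonical company name to a list of lowercase aliases
#' (including spacing variants such as "23 and me").
#'
#' @param path Path to a YAML file.
#' @return Named list of character vectors (class `company_lexicon`).
#' @export
read_company_lexicon <- function(path) {
  raw <- yaml::read_yaml(path)
  lex <- lapply(raw, function(x) tolower(trimws(unlist(x))))
  structure(lex, class = "company_lexicon")
}

#' @rdname read_company_lexicon
#' @export
defaultCompanyLexicon <- function() {
  read_company_lexicon(path_extdata("companies.yml"))
}

#' English stopword list
#'
#' The snowball-style English stopword list shipped with the package, used
#' by [build_dtm()].
#'
#' @return Character vector of lowercase stopwords.
#' @export
defaultStopwords <- function() {
  readLines(path_extdata("stopwords_english.txt"), warn = FALSE)
}
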