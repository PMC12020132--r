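#' Part-of-speech tagset
#'
#' The internal closed tagset every tokenizer must map into.  Morphological
#' analyzers for unsegmented languages emit their own dictionary-specific
#' tag names; an adapter translates those into this set, with anything
#' unmapped landing in `"other"` (which the default filter rules drop).
#'
#' @format character vector of major part-of-speech categories.
#' @export
POS_MAJOR <- c("noun", "verb", "adjective", "adverb", "interjection",
               "prenominal", "symbol", "particle", "auxiliary_verb", "other")

PROPER_NOUN_MINOR <- c("proper_noun_person", "proper_noun_org",
                       "proper_noun_location")

.tokenizers <- new.env(parent = emptyenv())

#' Register a tokenizer
#'
#' A tokenizer is a function from a character scalar to a token tibble
#' with columns `surface`, `base_form`, `pos_major`, `pos_minor`.  It must
#' be deterministic and must tag every token.  Registration makes the
#' tokenizer available to [tokenize()] by name, so corpora, configs and
#' tests can refer to tokenizers symbolically.
#'
#' @param name tokenizer name.
#' @param fn the tokenizing function.
#' @return `name`, invisibly.
#' @export
register_tokenizer <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1, is.function(fn))
  assign(name, fn, envir = .tokenizers)
  invisible(name)
}

get_tokenizer <- function(name) {
  if (!exists(name, envir = .tokenizers, inherits = FALSE)) {
    stop("no tokenizer registered under name '", name, "'", call. = FALSE)
  }
  get(name, envir = .tokenizers, inherits = FALSE)
}

#' Tokenize text
#'
#' Applies a registered tokenizer and validates its output against the
#' token contract: non-empty surfaces and `pos_major` values drawn from
#' [POS_MAJOR] (unknown categories are coerced to `"other"`).
#'
#' @param text character scalar.
#' @param tokenizer name of a registered tokenizer (default `"annotated"`,
#'   the pre-annotated fixture dialect; see [annotated_tokenizer()]).
#' @return token tibble: `surface`, `base_form`, `pos_major`, `pos_minor`.
#' @export
tokenize <- function(text, tokenizer = "annotated") {
  fn <- get_tokenizer(tokenizer)
  tk <- tibble::as_tibble(fn(text))
  if (nrow(tk) == 0) {
    return(tibble::tibble(surface = character(), base_form = character(),
                          pos_major = character(), pos_minor = character()))
  }
  stopifnot(all(c("surface", "base_form", "pos_major", "pos_minor") %in%
                  names(tk)))
  if (any(!nzchar(tk$surface))) stop("tokenizer emitted an empty surface")
  tk$pos_major[!tk$pos_major %in% POS_MAJOR] <- "other"
  tk
}

#' The pre-annotated fixture tokenizer
#'
#' Parses the language-neutral annotated dialect used throughout the test
#' suite and by the synthetic corpus generator: whitespace-separated items
#' of the form `surface/pos_major`, `surface/pos_major:pos_minor`, or
#' `surface/pos_major:pos_minor=base_form`.  Omitted fields default to
#' `pos_minor = "general"` and `base_form = surface`.  This makes the
#' whole pipeline runnable on pre-tagged token streams without any
#' language-specific morphological analyzer: the analysis itself is
#' tokenizer-agnostic, and a real analyzer plugs in as another registered
#' adapter emitting the same contract.
#'
#' @param text annotated character scalar.
#' @return token tibble.
#' @export
#' @examples
#' annotated_tokenizer("CRP/noun rise/verb ./symbol")
annotated_tokenizer <- function(text) {
  if (is.na(text) || !nzchar(trimws(text))) {
    return(tibble::tibble(surface = character(), base_form = character(),
                          pos_major = character(), pos_minor = character()))
  }
  items <- stringi::stri_split_regex(trimws(text), "\\s+")[[1]]
  m <- stringi::stri_match_first_regex(
    items, "^(.+?)/([a-z_]+)(?::([a-z_]+))?(?:=(.+))?$")
  if (anyNA(m[, 1])) {
    stop("unparseable annotated token(s): ",
         paste(items[is.na(m[, 1])], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    surface = m[, 2],
    base_form = ifelse(is.na(m[, 5]), m[, 2], m[, 5]),
    pos_major = m[, 3],
    pos_minor = ifelse(is.na(m[, 4]), "general", m[, 4]))
}

#' Tokenize every record of a corpus
#'
#' @param x a corpus whose records carry `text`.
#' @param tokenizer registered tokenizer name.
#' @return the corpus with its `tokens` table filled.
#' @export
tokenize_corpus <- function(x, tokenizer = "annotated") {
  stopifnot(inherits(x, "tn_corpus"))
  toks <- lapply(seq_len(nrow(x$records)), function(i) {
    tk <- tokenize(x$records$text[i], tokenizer)
    if (nrow(tk) == 0) return(NULL)
    tk$record_id <- x$records$record_id[i]
    tk$position <- seq_len(nrow(tk))
    tk
  })
  toks <- toks[!vapply(toks, is.null, TRUE)]
  x$tokens <- if (length(toks)) dplyr::bind_rows(toks) else
    tibble::tibble(surface = character(), base_form = character(),
                   pos_major = character(), pos_minor = character(),
                   record_id = character(), position = integer())
  x
}

.onLoad <- function(libname, pkgname) {
  register_tokenizer("annotated", annotated_tokenizer)
}
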