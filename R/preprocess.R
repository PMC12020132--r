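#' Part-of-speech filter rules
#'
#' The default rules implement the usual content-word filter for clinical
#' note mining: keep nouns, verbs, adjectives, adverbs, interjections and
#' prenominal adjectives; within nouns drop suffixes, numbers, pronouns,
#' formal (grammatical) nouns and auxiliary nouns; within adjectives drop
#' auxiliary adjectives; drop all symbols, particles and auxiliary verbs
#' outright (and anything tagged `"other"`).
#'
#' @param keep_major major categories retained.
#' @param drop_minor named list mapping a kept major category to the minor
#'   categories excluded within it.
#' @param drop_major major categories excluded outright.
#' @return an object of class `tn_pos_rules`.
#' @export
pos_filter_rules <- function(
    keep_major = c("noun", "verb", "adjective", "adverb", "interjection",
                   "prenominal"),
    drop_minor = list(
      noun = c("suffix", "number", "pronoun", "formal_noun", "auxiliary"),
      adjective = "auxiliary_adjective"),
    drop_major = c("symbol", "particle", "auxiliary_verb", "other")) {
  if (length(intersect(keep_major, drop_major))) {
    stop("keep_major and drop_major must be disjoint", call. = FALSE)
  }
  stopifnot(all(keep_major %in% POS_MAJOR), all(drop_major %in% POS_MAJOR))
  structure(list(keep_major = keep_major, drop_minor = drop_minor,
                 drop_major = drop_major),
            class = "tn_pos_rules")
}

#' Filter tokens by part of speech
#'
#' Retains tokens whose `pos_major` is kept and whose `pos_minor` is not
#' excluded for that category.  Idempotent, and commutes with
#' [anonymize_tokens()].
#'
#' @param tokens token tibble.
#' @param rules a [pos_filter_rules()] object.
#' @return the filtered token tibble.
#' @export
pos_filter <- function(tokens, rules = pos_filter_rules()) {
  stopifnot(inherits(rules, "tn_pos_rules"))
  keep <- tokens$pos_major %in% rules$keep_major
  for (major in names(rules$drop_minor)) {
    keep <- keep & !(tokens$pos_major == major &
                       tokens$pos_minor %in% rules$drop_minor[[major]])
  }
  tokens[keep, ]
}

#' Remove proper-noun identifiers from a token stream
#'
#' Drops (or redacts) tokens tagged as personal, organizational or
#' geographic proper nouns — the researcher-side anonymization pass run on
#' free text before any counting.
#'
#' @param tokens token tibble carrying proper-noun `pos_minor`
#'   subcategories.
#' @param placeholder if `NULL` (default) identifier tokens are removed;
#'   otherwise they are replaced by this redaction string (tagged
#'   `noun:redacted`).
#' @return the anonymized token tibble.
#' @export
anonymize_tokens <- function(tokens, placeholder = NULL) {
  hit <- tokens$pos_minor %in% PROPER_NOUN_MINOR
  if (is.null(placeholder)) return(tokens[!hit, ])
  tokens$surface[hit] <- placeholder
  tokens$base_form[hit] <- placeholder
  tokens$pos_minor[hit] <- "redacted"
  tokens
}

#' Apply part-of-speech filtering and anonymization to a corpus
#'
#' @param x tokenized corpus.
#' @param rules [pos_filter_rules()].
#' @param placeholder passed to [anonymize_tokens()].
#' @return the corpus with its token table filtered.
#' @export
preprocess_corpus <- function(x, rules = pos_filter_rules(),
                              placeholder = NULL) {
  stopifnot(inherits(x, "tn_corpus"), !is.null(x$tokens))
  x$tokens <- pos_filter(anonymize_tokens(x$tokens, placeholder), rules)
  x
}

#' Terminology standardization tables
#'
#' Bundles the three mapping tables produced during term standardization:
#' synonym sets keyed by controlled-vocabulary identifiers (terms mapped
#' to the same MeSH or SNOMED CT code are one synonym set and collapse to
#' one canonical term), exclusion words, and the compound lexicon (noun
#' sequences re-tokenized as single terms).
#'
#' @param synonyms tibble with columns `term`, `canonical`,
#'   `vocabulary_id` (identifier such as a MeSH descriptor or SNOMED
#'   concept id); may have zero rows.
#' @param exclusions character vector of terms removed from analysis.
#' @param compounds tibble with columns `parts` (space-joined token
#'   sequence) and `canonical` (the merged term); may have zero rows.
#' @return an object of class `tn_tables`.
#' @export
standardization_tables <- function(synonyms = NULL, exclusions = character(),
                                   compounds = NULL) {
  synonyms <- if (is.null(synonyms))
    tibble::tibble(term = character(), canonical = character(),
                   vocabulary_id = character())
  else tibble::as_tibble(synonyms)
  compounds <- if (is.null(compounds))
    tibble::tibble(parts = character(), canonical = character())
  else tibble::as_tibble(compounds)
  stopifnot(all(c("term", "canonical") %in% names(synonyms)),
            all(c("parts", "canonical") %in% names(compounds)))
  clash <- intersect(normalize_term(synonyms$canonical),
                     normalize_term(exclusions))
  if (length(clash)) {
    stop("canonical term(s) also listed as exclusions: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  structure(list(synonyms = synonyms,
                 exclusions = as.character(exclusions),
                 compounds = compounds),
            class = "tn_tables")
}

#' Read standardization tables from tab-separated files
#'
#' Expected layouts (UTF-8, with header): `synonyms.tsv` — `term`,
#' `canonical`, `vocabulary_id`; `exclusions.tsv` — `term`;
#' `compounds.tsv` — `parts`, `canonical` (extra columns such as scores
#' are ignored).
#'
#' @param synonyms,exclusions,compounds file paths; `NULL` for an empty
#'   table.
#' @return a [standardization_tables()] object.
#' @export
read_standardization_tables <- function(synonyms = NULL, exclusions = NULL,
                                        compounds = NULL) {
  rd <- function(p) if (is.null(p)) NULL else
    tibble::as_tibble(utils::read.delim(p, colClasses = "character",
                                        fileEncoding = "UTF-8"))
  ex <- rd(exclusions)
  standardization_tables(
    synonyms = rd(synonyms),
    exclusions = if (is.null(ex)) character() else ex$term,
    compounds = rd(compounds))
}

#' Normalize a term for matching
#'
#' Full-width characters are folded to half-width and alphabetic text is
#' lowercased, so that mapping tables that mix scripts and case still
#' match.  Canonical output forms are *not* normalized; normalization is
#' applied to lookup keys only.
#'
#' @param x character vector.
#' @return normalized character vector.
#' @export
normalize_term <- function(x) {
  stringi::stri_trans_tolower(
    stringi::stri_trans_general(x, "Fullwidth-Halfwidth"))
}

#' Standardize a corpus into analyzed terms
#'
#' Turns the filtered token stream of each record into the final analyzed
#' term stream in three passes: (1) greedy longest-match, left-to-right
#' merging of contiguous token runs listed in the compound lexicon;
#' (2) mapping every term through the synonym table to its canonical
#' form; (3) removal of exclusion words and single alphabet characters.
#' Matching is on normalized base forms by default (surfaces via
#' `use_base = FALSE`); standardization only merges, maps or drops, so it
#' never increases the number of distinct term types.
#'
#' @param x preprocessed corpus (tokens filtered).
#' @param tables [standardization_tables()].
#' @param use_base match and emit base forms (default) or surfaces.
#' @return the corpus with its `terms` table filled (`record_id`,
#'   `position`, `term`).
#' @export
standardize_corpus <- function(x, tables = standardization_tables(),
                               use_base = TRUE) {
  stopifnot(inherits(x, "tn_corpus"), !is.null(x$tokens),
            inherits(tables, "tn_tables"))
  syn_map <- stats::setNames(tables$synonyms$canonical,
                             normalize_term(tables$synonyms$term))
  excl <- normalize_term(tables$exclusions)
  comp_parts <- strsplit(normalize_term(tables$compounds$parts), " ",
                         fixed = TRUE)
  comp_map <- stats::setNames(tables$compounds$canonical,
                              vapply(comp_parts, paste, "", collapse = " "))
  max_len <- if (length(comp_parts)) max(lengths(comp_parts)) else 1L

  col <- if (use_base) "base_form" else "surface"
  toks <- x$tokens
  by_rec <- split(seq_len(nrow(toks)), toks$record_id)
  out <- lapply(names(by_rec), function(rid) {
    terms <- toks[[col]][by_rec[[rid]]]
    keys <- normalize_term(terms)
    n <- length(terms)
    res <- character(0)
    i <- 1L
    while (i <= n) {
      merged <- FALSE
      if (max_len >= 2 && n - i + 1L >= 2L) {
        for (L in seq(min(max_len, n - i + 1L), 2L)) {
          key <- paste(keys[i:(i + L - 1L)], collapse = " ")
          if (!is.na(comp_map[key])) {
            res <- c(res, comp_map[[key]])
            i <- i + L
            merged <- TRUE
            break
          }
        }
      }
      if (!merged) {
        res <- c(res, terms[i])
        i <- i + 1L
      }
    }
    # synonym mapping, then exclusion / single-letter removal
    k <- normalize_term(res)
    mapped <- ifelse(is.na(syn_map[k]), res, syn_map[k])
    k2 <- normalize_term(mapped)
    keep <- !(k2 %in% excl) & !grepl("^[a-z]$", k2)
    kept <- unname(mapped[keep])
    if (!length(kept)) return(NULL)
    tibble::tibble(record_id = rid, position = seq_along(kept), term = kept)
  })
  out <- out[!vapply(out, is.null, TRUE)]
  x$terms <- if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(record_id = character(), position = integer(),
                   term = character())
  x
}
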