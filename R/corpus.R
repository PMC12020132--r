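#' Construct a record corpus
#'
#' A corpus bundles the clinical records under analysis with (optionally)
#' their token streams, their standardized analyzed-term streams, and the
#' per-period totals of the full record base they were drawn from.  The
#' totals are carried separately because seed-term selection keeps only a
#' few percent of all records, yet share-of-total statistics must still be
#' computed against the full denominators.
#'
#' @param records tibble with columns `record_id`, `period` (`"pre"` /
#'   `"post"`), `month` (`"YYYY-MM"`), and optionally `text` and
#'   `record_type`.
#' @param tokens optional tibble of tokens: `record_id`, `position`,
#'   `surface`, `base_form`, `pos_major`, `pos_minor`.
#' @param terms optional tibble of analyzed terms: `record_id`, `position`,
#'   `term` (produced by [standardize_corpus()]).
#' @param totals optional named integer vector `c(pre = ..., post = ...)`
#'   giving the total record count per period *including* records that do
#'   not contain the seed term.
#' @return an object of class `tn_corpus`.
#' @export
corpus <- function(records, tokens = NULL, terms = NULL, totals = NULL) {
  records <- tibble::as_tibble(records)
  req <- c("record_id", "period", "month")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols)) {
    stop("records is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(records$record_id)) {
    stop("record_id values must be unique within a corpus", call. = FALSE)
  }
  assert_month(records$month)
  if (!all(records$period %in% c("pre", "post"))) {
    stop("period must be 'pre' or 'post'", call. = FALSE)
  }
  if (!is.null(totals)) {
    totals <- as.integer(totals[c("pre", "post")])
    names(totals) <- c("pre", "post")
    kept <- table(factor(records$period, c("pre", "post")))
    if (any(!is.na(totals) & totals < as.integer(kept))) {
      stop("per-period totals cannot be smaller than the records retained",
           call. = FALSE)
    }
  }
  structure(
    list(records = records,
         tokens = if (!is.null(tokens)) tibble::as_tibble(tokens),
         terms = if (!is.null(terms)) tibble::as_tibble(terms),
         totals = totals),
    class = "tn_corpus")
}

#' @export
print.tn_corpus <- function(x, ...) {
  n <- table(factor(x$records$period, c("pre", "post")))
  cat(sprintf("<tn_corpus> %d records (pre %d / post %d)%s%s\n",
              nrow(x$records), n[["pre"]], n[["post"]],
              if (!is.null(x$tokens)) sprintf("; %d tokens", nrow(x$tokens)) else "",
              if (!is.null(x$terms)) sprintf("; %d analyzed terms", nrow(x$terms)) else ""))
  if (!is.null(x$totals)) {
    cat(sprintf("  drawn from totals: pre %s / post %s\n",
                x$totals[["pre"]], x$totals[["post"]]))
  }
  invisible(x)
}

#' Derive the period label from the calendar month
#'
#' Records dated at or after the cutoff month belong to the post period;
#' everything earlier is pre.  The assignment is exhaustive and exclusive.
#'
#' @param month character vector of `"YYYY-MM"` months.
#' @param cutoff first month of the post (intervention) period.
#' @return character vector of `"pre"` / `"post"` labels.
#' @export
#' @examples
#' period_from_month(c("2018-03", "2018-04"), cutoff = "2018-04")
period_from_month <- function(month, cutoff = "2018-04") {
  assert_month(month); assert_month(cutoff, "cutoff")
  ifelse(month >= cutoff, "post", "pre")
}

#' Read records from JSONL or CSV
#'
#' Each row/line must provide `record_id`, `text`, and either `month`
#' (from which the period is derived using `cutoff`) or an explicit
#' `period`.  JSONL rows may additionally carry a pre-tokenized `tokens`
#' array of objects with `surface`, `base_form`, `pos_major`, `pos_minor`.
#'
#' @param path file to read.
#' @param format `"auto"` (by extension), `"jsonl"`, or `"csv"`.
#' @param cutoff cutoff month passed to [period_from_month()] when a row
#'   has no explicit period.
#' @return a [corpus()] (tokens attached when present in the input).
#' @export
read_records <- function(path, format = c("auto", "jsonl", "csv"),
                         cutoff = "2018-04") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (format == "csv") {
    df <- tibble::as_tibble(utils::read.csv(path, colClasses = "character"))
    rows <- NULL
  } else {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(lines, jsonlite::fromJSON, simplifyDataFrame = TRUE)
    df <- tibble::tibble(
      record_id = vapply(rows, function(r) as.character(r$record_id %||% NA_character_), ""),
      month = vapply(rows, function(r) as.character(r$month %||% NA_character_), ""),
      period = vapply(rows, function(r) as.character(r$period %||% NA_character_), ""),
      text = vapply(rows, function(r) as.character(r$text %||% NA_character_), ""),
      record_type = vapply(rows, function(r) as.character(r$record_type %||% NA_character_), ""))
  }
  for (col in c("record_id", "text")) {
    if (!col %in% names(df) || all(is.na(df[[col]]))) {
      stop("input is missing required column: ", col, call. = FALSE)
    }
  }
  has_month <- "month" %in% names(df) && !all(is.na(df$month))
  has_period <- "period" %in% names(df) && !all(is.na(df$period))
  if (!has_month && !has_period) {
    stop("input is missing required column: month (or period)", call. = FALSE)
  }
  if (has_month) {
    bad <- !is_month(df$month)
    if (any(bad)) {
      stop(sprintf("unparseable month for record_id %s",
                   paste(df$record_id[bad], collapse = ", ")), call. = FALSE)
    }
  }
  if (!has_period || anyNA(df$period) || any(!nzchar(df$period))) {
    df$period <- period_from_month(df$month, cutoff)
  }
  if (!"record_type" %in% names(df)) df$record_type <- NA_character_
  tokens <- NULL
  if (!is.null(rows)) {
    tok_rows <- lapply(seq_along(rows), function(i) {
      tk <- rows[[i]]$tokens
      if (is.null(tk) || NROW(tk) == 0) return(NULL)
      tk <- tibble::as_tibble(tk)
      tk$record_id <- df$record_id[i]
      tk$position <- seq_len(nrow(tk))
      tk
    })
    tok_rows <- tok_rows[!vapply(tok_rows, is.null, TRUE)]
    if (length(tok_rows)) tokens <- dplyr::bind_rows(tok_rows)
  }
  corpus(df[c("record_id", "period", "month", "text", "record_type")],
         tokens = tokens)
}

#' Write records to JSONL or CSV
#'
#' Inverse of [read_records()]: content fields round-trip losslessly.
#'
#' @param x a corpus.
#' @param path output file.
#' @param format `"jsonl"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_records <- function(x, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "tn_corpus"))
  if (format == "csv") {
    utils::write.csv(x$records, path, row.names = FALSE)
    return(invisible(path))
  }
  toks <- if (!is.null(x$tokens)) split(x$tokens, x$tokens$record_id)
  lines <- vapply(seq_len(nrow(x$records)), function(i) {
    rec <- as.list(x$records[i, ])
    rec <- rec[!vapply(rec, is.na, TRUE)]
    tk <- toks[[x$records$record_id[i]]]
    if (!is.null(tk)) {
      rec$tokens <- tk[c("surface", "base_form", "pos_major", "pos_minor")]
    }
    jsonlite::toJSON(rec, auto_unbox = TRUE, dataframe = "rows")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

seed_match_records <- function(x, seed_variants) {
  if (!is.null(x$tokens)) {
    hit <- x$tokens$base_form %in% seed_variants |
      x$tokens$surface %in% seed_variants
    unique(x$tokens$record_id[hit])
  } else {
    if (!"text" %in% names(x$records)) {
      stop("corpus has neither tokens nor record text to match against",
           call. = FALSE)
    }
    pat <- paste(vapply(seed_variants, function(v)
      stringi::stri_replace_all_regex(v, "([\\\\.^$|()\\[\\]{}*+?])", "\\\\$1"),
      ""), collapse = "|")
    x$records$record_id[stringi::stri_detect_regex(x$records$text, pat)]
  }
}

#' Select records containing the seed term
#'
#' Retains exactly the records whose token stream (base form or surface;
#' raw-text substring match when no tokens are attached) contains at least
#' one of the seed variants.  The original per-period totals are recorded
#' on the subset so that share-of-total statistics remain computable.
#'
#' @param x a corpus.
#' @param seed_variants non-empty character vector of seed surface forms,
#'   e.g. `c("antimicrobial", "antibiotic", "antibacterial",
#'   "anti-infective")`.
#' @param drop_record_types record types excluded before matching (the
#'   stewardship team's own notes, for instance); `NULL` keeps everything.
#' @return the corpus subset, with `totals` set to the pre-selection
#'   per-period record counts (unless already present).
#' @export
select_seed_records <- function(x, seed_variants, drop_record_types = NULL) {
  stopifnot(inherits(x, "tn_corpus"))
  if (length(seed_variants) == 0) {
    stop("seed_variants must be non-empty", call. = FALSE)
  }
  if (!is.null(drop_record_types)) {
    keep_ids <- x$records$record_id[
      !(x$records$record_type %in% drop_record_types)]
    x <- subset_corpus(x, keep_ids, keep_totals = FALSE)
  }
  totals <- x$totals
  if (is.null(totals)) {
    tab <- table(factor(x$records$period, c("pre", "post")))
    totals <- stats::setNames(as.integer(tab), c("pre", "post"))
  }
  ids <- seed_match_records(x, seed_variants)
  out <- subset_corpus(x, ids, keep_totals = FALSE)
  out$totals <- totals
  out
}

subset_corpus <- function(x, record_ids, keep_totals = TRUE) {
  keep <- x$records$record_id %in% record_ids
  corpus(x$records[keep, ],
         tokens = if (!is.null(x$tokens))
           x$tokens[x$tokens$record_id %in% record_ids, ],
         terms = if (!is.null(x$terms))
           x$terms[x$terms$record_id %in% record_ids, ],
         totals = if (keep_totals) x$totals)
}

#' Drop records from a given month onward
#'
#' Used for the pandemic sensitivity analysis: records dated
#' `exclude_from` or later are removed, leaving the pre period intact and
#' truncating the post period to its early window.  Per-period totals are
#' dropped because they are no longer known for the truncated window.
#'
#' @param x a corpus.
#' @param exclude_from first month to exclude (`"YYYY-MM"`).
#' @return the corpus subset with `month < exclude_from`.
#' @export
filter_by_month <- function(x, exclude_from) {
  stopifnot(inherits(x, "tn_corpus"))
  assert_month(exclude_from, "exclude_from")
  subset_corpus(x, x$records$record_id[x$records$month < exclude_from],
                keep_totals = FALSE)
}

#' Per-period corpus summary
#'
#' Computes, for each period, the documentation characteristics reported
#' for a study corpus: total records, seed-containing records and their
#' share of the total, and mean +/- SD of characters, raw terms (tokens)
#' and analyzed terms per record.
#'
#' @param x a corpus (tokenized and standardized for the term columns to
#'   be filled).
#' @return a tibble with one row per period.
#' @export
summarize_corpus <- function(x) {
  stopifnot(inherits(x, "tn_corpus"))
  out <- lapply(c("pre", "post"), function(p) {
    recs <- x$records[x$records$period == p, ]
    n <- nrow(recs)
    if (n == 0) {
      warning("no records in period '", p, "'; summary left empty",
              call. = FALSE)
      return(tibble::tibble(
        period = p, total_records = x$totals[[p]] %||% NA_integer_,
        seed_records = 0L, share_pct = NA_real_,
        chars_mean = NA_real_, chars_sd = NA_real_,
        raw_terms_mean = NA_real_, raw_terms_sd = NA_real_,
        analyzed_terms_mean = NA_real_, analyzed_terms_sd = NA_real_))
    }
    total <- x$totals[[p]] %||% NA_integer_
    per_rec <- function(df) {
      if (is.null(df)) return(rep(NA_real_, n))
      cnt <- table(factor(df$record_id, recs$record_id))
      as.numeric(cnt)
    }
    chars <- if ("text" %in% names(recs) && !all(is.na(recs$text)))
      nchar(recs$text) else rep(NA_real_, n)
    raw <- per_rec(x$tokens)
    ana <- per_rec(x$terms)
    sd0 <- function(v) if (length(v) < 2) 0 else stats::sd(v)
    tibble::tibble(
      period = p, total_records = total, seed_records = n,
      share_pct = if (is.na(total)) NA_real_ else share_percent(n, total),
      chars_mean = round_half_up(mean(chars), 1),
      chars_sd = round_half_up(sd0(chars), 1),
      raw_terms_mean = round_half_up(mean(raw), 1),
      raw_terms_sd = round_half_up(sd0(raw), 1),
      analyzed_terms_mean = round_half_up(mean(ana), 1),
      analyzed_terms_sd = round_half_up(sd0(ana), 1))
  })
  dplyr::bind_rows(out)
}
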