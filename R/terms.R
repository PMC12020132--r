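#' Extract compound-term candidates
#'
#' Scans the part-of-speech-filtered token stream of every record and
#' emits one candidate per *maximal* contiguous run of noun tokens
#' (runs of length 1 included — their neighbor statistics feed the
#' scoring).  Frequencies are aggregated corpus-wide, as are the noun
#' bigram counts needed by [score_lr()], which travel along as the
#' `"bigrams"` attribute.
#'
#' @param x corpus with a (filtered) token table, or a token tibble.
#' @param use_base count base forms (default) or surfaces.
#' @return tibble `parts` (space-joined noun run), `length`, `frequency`,
#'   with attribute `"bigrams"`: tibble `left`, `right`, `count` of
#'   adjacent noun pairs.
#' @export
extract_candidates <- function(x, use_base = TRUE) {
  toks <- if (inherits(x, "tn_corpus")) x$tokens else tibble::as_tibble(x)
  stopifnot(!is.null(toks))
  col <- if (use_base) "base_form" else "surface"
  runs <- character(0)
  bi_l <- character(0)
  bi_r <- character(0)
  for (idx in split(seq_len(nrow(toks)), toks$record_id)) {
    is_noun <- toks$pos_major[idx] == "noun"
    if (!any(is_noun)) next
    r <- rle(is_noun)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      words <- toks[[col]][idx[starts[j]:ends[j]]]
      runs <- c(runs, paste(words, collapse = " "))
      if (length(words) >= 2) {
        bi_l <- c(bi_l, words[-length(words)])
        bi_r <- c(bi_r, words[-1])
      }
    }
  }
  if (!length(runs)) {
    out <- tibble::tibble(parts = character(), length = integer(),
                          frequency = integer())
  } else {
    tab <- table(runs)
    out <- tibble::tibble(
      parts = names(tab),
      length = lengths(strsplit(names(tab), " ", fixed = TRUE)),
      frequency = as.integer(tab))
  }
  bigrams <- if (length(bi_l)) {
    bt <- table(paste(bi_l, bi_r, sep = "\r"))
    pr <- strsplit(names(bt), "\r", fixed = TRUE)
    tibble::tibble(left = vapply(pr, `[`, "", 1),
                   right = vapply(pr, `[`, "", 2),
                   count = as.integer(bt))
  } else {
    tibble::tibble(left = character(), right = character(),
                   count = integer())
  }
  attr(out, "bigrams") <- bigrams
  out
}

#' Score candidates by log-frequency ratio (FLR)
#'
#' For a candidate \eqn{W = N_1 \dots N_L},
#' \deqn{LR(W) = \Big(\prod_{i=1}^{L} (FL(N_i)+1)(FR(N_i)+1)\Big)^{1/2L}}
#' where \eqn{FL(N)} counts corpus occurrences of noun bigrams with
#' \eqn{N} as the second element (nouns attaching to its left) and
#' \eqn{FR(N)} those with \eqn{N} as the first element; the +1 smoothing
#' gives isolated nouns the floor \eqn{LR = 1}.  The importance score is
#' \eqn{FLR(W) = f(W) \times LR(W)} with \eqn{f} the candidate's corpus
#' frequency.  This is the geometric-mean ("average rate") variant of
#' Nakagawa-style compound-term scoring with bigram-frequency neighbor
#' counts.
#'
#' @param candidates output of [extract_candidates()].
#' @param bigrams noun bigram counts; defaults to the candidates'
#'   `"bigrams"` attribute.
#' @return tibble `parts`, `length`, `frequency`, `lr_score`,
#'   `flr_score`, sorted by decreasing `flr_score`.
#' @export
score_lr <- function(candidates, bigrams = attr(candidates, "bigrams")) {
  stopifnot(!is.null(bigrams))
  nouns <- unique(unlist(strsplit(candidates$parts, " ", fixed = TRUE)))
  fl <- vapply(nouns, function(n) sum(bigrams$count[bigrams$right == n]), 0)
  fr <- vapply(nouns, function(n) sum(bigrams$count[bigrams$left == n]), 0)
  lr <- vapply(strsplit(candidates$parts, " ", fixed = TRUE), function(ws) {
    prod((fl[ws] + 1) * (fr[ws] + 1))^(1 / (2 * length(ws)))
  }, 0)
  out <- candidates
  out$lr_score <- lr
  out$flr_score <- out$frequency * lr
  dplyr::arrange(out, dplyr::desc(.data$flr_score), .data$parts)
}

#' Select the top-percentile compound lexicon
#'
#' The score threshold is the `ceiling(p * n)`-th largest FLR score over
#' *all* candidates (single nouns included); the returned lexicon is the
#' multi-token candidates at or above that threshold, ties included
#' (closed boundary).  Restricting the quantile itself to multi-token
#' candidates is available via `scope = "multi"`.
#'
#' @param scores output of [score_lr()].
#' @param p top fraction selected (default 0.05, i.e. the top 5 percent).
#' @param scope population over which the threshold quantile is taken.
#' @return compound lexicon tibble `parts`, `canonical`, `flr_score`
#'   compatible with [standardization_tables()], sorted by decreasing
#'   score.
#' @export
select_top_percentile <- function(scores, p = 0.05,
                                  scope = c("all", "multi")) {
  scope <- match.arg(scope)
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p >= 1) {
    stop("p must be a single number in (0, 1)", call. = FALSE)
  }
  if (nrow(scores) == 0) stop("no candidates to select from", call. = FALSE)
  pool <- if (scope == "multi") scores$flr_score[scores$length >= 2]
  else scores$flr_score
  if (!length(pool)) stop("no candidates in scoring scope", call. = FALSE)
  k <- ceiling(p * length(pool))
  threshold <- sort(pool, decreasing = TRUE)[k]
  sel <- scores[scores$length >= 2 & scores$flr_score >= threshold, ]
  tibble::tibble(parts = sel$parts, canonical = sel$parts,
                 flr_score = sel$flr_score)
}

#' Write a compound lexicon as compounds.tsv
#'
#' @param lexicon output of [select_top_percentile()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_compound_lexicon <- function(lexicon, path) {
  utils::write.table(lexicon, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
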