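#' 1 - Dice dissimilarity matrix
#'
#' Pairwise dissimilarity between network terms, defined as one minus the
#' Dice coefficient computed on the supplied record set (typically the
#' pooled two-period records restricted to the union of per-period
#' network node sets).
#'
#' @param x a `tn_incidence`.
#' @param terms vocabulary subset to cluster (default: all terms).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
dice_dissimilarity <- function(x, terms = NULL) {
  d <- 1 - dice_matrix(x, terms)
  diag(d) <- 0
  d
}

#' Ward hierarchical clustering on a dissimilarity matrix
#'
#' Agglomerative clustering by Ward's minimum-variance criterion applied
#' directly to the supplied dissimilarities through the Lance-Williams
#' update (no embedding step), i.e. `stats::hclust(method = "ward.D2")`
#' on the condensed matrix.  Merge heights are non-decreasing.
#'
#' @param d symmetric dissimilarity matrix (or [stats::dist] object),
#'   e.g. from [dice_dissimilarity()].
#' @return an [stats::hclust] dendrogram.
#' @export
ward_cluster <- function(d) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (!isSymmetric(unname(d), tol = 1e-8)) {
      stop("dissimilarity matrix must be symmetric", call. = FALSE)
    }
    d <- stats::as.dist(d)
  }
  stats::hclust(d, method = "ward.D2")
}

#' Cut the dendrogram into clusters
#'
#' The cluster count defaults to 10 percent of the clustered terms
#' (half-up rounding, floored at 2); an explicit `k_override` reproduces
#' analyses whose cluster count was fixed after dendrogram inspection.
#'
#' @param dendrogram an [stats::hclust] object.
#' @param fraction cluster count as a fraction of the term count.
#' @param k_override explicit cluster count (takes precedence).
#' @return tibble `term`, `cluster` (ids `1..k`), with attribute `"k"`.
#' @export
cut_clusters <- function(dendrogram, fraction = 0.10, k_override = NULL) {
  n_terms <- length(dendrogram$labels)
  k <- k_override %||% max(2L, as.integer(round_half_up(fraction * n_terms)))
  if (k > n_terms) {
    stop("requested ", k, " clusters from only ", n_terms, " terms",
         call. = FALSE)
  }
  memb <- stats::cutree(dendrogram, k = k)
  out <- tibble::tibble(term = names(memb), cluster = as.integer(memb))
  attr(out, "k") <- as.integer(k)
  out
}

#' Record-level cluster incidence
#'
#' A record "contains" a cluster iff it contains at least one of the
#' cluster's terms (binary, however many member terms appear).
#'
#' @param x a `tn_incidence`.
#' @param assignment tibble `term`, `cluster` from [cut_clusters()] (or
#'   hand-built).
#' @return logical records x clusters matrix (columns named by cluster
#'   id), with the period vector carried as attribute `"period"`.
#' @export
record_cluster_incidence <- function(x, assignment) {
  stopifnot(inherits(x, "tn_incidence"))
  ids <- sort(unique(assignment$cluster))
  cols <- lapply(ids, function(cl) {
    terms <- intersect(assignment$term[assignment$cluster == cl],
                       colnames(x$matrix))
    if (!length(terms)) {
      stop("cluster ", cl, " has no terms in the incidence vocabulary",
           call. = FALSE)
    }
    rowSums(x$matrix[, terms, drop = FALSE]) > 0
  })
  m <- do.call(cbind, cols)
  colnames(m) <- as.character(ids)
  attr(m, "period") <- x$period
  m
}

#' Pre/post contingency tables per cluster
#'
#' For each cluster, the 2x2 table (`a` post records containing the
#' cluster, `b` post without, `c` pre with, `d` pre without) plus the
#' report percentages.
#'
#' @param incidence records x clusters matrix from
#'   [record_cluster_incidence()].
#' @param period period label per record; defaults to the matrix's
#'   `"period"` attribute.
#' @return tibble `cluster`, `a`, `b`, `c`, `d`, `pre_n`, `pre_pct`,
#'   `post_n`, `post_pct`.
#' @export
crosstab <- function(incidence, period = attr(incidence, "period")) {
  stopifnot(!is.null(period), length(period) == nrow(incidence))
  n_pre <- sum(period == "pre")
  n_post <- sum(period == "post")
  if (n_pre == 0 || n_post == 0) {
    stop("both periods must contain records", call. = FALSE)
  }
  res <- lapply(colnames(incidence), function(cl) {
    with_pre <- sum(incidence[period == "pre", cl])
    with_post <- sum(incidence[period == "post", cl])
    tibble::tibble(
      cluster = cl,
      a = as.integer(with_post), b = as.integer(n_post - with_post),
      c = as.integer(with_pre), d = as.integer(n_pre - with_pre),
      pre_n = as.integer(with_pre),
      pre_pct = round_half_up(100 * with_pre / n_pre, 1),
      post_n = as.integer(with_post),
      post_pct = round_half_up(100 * with_post / n_post, 1))
  })
  dplyr::bind_rows(res)
}

#' Odds ratio with confidence interval
#'
#' Point estimate is the sample (cross-product) odds ratio
#' \eqn{ad/(bc)}, oriented post over pre.  The default interval is the
#' Wald interval \eqn{\exp(\ln OR \pm z \sqrt{1/a + 1/b + 1/c + 1/d})};
#' `ci_method = "exact"` gives the conditional exact interval from the
#' noncentral hypergeometric likelihood ([stats::fisher.test]'s
#' interval), which is what many published 2x2 analyses print.  When any
#' cell is zero the Haldane-Anscombe +0.5 correction is applied to all
#' cells (flagged in the result); if both cells of either diagonal are
#' zero the odds ratio is undefined and `NA` is returned.
#'
#' @param a,b,c,d cell counts: post-with, post-without, pre-with,
#'   pre-without.  `a` may also be a length-4 vector or 2x2 matrix
#'   (rows post/pre, columns with/without).
#' @param conf_level confidence level (default 0.95).
#' @param ci_method `"wald"` (default) or `"exact"`.
#' @return list `or`, `ci_low`, `ci_high`, `corrected` (logical: was the
#'   +0.5 correction applied).
#' @export
odds_ratio <- function(a, b = NULL, c = NULL, d = NULL, conf_level = 0.95,
                       ci_method = c("wald", "exact")) {
  ci_method <- match.arg(ci_method)
  if (is.null(b)) {
    v <- as.vector(t(a))
    a <- v[1]; b <- v[2]; c <- v[3]; d <- v[4]
  }
  stopifnot(all(c(a, b, c, d) >= 0))
  if ((a == 0 && d == 0) || (b == 0 && c == 0)) {
    warning("odds ratio undefined: both cells of a diagonal are zero",
            call. = FALSE)
    return(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                corrected = FALSE))
  }
  corrected <- any(c(a, b, c, d) == 0)
  if (ci_method == "exact") {
    ft <- stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
                             conf.level = conf_level)
    or <- (a * d) / (b * c)       # sample OR, not the conditional MLE
    if (corrected) or <- ((a + .5) * (d + .5)) / ((b + .5) * (c + .5))
    return(list(or = or, ci_low = ft$conf.int[1], ci_high = ft$conf.int[2],
                corrected = corrected))
  }
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  or <- (a * d) / (b * c)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or, ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se), corrected = corrected)
}

#' Two-sided Fisher's exact test
#'
#' Exact hypergeometric test of association in a 2x2 table, two-sided by
#' the point-probability rule: the p-value sums the probabilities of all
#' tables with the observed margins whose probability does not exceed
#' that of the observed table.
#'
#' @inheritParams odds_ratio
#' @return the two-sided p-value.
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.null(b)) {
    v <- as.vector(t(a))
    a <- v[1]; b <- v[2]; c <- v[3]; d <- v[4]
  }
  cells <- c(a, b, c, d)
  if (any(cells != round(cells)) || any(cells < 0)) {
    stop("cells must be non-negative integers", call. = FALSE)
  }
  stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
}

#' Per-cluster association statistics
#'
#' Combines the contingency tables with odds ratios, confidence
#' intervals and Fisher exact p-values into one result table.
#'
#' @param tables output of [crosstab()].
#' @param conf_level confidence level.
#' @param ci_method passed to [odds_ratio()].
#' @param names optional named character vector mapping cluster id to a
#'   human-assigned label.
#' @return tibble `cluster`, `name`, counts/percentages, `odds_ratio`,
#'   `ci_low`, `ci_high`, `p_value`.
#' @export
association_results <- function(tables, conf_level = 0.95,
                                ci_method = c("wald", "exact"),
                                names = NULL) {
  ci_method <- match.arg(ci_method)
  rows <- lapply(seq_len(nrow(tables)), function(i) {
    t <- tables[i, ]
    orr <- odds_ratio(t$a, t$b, t$c, t$d, conf_level, ci_method)
    tibble::tibble(
      cluster = t$cluster,
      name = if (!is.null(names)) names[[t$cluster]] %||% t$cluster
      else t$cluster,
      pre_n = t$pre_n, pre_pct = t$pre_pct,
      post_n = t$post_n, post_pct = t$post_pct,
      odds_ratio = orr$or, ci_low = orr$ci_low, ci_high = orr$ci_high,
      corrected = orr$corrected,
      p_value = fisher_exact(t$a, t$b, t$c, t$d))
  })
  dplyr::bind_rows(rows)
}

#' Format the association results for reporting
#'
#' One row per cluster in the conventional layout: `n (%)` per period,
#' `OR (low - high)` at 2 decimals, and the p-value printed as `"< 0.01"`
#' below 0.01.
#'
#' @param results output of [association_results()].
#' @return tibble of formatted character columns `name`, `pre`, `post`,
#'   `or_ci`, `p`.
#' @export
format_results_table <- function(results) {
  fmt2 <- function(v) formatC(round_half_up(v, 2), format = "f", digits = 2)
  tibble::tibble(
    name = results$name,
    pre = fmt_n_pct(results$pre_n, results$pre_pct),
    post = fmt_n_pct(results$post_n, results$post_pct),
    or_ci = ifelse(is.na(results$odds_ratio), "NA",
                   sprintf("%s (%s − %s)", fmt2(results$odds_ratio),
                           fmt2(results$ci_low), fmt2(results$ci_high))),
    p = ifelse(results$p_value < 0.01, "< 0.01",
               fmt2(results$p_value)))
}
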