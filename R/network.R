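#' Build the records-by-terms incidence matrix
#'
#' Binary presence structure: entry `[r, t]` is 1 iff term `t` occurs at
#' least once in record `r` (multiplicity is ignored — all co-occurrence
#' is at the record level).  This is the substrate for every Dice
#' computation downstream.
#'
#' @param x standardized corpus (with a `terms` table), or a terms tibble
#'   (`record_id`, `term`) with `periods` supplied.
#' @param periods named character vector mapping record id to period;
#'   taken from the corpus records when `x` is a corpus.
#' @return an object of class `tn_incidence`: list with `matrix` (logical
#'   records x terms, dimnames set) and `period` (named vector).
#' @export
build_incidence <- function(x, periods = NULL) {
  if (inherits(x, "tn_corpus")) {
    stopifnot(!is.null(x$terms))
    terms <- x$terms
    periods <- stats::setNames(x$records$period, x$records$record_id)
    rec_ids <- x$records$record_id
  } else {
    terms <- tibble::as_tibble(x)
    stopifnot(!is.null(periods))
    rec_ids <- names(periods)
  }
  vocab <- sort(unique(terms$term))
  if (!length(vocab)) stop("empty vocabulary", call. = FALSE)
  m <- matrix(FALSE, length(rec_ids), length(vocab),
              dimnames = list(rec_ids, vocab))
  m[cbind(match(terms$record_id, rec_ids), match(terms$term, vocab))] <- TRUE
  incidence_from_matrix(m, periods[rec_ids])
}

#' Construct an incidence object from a binary matrix
#'
#' Lower-level constructor used when presence/absence is already known
#' (e.g. from the synthetic generator's fast path or from printed
#' marginal counts).
#'
#' @param m logical (or 0/1) matrix, records in rows, terms in columns;
#'   column names are the vocabulary.
#' @param period character vector of period labels, one per row (may be
#'   `NULL` when periods are irrelevant).
#' @return a `tn_incidence` object.
#' @export
incidence_from_matrix <- function(m, period = NULL) {
  m <- m != 0
  if (is.null(colnames(m))) stop("matrix must have term column names",
                                 call. = FALSE)
  if (is.null(rownames(m))) rownames(m) <- paste0("r", seq_len(nrow(m)))
  if (!is.null(period)) {
    stopifnot(length(period) == nrow(m))
    period <- stats::setNames(as.character(period), rownames(m))
  }
  structure(list(matrix = m, period = period), class = "tn_incidence")
}

#' @export
print.tn_incidence <- function(x, ...) {
  cat(sprintf("<tn_incidence> %d records x %d terms\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Restrict an incidence matrix to one period
#'
#' @param x a `tn_incidence`.
#' @param period `"pre"` or `"post"`.
#' @return the row-subset `tn_incidence`.
#' @export
incidence_period <- function(x, period) {
  stopifnot(inherits(x, "tn_incidence"), !is.null(x$period))
  keep <- x$period == period
  incidence_from_matrix(x$matrix[keep, , drop = FALSE], x$period[keep])
}

#' Dice coefficient between two terms
#'
#' \eqn{2|A \cap B| / (|A| + |B|)} over the sets of records containing
#' each term.  For a seed term present in every record this reduces to
#' the closed form \eqn{2 f_b / (n + f_b)}.
#'
#' @param x a `tn_incidence`.
#' @param a,b term names.
#' @return the coefficient in `[0, 1]` (0 with a warning when both terms
#'   are absent from every record).
#' @export
dice <- function(x, a, b) {
  stopifnot(inherits(x, "tn_incidence"))
  miss <- setdiff(c(a, b), colnames(x$matrix))
  if (length(miss)) stop("term(s) not in vocabulary: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  va <- x$matrix[, a]
  vb <- x$matrix[, b]
  denom <- sum(va) + sum(vb)
  if (denom == 0) {
    warning("both terms absent from every record; Dice defined as 0",
            call. = FALSE)
    return(0)
  }
  2 * sum(va & vb) / denom
}

#' All pairwise Dice coefficients
#'
#' @param x a `tn_incidence`.
#' @param terms vocabulary subset (default: all terms).
#' @return symmetric numeric matrix of Dice coefficients (unit diagonal
#'   for terms present somewhere; 0 diagonal for all-absent terms).
#' @export
dice_matrix <- function(x, terms = NULL) {
  stopifnot(inherits(x, "tn_incidence"))
  m <- x$matrix
  if (!is.null(terms)) {
    miss <- setdiff(terms, colnames(m))
    if (length(miss)) stop("term(s) not in vocabulary: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    m <- m[, terms, drop = FALSE]
  }
  cnt <- crossprod(m * 1)               # |A ∩ B|
  f <- diag(cnt)
  denom <- outer(f, f, "+")
  d <- ifelse(denom > 0, 2 * cnt / denom, 0)
  dimnames(d) <- dimnames(cnt)
  d
}

#' Terms strongly co-occurring with the seed
#'
#' The seed-centered first-order view: every term whose Dice coefficient
#' with the seed meets the threshold, with its record frequency, share of
#' records, and coefficient — the report layout used for the per-period
#' co-occurrence tables.
#'
#' @param x a `tn_incidence` (typically one period).
#' @param seed seed term name.
#' @param threshold minimum Dice coefficient (default 0.3).
#' @return tibble `term`, `frequency`, `share_pct` (1 decimal), `dice`
#'   (3 decimals), sorted alphabetically by term.
#' @export
seed_cooccurring_terms <- function(x, seed, threshold = 0.3) {
  stopifnot(inherits(x, "tn_incidence"))
  if (!seed %in% colnames(x$matrix)) {
    stop("seed term '", seed, "' not in vocabulary", call. = FALSE)
  }
  n <- nrow(x$matrix)
  f <- colSums(x$matrix)
  inter <- as.vector(crossprod(x$matrix * 1, x$matrix[, seed] * 1))
  d <- ifelse(f + f[[seed]] > 0, 2 * inter / (f + f[[seed]]), 0)
  keep <- d >= threshold & colnames(x$matrix) != seed
  tibble::tibble(term = colnames(x$matrix)[keep],
                 frequency = as.integer(unname(f[keep])),
                 share_pct = unname(round_half_up(100 * f[keep] / n, 1)),
                 dice = unname(round_half_up(d[keep], 3))) |>
    dplyr::arrange(.data$term)
}

#' Build the seed-centered co-occurrence network
#'
#' Edges are all term pairs with Dice coefficient at or above the
#' threshold; the node set is the connected component containing the seed
#' (so terms linked to the seed only through intermediaries are
#' included).  Node attribute `frequency` is the record frequency; edge
#' attribute `dice` the coefficient; graph attributes record the seed and
#' threshold.
#'
#' @param x a `tn_incidence`.
#' @param seed seed term name.
#' @param threshold minimum Dice coefficient for an edge (default 0.3).
#' @return an [igraph::igraph] graph.
#' @export
build_network <- function(x, seed, threshold = 0.3) {
  stopifnot(inherits(x, "tn_incidence"))
  if (!seed %in% colnames(x$matrix)) {
    stop("seed term '", seed, "' not in vocabulary", call. = FALSE)
  }
  d <- dice_matrix(x)
  diag(d) <- 0
  idx <- which(d >= threshold & upper.tri(d), arr.ind = TRUE)
  f <- colSums(x$matrix)
  if (nrow(idx) == 0) {
    warning("seed term is isolated at threshold ", threshold, call. = FALSE)
    g <- igraph::make_empty_graph(directed = FALSE) +
      igraph::vertices(seed, frequency = as.integer(f[[seed]]))
  } else {
    edges <- tibble::tibble(from = rownames(d)[idx[, 1]],
                            to = colnames(d)[idx[, 2]],
                            dice = d[idx])
    verts <- tibble::tibble(name = unique(c(seed, edges$from, edges$to)))
    verts$frequency <- as.integer(f[verts$name])
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = verts)
    comp <- igraph::components(g)
    keep <- comp$membership == comp$membership[[seed]]
    g <- igraph::induced_subgraph(g, which(keep))
    if (igraph::vcount(g) == 1) {
      warning("seed term is isolated at threshold ", threshold,
              call. = FALSE)
    }
  }
  g <- igraph::set_graph_attr(g, "seed", seed)
  igraph::set_graph_attr(g, "threshold", threshold)
}

#' Maximum-weight spanning tree of a co-occurrence network
#'
#' Kruskal's algorithm on edges sorted by decreasing Dice coefficient,
#' with deterministic lexicographic tie-breaking on the (sorted) edge
#' endpoint names.  Equivalent to the minimum spanning tree under the
#' 1 - Dice distance; used to declutter network depictions while keeping
#' the strongest co-occurrence backbone.
#'
#' @param g connected igraph network with edge attribute `dice`.
#' @return the spanning-tree subgraph (`|V| - 1` edges).
#' @export
max_spanning_tree <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::vcount(g) > 1 && !igraph::is_connected(g)) {
    stop("network must be connected", call. = FALSE)
  }
  if (igraph::ecount(g) == 0) return(g)
  el <- igraph::as_data_frame(g, what = "edges")
  a <- pmin(el$from, el$to)
  b <- pmax(el$from, el$to)
  ord <- order(-el$dice, a, b)
  parent <- stats::setNames(seq_len(igraph::vcount(g)),
                            igraph::V(g)$name)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  keep <- logical(nrow(el))
  for (e in ord) {
    ra <- find(match(el$from[e], names(parent)))
    rb <- find(match(el$to[e], names(parent)))
    if (ra != rb) {
      parent[ra] <- rb
      keep[e] <- TRUE
    }
  }
  igraph::subgraph_from_edges(g, which(keep), delete.vertices = FALSE)
}

#' Louvain community detection on the Dice-weighted network
#'
#' Greedy modularity optimization (resolution 1) on the Dice edge
#' weights, made deterministic by seeding the random number generator
#' that drives node visiting order.  An edgeless network yields the
#' all-singletons partition with modularity 0.
#'
#' @param g igraph network with edge attribute `dice`.
#' @param random_seed integer seed for reproducibility.
#' @return an object of class `tn_partition`: list with `membership`
#'   (named integer vector) and `modularity`.
#' @export
detect_communities <- function(g, random_seed = 1L) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::ecount(g) == 0) {
    memb <- stats::setNames(seq_len(igraph::vcount(g)), igraph::V(g)$name)
    return(structure(list(membership = memb, modularity = 0),
                     class = "tn_partition"))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(random_seed)
  cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$dice)
  memb <- igraph::membership(cl)
  structure(list(
    membership = stats::setNames(as.integer(memb), names(memb)),
    modularity = igraph::modularity(g, memb, weights = igraph::E(g)$dice)),
    class = "tn_partition")
}

#' @export
print.tn_partition <- function(x, ...) {
  cat(sprintf("<tn_partition> %d communities over %d terms, modularity %.4f\n",
              length(unique(x$membership)), length(x$membership),
              x$modularity))
  invisible(x)
}

#' Export a network to GraphML
#'
#' Writes node attributes `frequency` and (when a partition is given)
#' `community`, and the `dice` edge attribute; the file re-imports
#' losslessly with [import_graphml()] and opens in standard graph
#' viewers.
#'
#' @param g igraph network.
#' @param path output file.
#' @param partition optional [detect_communities()] result.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(g, path, partition = NULL) {
  if (!is.null(partition)) {
    stopifnot(inherits(partition, "tn_partition"))
    g <- igraph::set_vertex_attr(
      g, "community",
      value = as.integer(partition$membership[igraph::V(g)$name]))
  }
  ok <- try(igraph::write_graph(g, path, format = "graphml"), silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop("failed to write GraphML to ", path, ": ",
         attr(ok, "condition")$message, call. = FALSE)
  }
  invisible(path)
}

#' Import a GraphML network
#'
#' @param path GraphML file.
#' @return igraph graph.
#' @export
import_graphml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  igraph::read_graph(path, format = "graphml")
}
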