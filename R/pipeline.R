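#' Pipeline configuration
#'
#' Collects every tunable stage parameter in one object.  The analysis
#' parameters default to the conventional choices for seed-centered
#' co-occurrence mining: Dice threshold 0.3, top-5% compound selection,
#' clusters at 10% of terms, period cutover 2018-04 and sensitivity
#' window start 2020-04.
#'
#' @param seed_variants surface forms selecting seed records; the first
#'   entry is the canonical seed term the others are standardized to.
#' @param cutoff_month first month of the post period.
#' @param dice_threshold minimum Dice coefficient for network edges.
#' @param top_percentile top FLR score fraction classified as compounds.
#' @param cluster_fraction cluster count as a fraction of clustered
#'   terms.
#' @param k_override explicit cluster count (optional).
#' @param dice_pool record set used for the clustering dissimilarities:
#'   `"pooled"` (both periods), `"pre"`, or `"post"`.
#' @param rng_seed seed for community detection (and any other stage
#'   randomness).
#' @param sensitivity_exclude_from first month excluded by
#'   [run_sensitivity()].
#' @param tables a [standardization_tables()] object; when `NULL` the
#'   compound lexicon discovered by FLR scoring is used alone.
#' @param tokenizer registered tokenizer name (for corpora that arrive
#'   as raw text).
#' @param anonymize_placeholder passed to [anonymize_tokens()].
#' @param cluster_names optional named character vector labelling cluster
#'   ids in reports.
#' @param output_dir directory for artifacts; `NULL` disables writing.
#' @return an object of class `tn_config`.
#' @export
pipeline_config <- function(
    seed_variants = c("antimicrobial", "antibiotic", "antibacterial",
                      "anti-infective"),
    cutoff_month = "2018-04",
    dice_threshold = 0.3,
    top_percentile = 0.05,
    cluster_fraction = 0.10,
    k_override = NULL,
    dice_pool = c("pooled", "pre", "post"),
    rng_seed = 1L,
    sensitivity_exclude_from = "2020-04",
    tables = NULL,
    tokenizer = "annotated",
    anonymize_placeholder = NULL,
    cluster_names = NULL,
    output_dir = NULL) {
  dice_pool <- match.arg(dice_pool)
  stopifnot(dice_threshold > 0, dice_threshold <= 1,
            top_percentile > 0, top_percentile < 1,
            cluster_fraction > 0, cluster_fraction <= 1)
  assert_month(cutoff_month, "cutoff_month")
  assert_month(sensitivity_exclude_from, "sensitivity_exclude_from")
  structure(list(
    seed_variants = seed_variants, cutoff_month = cutoff_month,
    dice_threshold = dice_threshold, top_percentile = top_percentile,
    cluster_fraction = cluster_fraction, k_override = k_override,
    dice_pool = dice_pool, rng_seed = as.integer(rng_seed),
    sensitivity_exclude_from = sensitivity_exclude_from,
    tables = tables, tokenizer = tokenizer,
    anonymize_placeholder = anonymize_placeholder,
    cluster_names = cluster_names, output_dir = output_dir),
    class = "tn_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of [pipeline_config()] may appear as top-level keys;
#' `synonyms`, `exclusions` and `compounds` keys are file paths loaded
#' through [read_standardization_tables()].
#'
#' @param path YAML file.
#' @return a `tn_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  tbl_keys <- c("synonyms", "exclusions", "compounds")
  tables <- NULL
  if (any(tbl_keys %in% names(y))) {
    tables <- read_standardization_tables(y$synonyms, y$exclusions,
                                          y$compounds)
  }
  y <- y[setdiff(names(y), tbl_keys)]
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, c(y, list(tables = tables)))
}

log_stage <- function(fmt, ...) message(sprintf(paste0("[termnet] ", fmt), ...))

#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end: seed-record selection,
#' tokenization (when needed), part-of-speech filtering and
#' anonymization, compound-term discovery and terminology
#' standardization, per-period seed-centered networks with spanning
#' trees and Louvain communities, Ward clustering of the union of
#' per-period network terms on 1 - Dice, and the pre/post
#' cross-tabulation with odds ratios and Fisher exact tests.  Counts are
#' logged at every stage; artifacts (reports, GraphML, cluster lists,
#' JSON results, run manifest) are written when the config names an
#' output directory.
#'
#' @param x a corpus (raw or tokenized).
#' @param config a [pipeline_config()].
#' @return an object of class `tn_result`: list with `summary`,
#'   `compound_lexicon`, `cooccurrence` (per-period seed tables),
#'   `networks`, `spanning_trees`, `communities` (per period),
#'   `union_terms`, `dendrogram`, `assignment`, `crosstab`, `results`,
#'   `results_formatted`, `config`, and `artifacts` (paths written).
#' @export
run_pipeline <- function(x, config = pipeline_config()) {
  stopifnot(inherits(x, "tn_corpus"), inherits(config, "tn_config"))
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  sel <- run_stage("select", select_seed_records(x, config$seed_variants))
  log_stage("selected %d of %d records containing the seed term",
            nrow(sel$records), nrow(x$records))
  if (is.null(sel$tokens)) {
    sel <- run_stage("tokenize", tokenize_corpus(sel, config$tokenizer))
    log_stage("tokenized %d records into %d tokens",
              nrow(sel$records), nrow(sel$tokens))
  }
  pre <- run_stage("preprocess",
                   preprocess_corpus(sel, placeholder =
                                       config$anonymize_placeholder))
  log_stage("part-of-speech filter + anonymization kept %d of %d tokens",
            nrow(pre$tokens), nrow(sel$tokens))

  cands <- run_stage("terms", extract_candidates(pre))
  lex <- if (nrow(cands)) {
    run_stage("terms", select_top_percentile(score_lr(cands),
                                             p = config$top_percentile))
  } else {
    tibble::tibble(parts = character(), canonical = character(),
                   flr_score = numeric())
  }
  log_stage("compound extraction: %d candidates, %d compounds at top %.0f%%",
            nrow(cands), nrow(lex), 100 * config$top_percentile)

  tables <- config$tables %||% standardization_tables()
  if (nrow(lex)) {
    tables$compounds <- dplyr::bind_rows(
      tables$compounds, lex[c("parts", "canonical")]) |>
      dplyr::distinct(.data$parts, .keep_all = TRUE)
  }
  # map every seed variant onto the canonical seed term
  seed <- config$seed_variants[1]
  extra <- setdiff(config$seed_variants, seed)
  if (length(extra)) {
    tables$synonyms <- dplyr::bind_rows(
      tables$synonyms,
      tibble::tibble(term = extra, canonical = seed,
                     vocabulary_id = "seed"))
  }
  std <- run_stage("standardize", standardize_corpus(pre, tables))
  log_stage("standardized into %d analyzed term tokens, %d types",
            nrow(std$terms), dplyr::n_distinct(std$terms$term))

  summary <- summarize_corpus(std)
  inc <- run_stage("incidence", build_incidence(std))

  per_period <- lapply(c(pre = "pre", post = "post"), function(p) {
    ip <- incidence_period(inc, p)
    ip$matrix <- ip$matrix[, colSums(ip$matrix) > 0, drop = FALSE]
    tab <- seed_cooccurring_terms(ip, seed, config$dice_threshold)
    net <- build_network(ip, seed, config$dice_threshold)
    comm <- detect_communities(net, config$rng_seed)
    tree <- if (igraph::vcount(net) > 1) max_spanning_tree(net) else net
    log_stage("%s period: %d direct co-occurrents, %d network nodes, %d communities",
              p, nrow(tab), igraph::vcount(net),
              length(unique(comm$membership)))
    list(table = tab, network = net, communities = comm, tree = tree)
  })

  union_terms <- sort(unique(c(
    igraph::V(per_period$pre$network)$name,
    igraph::V(per_period$post$network)$name)))
  log_stage("union of per-period network node sets: %d terms",
            length(union_terms))
  pool_inc <- switch(config$dice_pool,
                     pooled = inc,
                     pre = incidence_period(inc, "pre"),
                     post = incidence_period(inc, "post"))
  dend <- run_stage("cluster", {
    d <- dice_dissimilarity(pool_inc, union_terms)
    ward_cluster(d)
  })
  assignment <- cut_clusters(dend, config$cluster_fraction,
                             config$k_override)
  log_stage("Ward clustering of %d terms into %d clusters",
            length(union_terms), attr(assignment, "k"))

  tabs <- run_stage("crosstab", {
    ci <- record_cluster_incidence(inc, assignment)
    crosstab(ci)
  })
  results <- association_results(tabs, names = config$cluster_names)
  formatted <- format_results_table(results)

  out <- structure(list(
    summary = summary, compound_lexicon = lex,
    cooccurrence = lapply(per_period, `[[`, "table"),
    networks = lapply(per_period, `[[`, "network"),
    spanning_trees = lapply(per_period, `[[`, "tree"),
    communities = lapply(per_period, `[[`, "communities"),
    union_terms = union_terms, dendrogram = dend,
    assignment = assignment, crosstab = tabs, results = results,
    results_formatted = formatted, config = config,
    artifacts = character()), class = "tn_result")
  if (!is.null(config$output_dir)) {
    out$artifacts <- write_artifacts(out, config$output_dir)
  }
  out
}

#' @export
print.tn_result <- function(x, ...) {
  cat("<tn_result>\n")
  cat(sprintf("  %d union terms, %d clusters\n",
              length(x$union_terms), attr(x$assignment, "k")))
  print(x$results_formatted)
  invisible(x)
}

write_artifacts <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wtsv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    p
  }
  paths <- c(paths, wtsv(res$summary, "summary.tsv"))
  for (p in c("pre", "post")) {
    paths <- c(paths,
               wtsv(res$cooccurrence[[p]],
                    sprintf("cooccurrence_%s.tsv", p)))
    gp <- file.path(dir, sprintf("network_%s.graphml", p))
    export_graphml(res$networks[[p]], gp, res$communities[[p]])
    paths <- c(paths, gp)
    el <- igraph::as_data_frame(res$networks[[p]], what = "edges")
    names(el) <- c("term_a", "term_b", "dice")
    ep <- file.path(dir, sprintf("edges_%s.csv", p))
    utils::write.csv(el, ep, row.names = FALSE)
    paths <- c(paths, ep)
  }
  paths <- c(paths, wtsv(res$compound_lexicon, "compounds.tsv"),
             wtsv(res$assignment, "clusters.tsv"),
             wtsv(res$results_formatted, "results_table.tsv"))
  jp <- file.path(dir, "results.json")
  jsonlite::write_json(
    list(crosstab = res$crosstab, results = res$results),
    jp, dataframe = "rows", digits = NA)
  paths <- c(paths, jp)
  mp <- file.path(dir, "run_manifest.json")
  cfg <- res$config
  cfg$tables <- NULL
  jsonlite::write_json(list(
    config = cfg[!vapply(cfg, is.null, TRUE)],
    artifacts = lapply(stats::setNames(paths, basename(paths)),
                       function(p) unname(tools::md5sum(p)))),
    mp, auto_unbox = TRUE)
  c(paths, mp)
}

#' Sensitivity analysis on a truncated post period
#'
#' Re-runs the full pipeline after dropping records dated
#' `sensitivity_exclude_from` or later, comparing the pre period with
#' the early post window only (the usual guard against a late-period
#' shock, such as a pandemic, driving the main findings).
#'
#' @param x a corpus.
#' @param config a [pipeline_config()]; artifacts go to an
#'   `output_dir/sensitivity` subdirectory when writing is enabled.
#' @return a `tn_result` whose result table is labelled
#'   "pre vs early-post".
#' @export
run_sensitivity <- function(x, config = pipeline_config()) {
  stopifnot(inherits(x, "tn_corpus"), inherits(config, "tn_config"))
  if (is.null(config$sensitivity_exclude_from)) {
    stop("sensitivity_exclude_from is not configured", call. = FALSE)
  }
  filt <- filter_by_month(x, config$sensitivity_exclude_from)
  n_per <- table(factor(filt$records$period, c("pre", "post")))
  if (any(n_per == 0)) {
    stop("month filter left a period empty (exclude_from = ",
         config$sensitivity_exclude_from, ")", call. = FALSE)
  }
  log_stage("sensitivity window: pre vs early-post (n = %d / %d), excluding %s onward",
            n_per[["pre"]], n_per[["post"]], config$sensitivity_exclude_from)
  if (!is.null(config$output_dir)) {
    config$output_dir <- file.path(config$output_dir, "sensitivity")
  }
  res <- run_pipeline(filt, config)
  attr(res$results_formatted, "comparison") <- "pre vs early-post"
  res
}
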