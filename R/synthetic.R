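#' Configuration for the synthetic two-period corpus generator
#'
#' The generator emulates the structure of a seed-selected clinical-note
#' corpus: every record contains the seed term; topical terms arrive in
#' co-activating planted clusters whose prevalence shifts between the two
#' periods by configurable odds ratios; everything else is noise and
#' padding.  Defaults mirror the study conditions the pipeline targets —
#' 1,353 pre- and 5,155 post-period records spanning April 2014 to March
#' 2022 with the cutover in April 2018, and record lengths of roughly
#' 55-65 analyzed terms.
#'
#' For each record, cluster `c` activates as Bernoulli(\eqn{\pi_{period}})
#' where \eqn{odds(\pi_{post}) = OR_c \times odds(\pi_{pre})}.  An active
#' cluster always emits its first member (its "head" term, which makes
#' record-level cluster incidence identical to activation when
#' `epsilon = 0`) and each remaining member independently with
#' probability `q`.  Every cluster member additionally appears as
#' background noise with probability `epsilon` regardless of activation.
#'
#' @param clusters list of planted clusters, each a list with `name`,
#'   `members` (character), `pi_pre` (pre-period activation probability)
#'   and `or` (period odds multiplier \eqn{OR_c}).
#' @param seed_term the anchor term emitted in every record.
#' @param q within-cluster activation rate: probability a non-head member
#'   is emitted given the cluster is active.
#' @param epsilon background per-term noise probability.
#' @param n_pre,n_post record counts per period.
#' @param pre_months,post_months inclusive month ranges (`c(from, to)`).
#' @param filler_terms neutral padding nouns sampled per record (token
#'   multiplicity allowed); these model record length, not co-occurrence
#'   structure.
#' @param filler_mu,filler_size negative-binomial mean and size for the
#'   per-record filler token count.
#' @param proper_noun_rate,particle_rate Poisson means for injected
#'   proper-noun identifier tokens and particle tokens per record.
#' @param compound_pairs list of lists with `parts` (character vector of
#'   adjacent noun tokens) and `rate` (per-record injection
#'   probability); injected runs exercise compound extraction/merging.
#' @param rng_seed integer seed; identical config + seed gives a
#'   byte-identical corpus.
#' @return an object of class `tn_genconfig`.
#' @export
generator_config <- function(
    clusters = list(
      list(name = "laboratory_monitoring",
           members = c("crp", "wbc", "laboratory_test", "neutrophil"),
           pi_pre = 0.456, or = 1.58),
      list(name = "infection_assessment",
           members = c("fever", "bacterial_test", "qualitative_test",
                       "ceftriaxone"),
           pi_pre = 0.442, or = 2.09),
      list(name = "patient_education",
           members = c("guidance", "explanation", "med_adherence",
                       "med_taking"),
           pi_pre = 0.437, or = 0.28)),
    seed_term = "antimicrobial",
    q = 0.9, epsilon = 0.02,
    n_pre = 1353L, n_post = 5155L,
    pre_months = c("2014-04", "2018-03"),
    post_months = c("2018-04", "2022-03"),
    filler_terms = paste0("filler", sprintf("%02d", 1:40)),
    filler_mu = 50, filler_size = 8,
    proper_noun_rate = 0.5, particle_rate = 4,
    compound_pairs = list(
      list(parts = c("renal", "function"), rate = 0.15),
      list(parts = c("liver", "enzyme"), rate = 0.10)),
    rng_seed = 1L) {
  stopifnot(length(clusters) >= 1, n_pre >= 1, n_post >= 1,
            q >= 0, q <= 1, epsilon >= 0, epsilon <= 1)
  members <- unlist(lapply(clusters, `[[`, "members"))
  if (anyDuplicated(members)) {
    stop("cluster member lists must be disjoint", call. = FALSE)
  }
  if (seed_term %in% c(members, filler_terms)) {
    stop("seed_term must not appear among cluster members or fillers",
         call. = FALSE)
  }
  for (cl in clusters) {
    stopifnot(length(cl$members) >= 1,
              cl$pi_pre > 0, cl$pi_pre < 1, cl$or > 0)
  }
  structure(list(
    clusters = clusters, seed_term = seed_term, q = q, epsilon = epsilon,
    n_pre = as.integer(n_pre), n_post = as.integer(n_post),
    pre_months = pre_months, post_months = post_months,
    filler_terms = filler_terms, filler_mu = filler_mu,
    filler_size = filler_size, proper_noun_rate = proper_noun_rate,
    particle_rate = particle_rate, compound_pairs = compound_pairs,
    rng_seed = as.integer(rng_seed)), class = "tn_genconfig")
}

odds <- function(p) p / (1 - p)
inv_odds <- function(o) o / (1 + o)

pi_post_of <- function(cl) inv_odds(cl$or * odds(cl$pi_pre))

#' Generate planted term presence (fast path)
#'
#' Draws the record-by-term presence structure — cluster activations,
#' member emissions and background noise — without rendering token
#' streams.  This is the generator's analysis-grade core: the emitted
#' matrix feeds [incidence_from_matrix()] directly, and the manifest
#' records the ground truth (activations, per-cluster contingency cells,
#' realized term frequencies).  Token rendering, fillers and injected
#' noise tokens live in [generate_corpus()].
#'
#' @param config a [generator_config()].
#' @return list: `presence` (logical records x terms matrix; seed column
#'   all ones), `period`, `month`, `activation` (records x clusters),
#'   `manifest` (see details).  The manifest holds `cluster_cells`
#'   (tibble of realized `a`, `b`, `c`, `d` per cluster, counting records
#'   containing >= 1 member term), `term_frequency`, and the planted
#'   parameters (`pi_pre`, `pi_post`, `or`).
#' @export
generate_presence <- function(config) {
  stopifnot(inherits(config, "tn_genconfig"))
  set.seed(config$rng_seed)
  n <- config$n_pre + config$n_post
  period <- rep(c("pre", "post"), c(config$n_pre, config$n_post))
  month <- c(sample(month_seq(config$pre_months[1], config$pre_months[2]),
                    config$n_pre, replace = TRUE),
             sample(month_seq(config$post_months[1], config$post_months[2]),
                    config$n_post, replace = TRUE))
  members <- unlist(lapply(config$clusters, `[[`, "members"))
  vocab <- c(config$seed_term, members)
  presence <- matrix(FALSE, n, length(vocab),
                     dimnames = list(sprintf("r%06d", seq_len(n)), vocab))
  presence[, config$seed_term] <- TRUE
  k <- length(config$clusters)
  activation <- matrix(FALSE, n, k)
  colnames(activation) <- vapply(config$clusters, `[[`, "", "name")
  for (j in seq_len(k)) {
    cl <- config$clusters[[j]]
    pi_vec <- ifelse(period == "post", pi_post_of(cl), cl$pi_pre)
    act <- stats::rbinom(n, 1, pi_vec) == 1
    activation[, j] <- act
    for (m_i in seq_along(cl$members)) {
      m <- cl$members[m_i]
      emit_q <- if (m_i == 1) 1 else config$q   # head term always emitted
      emitted <- act & (stats::rbinom(n, 1, emit_q) == 1)
      noise <- stats::rbinom(n, 1, config$epsilon) == 1
      presence[, m] <- emitted | noise
    }
  }
  cells <- lapply(seq_len(k), function(j) {
    cl <- config$clusters[[j]]
    has <- rowSums(presence[, cl$members, drop = FALSE]) > 0
    tibble::tibble(
      cluster = cl$name,
      a = sum(has & period == "post"), b = sum(!has & period == "post"),
      c = sum(has & period == "pre"), d = sum(!has & period == "pre"),
      pi_pre = cl$pi_pre, pi_post = pi_post_of(cl), or = cl$or)
  })
  manifest <- list(
    cluster_cells = dplyr::bind_rows(cells),
    term_frequency = tibble::tibble(term = vocab,
                                    frequency = as.integer(colSums(presence))),
    n_pre = config$n_pre, n_post = config$n_post,
    rng_seed = config$rng_seed)
  list(presence = presence, period = period, month = month,
       activation = activation, manifest = manifest)
}

#' Generate a synthetic two-period tokenized corpus
#'
#' Renders the presence draw of [generate_presence()] into full records
#' in the annotated token dialect: the seed and every present topical
#' term as general nouns, negative-binomial filler nouns for realistic
#' record length, Poisson-injected proper-noun identifiers (for the
#' anonymization stage) and particles (for the part-of-speech filter),
#' and adjacent-noun compound runs (for compound extraction and
#' merging).  Record text is the space-joined annotated stream, so
#' [tokenize_corpus()] round-trips it.
#'
#' @param config a [generator_config()].
#' @return list: `corpus` (a [corpus()] with tokens attached and totals
#'   set to the per-period record counts) and `manifest` (ground truth;
#'   see [generate_presence()]).
#' @export
generate_corpus <- function(config) {
  gp <- generate_presence(config)
  n <- nrow(gp$presence)
  vocab <- colnames(gp$presence)
  # per-record injected token counts (drawn after the presence pass, in a
  # fixed order, so the whole corpus is reproducible from the one seed)
  n_fill <- stats::rnbinom(n, mu = config$filler_mu,
                           size = config$filler_size)
  n_prop <- stats::rpois(n, config$proper_noun_rate)
  n_part <- stats::rpois(n, config$particle_rate)
  comp_hit <- lapply(config$compound_pairs, function(cp)
    stats::rbinom(n, 1, cp$rate) == 1)
  particles <- c("wa", "ga", "no", "ni", "de")
  prop_names <- c("yamada", "tanaka", "sato", "kyoto", "osaka",
                  "city_hospital")
  prop_minor <- c("proper_noun_person", "proper_noun_person",
                  "proper_noun_person", "proper_noun_location",
                  "proper_noun_location", "proper_noun_org")

  rows <- character(n)
  tok_list <- vector("list", n)
  for (i in seq_len(n)) {
    terms_i <- vocab[gp$presence[i, ]]
    topical <- c(terms_i[1],
                 if (length(terms_i) > 1) sample(terms_i[-1]))
    items <- paste0(topical, "/noun")
    if (n_fill[i] > 0) {
      items <- c(items, paste0(sample(config$filler_terms, n_fill[i],
                                      replace = TRUE), "/noun"))
    }
    for (ci in seq_along(config$compound_pairs)) {
      if (comp_hit[[ci]][i]) {
        items <- c(items, paste0(config$compound_pairs[[ci]]$parts, "/noun"))
      }
    }
    if (n_prop[i] > 0) {
      pick <- sample(length(prop_names), n_prop[i], replace = TRUE)
      items <- c(items, sprintf("%s/noun:%s", prop_names[pick],
                                prop_minor[pick]))
    }
    if (n_part[i] > 0) {
      # interleave particles at random positions
      parts <- paste0(sample(particles, n_part[i], replace = TRUE),
                      "/particle")
      pos <- sample(length(items) + n_part[i], n_part[i])
      merged <- character(length(items) + n_part[i])
      merged[pos] <- parts
      merged[-pos] <- items
      items <- merged
    }
    rows[i] <- paste(items, collapse = " ")
  }
  records <- tibble::tibble(
    record_id = rownames(gp$presence),
    period = gp$period, month = gp$month, text = rows,
    record_type = "ward")
  cp <- corpus(records,
               totals = c(pre = config$n_pre, post = config$n_post))
  cp <- tokenize_corpus(cp, "annotated")
  list(corpus = cp, manifest = gp$manifest)
}

#' Theoretical seed-term Dice coefficient for a generated term
#'
#' For a vocabulary term, the marginal per-record presence probability
#' `p` follows from the generator parameters by inclusion-exclusion
#' (\eqn{p = 1 - (1 - \pi q_t)(1 - \epsilon)} for a cluster member with
#' emission rate \eqn{q_t}; \eqn{p = \epsilon} for a noise-only term),
#' and the expected Dice coefficient with the always-present seed is
#' \eqn{2p/(1 + p)}.
#'
#' @param config a [generator_config()].
#' @param term a cluster member term.
#' @return tibble `period`, `p`, `dice`.
#' @export
expected_dice <- function(config, term) {
  stopifnot(inherits(config, "tn_genconfig"))
  found <- NULL
  for (cl in config$clusters) {
    m_i <- match(term, cl$members)
    if (!is.na(m_i)) {
      found <- list(cl = cl, q_t = if (m_i == 1) 1 else config$q)
      break
    }
  }
  if (is.null(found)) {
    if (term == config$seed_term) {
      return(tibble::tibble(period = c("pre", "post"), p = 1, dice = 1))
    }
    stop("unknown term: ", term, call. = FALSE)
  }
  p_of <- function(pi) 1 - (1 - pi * found$q_t) * (1 - config$epsilon)
  p <- c(pre = p_of(found$cl$pi_pre), post = p_of(pi_post_of(found$cl)))
  tibble::tibble(period = names(p), p = unname(p),
                 dice = unname(2 * p / (1 + p)))
}
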