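# Shared fixture builders: tiny corpora written in the annotated token
# dialect, constructed in code at test time.

fixture_records <- function(texts, months = NULL, period = NULL,
                            ids = NULL) {
  n <- length(texts)
  months <- months %||% rep(c("2016-01", "2019-01"), length.out = n)
  tibble::tibble(
    record_id = ids %||% sprintf("r%02d", seq_len(n)),
    month = months,
    period = period %||% period_from_month(months),
    text = texts,
    record_type = "ward")
}

fixture_corpus <- function(texts, ...) {
  tokenize_corpus(corpus(fixture_records(texts, ...)))
}

# a small two-period corpus with the seed in every record
fixture_seed_corpus <- function() {
  fixture_corpus(c(
    "antimicrobial/noun crp/noun rise/verb no/particle",
    "antimicrobial/noun crp/noun wbc/noun",
    "antimicrobial/noun guidance/noun tanaka/noun:proper_noun_person",
    "antimicrobial/noun wbc/noun crp/noun",
    "antimicrobial/noun guidance/noun explanation/noun",
    "antimicrobial/noun crp/noun"),
    months = c("2015-05", "2016-07", "2017-02", "2018-06", "2019-09",
               "2021-12"))
}

# incidence with known marginals: seed present everywhere, term 'b' in
# f_b records out of n
fixture_seed_incidence <- function(n, freqs, period = NULL) {
  m <- cbind(seed = rep(TRUE, n))
  for (nm in names(freqs)) {
    m <- cbind(m, rep(c(TRUE, FALSE), c(freqs[[nm]], n - freqs[[nm]])))
    colnames(m)[ncol(m)] <- nm
  }
  incidence_from_matrix(m, period)
}

random_tokens <- function(n, seed) {
  set.seed(seed)
  majors <- sample(POS_MAJOR, n, replace = TRUE)
  minors <- ifelse(
    majors == "noun",
    sample(c("general", "suffix", "number", "pronoun", "formal_noun",
             "proper_noun_person", "proper_noun_org",
             "proper_noun_location"), n, replace = TRUE),
    "general")
  tibble::tibble(
    record_id = sample(sprintf("r%d", 1:3), n, replace = TRUE),
    position = seq_len(n),
    surface = sprintf("w%02d", sample(30, n, replace = TRUE)),
    base_form = sprintf("w%02d", sample(30, n, replace = TRUE)),
    pos_major = majors, pos_minor = minors)
}
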