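test_that("Ward clustering handles two points and duplicate columns", {
  d <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("a", "b"),
                                                    c("a", "b")))
  h <- ward_cluster(d)
  expect_equal(h$height, 0.4)

  # duplicate term columns merge first at height 0
  inc <- incidence_from_matrix(cbind(
    s = c(T, T, T, T), a = c(T, T, F, F), a2 = c(T, T, F, F),
    b = c(F, F, T, T)))
  h2 <- ward_cluster(dice_dissimilarity(inc, c("a", "a2", "b")))
  expect_equal(h2$height[1], 0)
  first_pair <- -h2$merge[1, ]
  expect_setequal(h2$labels[first_pair], c("a", "a2"))

  bad <- matrix(c(0, 0.2, 0.5, 0), 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(ward_cluster(bad), "symmetric")
})

test_that("Ward merge order and heights match the Lance-Williams oracle", {
  set.seed(17)
  for (rep in 1:8) {
    n <- sample(4:5, 1)
    R <- matrix(runif(n * n, 0.05, 1), n)
    R <- (R + t(R)) / 2
    diag(R) <- 0
    dimnames(R) <- list(letters[1:n], letters[1:n])
    h <- ward_cluster(R)
    expect_equal(canon_merges(hclust_merges(h)),
                 canon_merges(oracle_ward(R)))
    expect_true(all(diff(h$height) >= -1e-12))  # Ward monotonicity
  }
})

test_that("clustering is invariant to term order", {
  set.seed(23)
  n <- 6
  R <- matrix(runif(n * n, 0.05, 1), n)
  R <- (R + t(R)) / 2; diag(R) <- 0
  dimnames(R) <- list(letters[1:n], letters[1:n])
  perm <- sample(n)
  h1 <- cut_clusters(ward_cluster(R), k_override = 3)
  h2 <- cut_clusters(ward_cluster(R[perm, perm]), k_override = 3)
  m1 <- stats::setNames(h1$cluster, h1$term)
  m2 <- stats::setNames(h2$cluster, h2$term)
  # same partition up to label permutation
  expect_equal(length(unique(paste(m1[letters[1:n]], m2[letters[1:n]]))),
               length(unique(m1)))
})

test_that("the cluster-count rule and the dendrogram cut behave", {
  set.seed(3)
  n <- 20
  R <- matrix(runif(n * n, 0.05, 1), n)
  R <- (R + t(R)) / 2; diag(R) <- 0
  dimnames(R) <- list(sprintf("t%02d", 1:n), sprintf("t%02d", 1:n))
  h <- ward_cluster(R)
  cut10 <- cut_clusters(h, fraction = 0.10)
  expect_equal(attr(cut10, "k"), 2L)          # max(2, round(2.0))
  cut7 <- cut_clusters(h, k_override = 7)
  expect_equal(attr(cut7, "k"), 7L)
  expect_equal(dplyr::n_distinct(cut7$cluster), 7)
  # every term assigned exactly once
  expect_setequal(cut7$term, sprintf("t%02d", 1:n))
  expect_equal(nrow(cut7), n)
  expect_error(cut_clusters(h, k_override = 21), "21 clusters")
  # 84 terms with an override of 7 reproduces a 7-group solution
  n2 <- 84
  R2 <- matrix(runif(n2 * n2, 0.05, 1), n2)
  R2 <- (R2 + t(R2)) / 2; diag(R2) <- 0
  dimnames(R2) <- list(sprintf("u%02d", 1:n2), sprintf("u%02d", 1:n2))
  expect_equal(attr(cut_clusters(ward_cluster(R2), k_override = 7), "k"), 7L)
})

test_that("record-level cluster incidence is binary containment", {
  inc <- incidence_from_matrix(rbind(
    r1 = c(a = TRUE, b = TRUE, c = TRUE, z = FALSE),
    r2 = c(a = FALSE, b = FALSE, c = FALSE, z = TRUE),
    r3 = c(a = TRUE, b = FALSE, c = FALSE, z = FALSE),
    r4 = c(a = FALSE, b = FALSE, c = FALSE, z = FALSE)),
    period = c("pre", "pre", "post", "post"))
  assign <- tibble::tibble(term = c("a", "b", "c", "z"),
                           cluster = c(1L, 1L, 1L, 2L))
  ci <- record_cluster_incidence(inc, assign)
  expect_equal(unname(ci[, "1"]), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(unname(ci[, "2"]), c(FALSE, TRUE, FALSE, FALSE))
  expect_error(
    record_cluster_incidence(inc, tibble::tibble(term = "nope",
                                                 cluster = 9L)),
    "no terms")
})

test_that("crosstab cells, percentages and degenerate cases", {
  # planted: post 3 of 4 with, pre 1 of 2 with
  m <- rbind(r1 = c(x = TRUE), r2 = c(x = FALSE), r3 = c(x = TRUE),
             r4 = c(x = TRUE), r5 = c(x = TRUE), r6 = c(x = FALSE))
  inc <- incidence_from_matrix(m, period = c("pre", "pre", rep("post", 4)))
  ci <- record_cluster_incidence(inc, tibble::tibble(term = "x",
                                                     cluster = 1L))
  tab <- crosstab(ci)
  expect_equal(unlist(tab[c("a", "b", "c", "d")]),
               c(a = 3L, b = 1L, c = 1L, d = 1L))
  expect_equal(tab$post_pct, 75)
  expect_equal(tab$pre_pct, 50)

  all_in <- incidence_from_matrix(rbind(r1 = c(x = TRUE), r2 = c(x = TRUE)),
                                  period = c("pre", "post"))
  ci2 <- record_cluster_incidence(all_in,
                                  tibble::tibble(term = "x", cluster = 1L))
  tab2 <- crosstab(ci2)
  expect_equal(tab2$b + tab2$d, 0L)

  one_period <- incidence_from_matrix(rbind(r1 = c(x = TRUE)),
                                      period = "pre")
  ci3 <- record_cluster_incidence(one_period,
                                  tibble::tibble(term = "x", cluster = 1L))
  expect_error(crosstab(ci3), "both periods")
})

test_that("odds ratios, Wald and exact intervals, and corrections", {
  lab <- odds_ratio(2934, 2221, 617, 736)
  expect_equal(round_half_up(lab$or, 2), 1.58)
  expect_true(lab$ci_low <= lab$or && lab$or <= lab$ci_high)

  inf <- odds_ratio(3214, 1941, 598, 755)
  expect_equal(round_half_up(inf$or, 2), 2.09)
  expect_equal(round_half_up(inf$ci_low, 2), 1.85)
  expect_equal(round_half_up(inf$ci_high, 2), 2.36)

  # equal proportions give OR 1
  expect_equal(odds_ratio(10, 10, 5, 5)$or, 1)

  # inversion and scale invariance of the point estimate
  expect_equal(odds_ratio(617, 736, 2934, 2221)$or, 1 / lab$or)
  expect_equal(odds_ratio(20, 10, 6, 12)$or,
               odds_ratio(200, 100, 60, 120)$or)

  # CI width shrinks as all cells grow
  small <- odds_ratio(20, 10, 6, 12)
  big <- odds_ratio(200, 100, 60, 120)
  expect_lt(log(big$ci_high / big$ci_low),
            log(small$ci_high / small$ci_low))

  # Haldane-Anscombe on a zero cell, flagged
  z <- odds_ratio(5, 0, 3, 4)
  expect_true(z$corrected)
  expect_true(is.finite(z$or))
  expect_warning(und <- odds_ratio(0, 5, 3, 0), "undefined")
  expect_true(is.na(und$or))

  # matrix and vector calling conventions agree
  expect_equal(odds_ratio(matrix(c(20, 10, 6, 12), 2, byrow = TRUE))$or,
               odds_ratio(20, 10, 6, 12)$or)

  # exact conditional interval (fisher.test's) differs from Wald and
  # still brackets the estimate
  ex <- odds_ratio(1896, 3259, 746, 607, ci_method = "exact")
  expect_equal(round_half_up(ex$or, 2), 0.47)
  expect_true(ex$ci_low < ex$or && ex$or < ex$ci_high)
})

test_that("Fisher exact equals the enumeration oracle and the frozen examples", {
  expect_equal(fisher_exact(1, 9, 11, 3), 0.002759456, tolerance = 1e-6)
  expect_equal(fisher_exact(1, 1, 1, 1), 1)
  expect_equal(fisher_exact(5068, 87, 1337, 16), 0.22, tolerance = 0.02)
  expect_error(fisher_exact(1.5, 2, 3, 4), "integers")

  set.seed(41)
  for (i in 1:50) {
    cells <- sample(0:12, 4, replace = TRUE)
    if (sum(cells[1:2]) == 0 || sum(cells[3:4]) == 0) next
    expect_equal(fisher_exact(cells[1], cells[2], cells[3], cells[4]),
                 oracle_fisher_p(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-10)
  }
})

test_that("association results table formats the report dialect", {
  tabs <- crosstab(
    structure(cbind(`1` = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE)),
              period = c("pre", "pre", "pre", "post", "post", "post")),
    period = c("pre", "pre", "pre", "post", "post", "post"))
  res <- association_results(tabs, names = c(`1` = "Laboratory Monitoring"))
  fmt <- format_results_table(res)
  expect_equal(fmt$name, "Laboratory Monitoring")
  expect_match(fmt$pre, "^2 \\(66\\.7\\)$")

  # formatting of a published-style results row and the p-value rules
  res2 <- tibble::tibble(
    cluster = "1", name = "Laboratory Monitoring",
    pre_n = 617L, pre_pct = 45.6, post_n = 2934L, post_pct = 56.9,
    odds_ratio = 1.5758, ci_low = 1.3971, ci_high = 1.7773,
    corrected = FALSE, p_value = 1.3e-13)
  f2 <- format_results_table(res2)
  expect_equal(f2$pre, "617 (45.6)")
  expect_equal(f2$post, "2,934 (56.9)")
  expect_match(f2$or_ci, "^1\\.58 \\(1\\.40 − 1\\.78\\)$")
  expect_equal(f2$p, "< 0.01")
  res2$p_value <- 0.22
  expect_equal(format_results_table(res2)$p, "0.22")
  res2$p_value <- 0.004
  expect_equal(format_results_table(res2)$p, "< 0.01")
})
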