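test_that("incidence binarizes multiplicity and tallies record frequencies", {
  cp <- fixture_corpus(c("s/noun a/noun a/noun a/noun", "s/noun b/noun"))
  cp$terms <- dplyr::transmute(cp$tokens, record_id = .data$record_id,
                               position = .data$position,
                               term = .data$base_form)
  inc <- build_incidence(cp)
  expect_equal(unname(inc$matrix["r01", "a"]), TRUE)
  expect_equal(sort(colnames(inc$matrix)), c("a", "b", "s"))
  expect_equal(unname(colSums(inc$matrix)[c("a", "b", "s")]), c(1, 1, 2))

  hand <- matrix(c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE), 2,
                 dimnames = list(c("r01", "r02"), c("a", "b", "s")))
  expect_equal(inc$matrix[, colnames(hand)], hand)

  # column sum equals record frequency by construction
  m10 <- fixture_seed_incidence(10, c(t = 4))
  expect_equal(sum(m10$matrix[, "t"]), 4)
  cp_empty <- cp
  cp_empty$terms <- cp$terms[0, ]
  expect_error(build_incidence(cp_empty), "empty vocabulary")
})

test_that("Dice identities, symmetry, range and monotonicity hold", {
  inc <- fixture_seed_incidence(8, c(a = 4, b = 2))
  expect_equal(dice(inc, "a", "a"), 1)
  expect_equal(dice(inc, "a", "b"), dice(inc, "b", "a"))
  disjoint <- incidence_from_matrix(
    cbind(a = c(TRUE, FALSE), b = c(FALSE, TRUE)))
  expect_equal(dice(disjoint, "a", "b"), 0)
  none <- incidence_from_matrix(cbind(a = FALSE, b = FALSE))
  expect_warning(d0 <- dice(none, "a", "b"), "defined as 0")
  expect_equal(d0, 0)

  set.seed(5)
  for (i in 1:10) {
    m <- matrix(runif(60) < 0.5, 10, dimnames = list(NULL, letters[1:6]))
    inc <- incidence_from_matrix(m)
    dm <- dice_matrix(inc)
    expect_true(all(dm >= 0 & dm <= 1))
    expect_equal(dm, t(dm))
    # brute-force pairwise check
    for (pair in list(c("a", "b"), c("c", "f"))) {
      A <- which(m[, pair[1]]); B <- which(m[, pair[2]])
      expected <- if (length(A) + length(B) == 0) 0 else
        2 * length(intersect(A, B)) / (length(A) + length(B))
      expect_equal(dm[pair[1], pair[2]], expected)
    }
  }
})

test_that("seed Dice reduces to 2f/(n+f) on seed-selected corpora", {
  set.seed(9)
  n <- 200
  freqs <- c(t1 = 150, t2 = 90, t3 = 31, t4 = 7)
  inc <- fixture_seed_incidence(n, freqs)
  tab <- seed_cooccurring_terms(inc, "seed", threshold = 0)
  closed <- round_half_up(2 * freqs / (n + freqs), 3)
  expect_equal(tab$dice, unname(closed[tab$term]))
  expect_equal(tab$term, sort(tab$term))

  # threshold algebra: minimum admissible frequency f >= theta*n/(2-theta)
  theta <- 0.3
  fmin <- ceiling(theta * n / (2 - theta))
  inc2 <- fixture_seed_incidence(n, c(lo = fmin - 1L, hi = fmin))
  tab2 <- seed_cooccurring_terms(inc2, "seed", threshold = theta)
  expect_equal(tab2$term, "hi")
  expect_equal(ceiling(0.3 * 1353 / 1.7), 239)
})

test_that("network keeps the seed's component at the threshold", {
  # chain: seed-A strong, A-B strong, B touches seed not at all, C weak
  m <- cbind(
    seed = c(T, T, T, T, T, F, F, F, F, F),
    A    = c(T, T, F, F, F, T, T, T, F, F),
    B    = c(F, F, F, F, F, T, T, T, F, F),
    C    = c(F, F, F, F, F, F, F, F, T, F))
  inc <- incidence_from_matrix(m)
  d <- dice_matrix(inc)
  expect_gte(d["seed", "A"], 0.3)   # 0.4
  expect_gte(d["A", "B"], 0.3)      # 0.75: B reaches the seed via A only
  expect_lt(d["seed", "B"], 0.3)
  expect_lt(d["B", "C"], 0.3)
  g <- build_network(inc, "seed", threshold = 0.3)
  expect_setequal(igraph::V(g)$name, c("seed", "A", "B"))
  expect_equal(igraph::ecount(g), 2)

  expect_warning(g1 <- build_network(inc, "seed", threshold = 1),
                 "isolated")
  expect_equal(igraph::V(g1)$name, "seed")
  expect_equal(unname(igraph::V(g)$frequency[igraph::V(g)$name == "seed"]),
               5L)
})

test_that("network node set equals brute-force component computation", {
  set.seed(21)
  for (rep in 1:5) {
    m <- matrix(runif(200) < 0.35, 20,
                dimnames = list(NULL, c("seed", letters[1:9])))
    m[, "seed"] <- TRUE
    inc <- incidence_from_matrix(m)
    theta <- 0.45
    g <- build_network(inc, "seed", theta)
    # oracle: BFS over the thresholded dice graph
    d <- dice_matrix(inc); diag(d) <- 0
    adj <- d >= theta
    reach <- "seed"; frontier <- "seed"
    while (length(frontier)) {
      nxt <- setdiff(colnames(adj)[colSums(adj[frontier, , drop = FALSE]) > 0],
                     reach)
      reach <- c(reach, nxt); frontier <- nxt
    }
    expect_setequal(igraph::V(g)$name, reach)
  }
})

test_that("maximum spanning tree drops the weakest cycle edge and matches brute force", {
  tri <- igraph::graph_from_data_frame(
    tibble::tibble(from = c("a", "a", "b"), to = c("b", "c", "c"),
                   dice = c(0.9, 0.8, 0.7)), directed = FALSE)
  t1 <- max_spanning_tree(tri)
  el <- igraph::as_data_frame(t1)
  expect_equal(nrow(el), 2)
  expect_false(any(el$dice == 0.7))

  expect_equal(igraph::ecount(max_spanning_tree(t1)), 2)  # tree is fixed point

  set.seed(31)
  for (rep in 1:5) {
    n <- 5
    full <- t(utils::combn(letters[1:n], 2))
    edges <- tibble::tibble(from = full[, 1], to = full[, 2],
                            dice = round(runif(nrow(full)), 3))
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
    tr <- max_spanning_tree(g)
    expect_equal(igraph::ecount(tr), n - 1)
    expect_true(igraph::is_connected(tr))
    expect_equal(sum(igraph::E(tr)$dice),
                 oracle_mst_weight(edges, n))
  }
  disc <- igraph::graph_from_data_frame(
    tibble::tibble(from = "a", to = "b", dice = 0.5), directed = FALSE,
    vertices = c("a", "b", "c"))
  expect_error(max_spanning_tree(disc), "connected")
})

test_that("Louvain matches exhaustive modularity maximization on the two-clique benchmark", {
  blocks <- t(utils::combn(1:4, 2))
  edges <- tibble::tibble(
    from = c(paste0("a", blocks[, 1]), paste0("b", blocks[, 1]), "a1"),
    to = c(paste0("a", blocks[, 2]), paste0("b", blocks[, 2]), "b1"),
    w = c(rep(0.8, 12), 0.3))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::E(g)$dice <- edges$w
  part <- detect_communities(g, random_seed = 4)

  verts <- igraph::V(g)$name
  parts <- all_partitions(length(verts))
  best_q <- -Inf; best_p <- NULL
  for (p in parts) {
    memb <- stats::setNames(p, verts)
    q <- oracle_modularity(edges, memb)
    if (q > best_q) { best_q <- q; best_p <- memb }
  }
  # same partition up to label permutation: the two 4-cliques
  expect_equal(length(unique(part$membership)), length(unique(best_p)))
  expect_equal(unname(part$membership[paste0("a", 1:4)]),
               rep(part$membership[["a1"]], 4))
  expect_equal(unname(part$membership[paste0("b", 1:4)]),
               rep(part$membership[["b1"]], 4))
  expect_false(part$membership[["a1"]] == part$membership[["b1"]])
  expect_equal(part$modularity, best_q, tolerance = 1e-10)
})

test_that("community partitions respect components, beat singletons, survive relabeling", {
  edges <- tibble::tibble(from = c("a", "b", "x"), to = c("b", "c", "y"),
                          dice = c(0.9, 0.8, 0.7))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  part <- detect_communities(g, 1)
  expect_false(part$membership[["a"]] == part$membership[["x"]])
  expect_gte(part$modularity,
             igraph::modularity(g, seq_len(igraph::vcount(g)),
                                weights = igraph::E(g)$dice))
  # determinism under a fixed seed
  expect_identical(detect_communities(g, 7)$membership,
                   detect_communities(g, 7)$membership)
  # edgeless network: singletons, modularity 0
  g0 <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices("s")
  p0 <- detect_communities(g0, 1)
  expect_equal(p0$modularity, 0)
})

test_that("GraphML export round-trips nodes, edges, weights and communities", {
  inc <- fixture_seed_incidence(20, c(a = 15, b = 12, c = 9))
  g <- build_network(inc, "seed", 0.3)
  part <- detect_communities(g, 2)
  path <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(g, path, part)
  g2 <- import_graphml(path)
  expect_equal(igraph::vcount(g2), igraph::vcount(g))
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
  ord <- match(igraph::V(g)$name, igraph::V(g2)$name)
  expect_equal(igraph::V(g2)$frequency[ord], igraph::V(g)$frequency)
  expect_equal(igraph::V(g2)$community[ord],
               unname(part$membership[igraph::V(g)$name]))
  expect_equal(sort(igraph::E(g2)$dice), sort(igraph::E(g)$dice))
  # plain export omits the community attribute
  export_graphml(g, path)
  expect_false("community" %in%
                 igraph::vertex_attr_names(import_graphml(path)))
  # well-formed XML with the GraphML root element
  doc <- xml2::read_xml(path)
  expect_equal(xml2::xml_name(doc), "graphml")
})
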