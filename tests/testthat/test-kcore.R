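test_that("k-core predicate follows the induced-degree definition", {
  k4 <- complete_graph(4)
  expect_true(is_kcore(k4, 1:4, 3))
  expect_false(is_kcore(k4, 1:3, 3))
  expect_true(is_kcore(cycle_graph(6), 1:6, 2))
  expect_false(is_kcore(k4, integer(0), 1))  # empty set is not a k-core
})

test_that("greedy peel returns the maximum k-core and its removal order", {
  # C5 plus a pendant vertex
  g <- kgraph(6, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 1), c(6, 1)))
  res <- maximum_kcore(g, 2)
  expect_equal(res$core, 1:5)
  expect_equal(res$removal_order$vertex, 6L)
  expect_equal(res$removal_order$degree, 1L)

  expect_equal(maximum_kcore(complete_graph(4), 4)$core, integer(0))
  expect_equal(maximum_kcore(two_triangles(), 2)$core, 1:6)  # disconnected

  # core + removed partition the vertex set; core has min induced degree >= k
  set.seed(41)
  for (i in 1:20) {
    g <- bernoulli_graph(12, runif(1, 0.2, 0.6))
    k <- sample(1:3, 1)
    res <- maximum_kcore(g, k)
    expect_setequal(c(res$core, res$removal_order$vertex), 1:12)
    if (length(res$core)) expect_true(is_kcore(g, res$core, k))
    expect_true(all(res$removal_order$degree < k))
  }
})

test_that("peel agrees with igraph coreness and contains every k-core", {
  skip_if_not_installed("igraph")
  set.seed(42)
  for (i in 1:15) {
    g <- bernoulli_graph(12, runif(1, 0.2, 0.7))
    k <- sample(1:4, 1)
    ig <- igraph::graph_from_edgelist(graph_edges(g), directed = FALSE)
    ig <- igraph::add_vertices(ig, max(0, 12 - igraph::vcount(ig)))
    expect_equal(maximum_kcore(g, k)$core,
                 which(igraph::coreness(ig) >= k))
    # union-of-all-k-cores property against the exhaustive oracle
    for (S in subset_oracle(g, k)$cores) {
      expect_true(all(S %in% maximum_kcore(g, k)$core))
    }
  }
})

test_that("minimality predicate matches its definition", {
  k4 <- complete_graph(4)
  expect_true(is_minimal_kcore(k4, c(1, 2, 4), 2))
  expect_false(is_minimal_kcore(k4, 1:4, 2))     # contains triangles
  expect_true(is_minimal_kcore(cycle_graph(6), 1:6, 2))
  expect_false(is_minimal_kcore(path_graph(3), 1:3, 2))  # not even a k-core
})

test_that("Bron-Kerbosch reports exactly the maximal cliques", {
  # K4 minus one edge: two triangles
  g <- kgraph(4, rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4)))
  expect_equal(maximal_cliques(g), list(c(1L, 2L, 3L), c(1L, 2L, 4L)))
  # C5: the five edges
  expect_equal(lengths(maximal_cliques(cycle_graph(5))), rep(2L, 5))
  expect_equal(maximal_cliques(complete_graph(5)), list(1:5))

  # brute-force subset oracle on seeded random graphs
  set.seed(43)
  for (i in 1:8) {
    g <- bernoulli_graph(10, 0.5)
    is_clique <- function(S) all(combn(S, 2, function(e) e[2] %in% g$adj[[e[1]]]))
    subsets <- unlist(lapply(1:10, function(m) combn(10, m, simplify = FALSE)),
                      recursive = FALSE)
    cliques <- Filter(function(S) length(S) == 1 || is_clique(S), subsets)
    keys <- vapply(cliques, paste, character(1), collapse = ",")
    maximal <- Filter(function(S) {
      !any(vapply(setdiff(1:10, S), function(v) {
        paste(sort(c(S, v)), collapse = ",") %in% keys
      }, logical(1)))
    }, cliques)
    expect_setequal(vapply(maximal, paste, character(1), collapse = ","),
                    core_ids(list(cores = maximal_cliques(g))))
  }
})

test_that("Bron-Kerbosch agrees with igraph on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(44)
  for (i in 1:10) {
    g <- bernoulli_graph(13, runif(1, 0.3, 0.7))
    ig <- igraph::graph_from_edgelist(graph_edges(g), directed = FALSE)
    ig <- igraph::add_vertices(ig, max(0, 13 - igraph::vcount(ig)))
    ours <- vapply(maximal_cliques(g), paste, character(1), collapse = ",")
    theirs <- vapply(igraph::max_cliques(ig),
                     function(x) paste(sort(as.integer(x)), collapse = ","),
                     character(1))
    expect_setequal(ours, theirs)
  }
})

test_that("every (k+1)-clique is a minimal k-core", {
  set.seed(45)
  for (i in 1:6) {
    g <- bernoulli_graph(10, 0.6)
    for (clq in maximal_cliques(g)) {
      k <- length(clq) - 1L
      if (k < 1L) next
      expect_true(is_minimal_kcore(g, clq, k))
      if (length(clq) >= 3) {
        for (S in combn(clq, 3, simplify = FALSE)) {
          expect_true(is_minimal_kcore(g, S, 2))
        }
      }
    }
  }
})

test_that("directed filter keeps undirected minimal cores meeting degree mode", {
  # directed 3-cycle: the undirected minimal 1-cores are single edges, and
  # every edge fails one endpoint's directed degree, so the filter is empty
  d <- kdigraph(3, rbind(c(1, 2), c(2, 3), c(3, 1)))
  expect_equal(directed_kcore_filter(d, 1, "in"), list())
  expect_equal(directed_kcore_filter(d, 1, "out"), list())
  # a reciprocal pair passes in both modes
  rec <- kdigraph(2, rbind(c(1, 2), c(2, 1)))
  expect_equal(directed_kcore_filter(rec, 1, "in"), list(1:2))
  expect_equal(directed_kcore_filter(rec, 1, "out"), list(1:2))
  # at k = 2 a directed triangle with all reciprocal arcs keeps the triangle
  tri2 <- kdigraph(3, rbind(c(1, 2), c(2, 1), c(2, 3), c(3, 2),
                            c(3, 1), c(1, 3)))
  expect_equal(directed_kcore_filter(tri2, 2, "in"), list(1:3))
  # star with all arcs pointing at the hub: every undirected minimal 1-core
  # is an edge, and each edge fails one endpoint in either mode
  star <- kdigraph(4, rbind(c(2, 1), c(3, 1), c(4, 1)))
  expect_equal(directed_kcore_filter(star, 1, "out"), list())
  expect_equal(directed_kcore_filter(star, 1, "in"), list())
  # brute-force check of both endpoints per edge on a mixed digraph
  set.seed(46)
  arcs <- cbind(sample(6, 12, TRUE), sample(6, 12, TRUE))
  arcs <- arcs[arcs[, 1] != arcs[, 2], , drop = FALSE]
  d2 <- kdigraph(6, arcs)
  got <- directed_kcore_filter(d2, 1, "out")
  und <- minimal_kcores(underlying_graph(d2), 1)$cores
  want <- Filter(function(S) {
    all(vapply(S, function(v) sum(d2$out_adj[[v]] %in% S), 0L) >= 1L)
  }, und)
  expect_identical(got, want)
})
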