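# Small named graphs used as fixtures throughout the suite.

complete_graph <- function(n) kgraph(n, t(combn(n, 2)))

cycle_graph <- function(n) kgraph(n, cbind(seq_len(n), c(seq_len(n)[-1], 1L)))

path_graph <- function(n) kgraph(n, cbind(seq_len(n - 1L), seq.int(2L, n)))

# Outer 5-cycle, inner pentagram, spokes: 3-regular on 10 vertices.
petersen_graph <- function() {
  kgraph(10, rbind(cbind(1:5, c(2:5, 1)),
                   cbind(6:10, c(8, 9, 10, 6, 7)),
                   cbind(1:5, 6:10)))
}

two_triangles <- function() {
  kgraph(6, rbind(c(1, 2), c(2, 3), c(3, 1), c(4, 5), c(5, 6), c(6, 4)))
}

# Triangle 1-2-3 plus vertex 4 adjacent to 1 and 2.
triangle_plus_pendant2 <- function() {
  kgraph(4, rbind(c(1, 2), c(2, 3), c(3, 1), c(4, 1), c(4, 2)))
}

core_ids <- function(result) {
  vapply(result$cores, paste, character(1), collapse = ",")
}

expect_same_cores <- function(a, b) {
  expect_identical(core_ids(a), core_ids(b))
}

# Edge-set fingerprint for comparing graphs structurally.
edge_key <- function(g) {
  e <- graph_edges(g)
  paste(e[, 1], e[, 2], sep = "-", collapse = ";")
}
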