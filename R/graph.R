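#' Construct an undirected simple graph
#'
#' Graphs model a network of neurons (vertices) and synapses (edges). The
#' representation is a symmetric adjacency list over vertices `1..n`; edges
#' are deduplicated and symmetrised, self-loops are rejected.
#'
#' @param n Number of vertices; the vertex set is `1..n`.
#' @param edges Two-column matrix (or data frame) of vertex id pairs, one
#'   edge per row. `NULL` or zero rows gives an edgeless graph.
#' @return An object of class `kgraph` with fields `n` (vertex count),
#'   `adj` (list of sorted integer neighbour vectors) and `labels`
#'   (original vertex ids, used by [induced_subgraph()]).
#' @examples
#' g <- kgraph(3, rbind(c(1, 2), c(2, 3), c(3, 1)))  # triangle
#' degree(g)
#' @export
kgraph <- function(n, edges = NULL) {
  n <- as.integer(n)
  stopifnot(length(n) == 1L, !is.na(n), n >= 0L)
  if (is.null(edges) || NROW(edges) == 0L) {
    return(new_kgraph(n, rep(list(integer(0)), n)))
  }
  e <- as.matrix(edges)
  if (ncol(e) != 2L) stop("`edges` must have two columns")
  storage.mode(e) <- "integer"
  if (anyNA(e)) stop("`edges` contains non-integer or missing endpoints")
  bad <- which(e[, 1L] < 1L | e[, 1L] > n | e[, 2L] < 1L | e[, 2L] > n)
  if (length(bad)) {
    stop(sprintf("edge (%d, %d) has an endpoint outside 1..%d",
                 e[bad[1L], 1L], e[bad[1L], 2L], n))
  }
  loops <- which(e[, 1L] == e[, 2L])
  if (length(loops)) {
    stop(sprintf("self-loop (%d, %d) is not allowed",
                 e[loops[1L], 1L], e[loops[1L], 2L]))
  }
  u <- pmin(e[, 1L], e[, 2L])
  v <- pmax(e[, 1L], e[, 2L])
  keep <- !duplicated((u - 1) * as.double(n) + v)
  u <- u[keep]; v <- v[keep]
  adj <- unname(split(c(v, u), factor(c(u, v), levels = seq_len(n))))
  adj <- lapply(adj, function(x) sort.int(as.integer(x)))
  new_kgraph(n, adj)
}

new_kgraph <- function(n, adj, labels = seq_len(n)) {
  structure(list(n = n, adj = adj, labels = as.integer(labels)),
            class = "kgraph")
}

#' @export
print.kgraph <- function(x, ...) {
  cat(sprintf("kgraph: %d vertices, %d edges\n", x$n, n_edges(x)))
  invisible(x)
}

#' Graph accessors
#'
#' @param g A `kgraph`.
#' @return `vertices()` the vertex ids `1..n`; `n_vertices()` / `n_edges()`
#'   counts; `graph_edges()` a two-column matrix with each edge once,
#'   smaller endpoint first; `degree()` the integer degree sequence.
#' @name kgraph-accessors
#' @export
vertices <- function(g) seq_len(g$n)

#' @rdname kgraph-accessors
#' @export
n_vertices <- function(g) g$n

#' @rdname kgraph-accessors
#' @export
n_edges <- function(g) sum(lengths(g$adj)) %/% 2L

#' @rdname kgraph-accessors
#' @export
graph_edges <- function(g) {
  u <- rep.int(seq_len(g$n), lengths(g$adj))
  v <- unlist(g$adj, use.names = FALSE)
  keep <- u < v
  cbind(u = u[keep], v = v[keep])
}

#' @rdname kgraph-accessors
#' @export
degree <- function(g) lengths(g$adj)

# Validate a vertex subset against a graph; returns it sorted and unique.
check_vertex_set <- function(g, S) {
  S <- as.integer(S)
  if (anyNA(S) || any(S < 1L) || any(S > g$n)) {
    stop(sprintf("vertex set contains ids outside 1..%d", g$n))
  }
  sort.int(unique(S))
}

check_threshold <- function(k) {
  k <- as.integer(k)
  stopifnot(length(k) == 1L, !is.na(k), k >= 1L)
  k
}

#' Induced subgraph
#'
#' Restricts a graph to a vertex subset, keeping exactly the edges with both
#' endpoints in `S`. As in igraph, the result is renumbered `1..|S|`; the
#' original ids (in ascending order) are kept in the `labels` field.
#'
#' @param g A `kgraph`.
#' @param S Vertex subset.
#' @return A `kgraph` on `length(S)` vertices.
#' @export
induced_subgraph <- function(g, S) {
  S <- check_vertex_set(g, S)
  idx <- integer(g$n)
  idx[S] <- seq_along(S)
  adj <- lapply(g$adj[S], function(nb) idx[nb[idx[nb] > 0L]])
  new_kgraph(length(S), adj, labels = g$labels[S])
}

#' Read and write edge lists
#'
#' Plain-text edge lists: one `u v` pair per whitespace-separated line,
#' 0-based vertex ids, `#` starting a comment line. The writer emits a
#' `# n <N>` header so isolated vertices survive the round trip, and each
#' edge once with the smaller endpoint first. For directed graphs each line
#' is an arc `u -> v`.
#'
#' @param path File path.
#' @param directed Read/write a directed graph ([kdigraph]) instead.
#' @return `read_edge_list()` a `kgraph` (or `kdigraph`);
#'   `write_edge_list()` the path, invisibly.
#' @export
read_edge_list <- function(path, directed = FALSE) {
  lines <- readLines(path)
  n_stated <- 0L
  edges <- matrix(integer(0), 0L, 2L)
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line)) next
    if (startsWith(line, "#")) {
      hdr <- regmatches(line, regexec("^#\\s*n\\s+(\\d+)\\s*$", line))[[1L]]
      if (length(hdr) == 2L) n_stated <- as.integer(hdr[[2L]])
      next
    }
    tok <- strsplit(line, "\\s+")[[1L]]
    if (length(tok) != 2L || anyNA(suppressWarnings(as.integer(tok)))) {
      stop(sprintf("%s: line %d: expected two integer vertex ids, got '%s'",
                   path, i, line))
    }
    uv <- as.integer(tok)
    if (any(uv < 0L)) stop(sprintf("%s: line %d: negative vertex id", path, i))
    if (uv[1L] == uv[2L]) {
      stop(sprintf("%s: line %d: self-loop on vertex %d", path, i, uv[1L]))
    }
    rows[[i]] <- uv + 1L
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows)) edges <- do.call(rbind, rows)
  n <- max(n_stated, if (length(edges)) max(edges) else 0L)
  if (directed) kdigraph(n, edges) else kgraph(n, edges)
}

#' @rdname read_edge_list
#' @param g Graph to write.
#' @export
write_edge_list <- function(g, path) {
  if (inherits(g, "kdigraph")) {
    e <- digraph_arcs(g)
    e <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
  } else {
    e <- graph_edges(g)
    e <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n %d", g$n), con)
  if (nrow(e)) writeLines(sprintf("%d %d", e[, 1L] - 1L, e[, 2L] - 1L), con)
  invisible(path)
}

#' Connectivity
#'
#' @param g A `kgraph`.
#' @return `is_connected()`: `TRUE` iff `g` has at most one connected
#'   component (the empty graph counts as connected);
#'   `count_components()`: the number of connected components.
#' @export
is_connected <- function(g) count_components(g) <= 1L

#' @rdname is_connected
#' @export
count_components <- function(g) {
  comp <- integer(g$n)
  ncomp <- 0L
  for (s in seq_len(g$n)) {
    if (comp[s] > 0L) next
    ncomp <- ncomp + 1L
    queue <- s
    comp[s] <- ncomp
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- g$adj[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- ncomp
      queue <- c(queue, new)
    }
  }
  ncomp
}
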