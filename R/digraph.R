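#' Construct a directed simple graph
#'
#' Arcs `u -> v` model one-way synapses. Self-loops are rejected, parallel
#' arcs are deduplicated; an arc in each direction between the same pair is
#' allowed.
#'
#' @param n Number of vertices; the vertex set is `1..n`.
#' @param edges Two-column matrix of arcs, tail then head.
#' @return An object of class `kdigraph` with fields `n`, `out_adj` and
#'   `in_adj` (lists of sorted successor / predecessor vectors).
#' @export
kdigraph <- function(n, edges = NULL) {
  n <- as.integer(n)
  stopifnot(length(n) == 1L, !is.na(n), n >= 0L)
  out_adj <- in_adj <- rep(list(integer(0)), n)
  if (!is.null(edges) && NROW(edges) > 0L) {
    e <- as.matrix(edges)
    if (ncol(e) != 2L) stop("`edges` must have two columns")
    storage.mode(e) <- "integer"
    if (anyNA(e)) stop("`edges` contains non-integer or missing endpoints")
    if (any(e < 1L | e > n)) stop(sprintf("arc endpoint outside 1..%d", n))
    loops <- which(e[, 1L] == e[, 2L])
    if (length(loops)) {
      stop(sprintf("self-loop (%d, %d) is not allowed",
                   e[loops[1L], 1L], e[loops[1L], 2L]))
    }
    keep <- !duplicated((e[, 1L] - 1) * as.double(n) + e[, 2L])
    u <- e[keep, 1L]; v <- e[keep, 2L]
    out_adj <- unname(split(v, factor(u, levels = seq_len(n))))
    in_adj <- unname(split(u, factor(v, levels = seq_len(n))))
    out_adj <- lapply(out_adj, function(x) sort.int(as.integer(x)))
    in_adj <- lapply(in_adj, function(x) sort.int(as.integer(x)))
  }
  structure(list(n = n, out_adj = out_adj, in_adj = in_adj),
            class = "kdigraph")
}

#' @export
print.kdigraph <- function(x, ...) {
  cat(sprintf("kdigraph: %d vertices, %d arcs\n", x$n,
              sum(lengths(x$out_adj))))
  invisible(x)
}

digraph_arcs <- function(d) {
  u <- rep.int(seq_len(d$n), lengths(d$out_adj))
  v <- unlist(d$out_adj, use.names = FALSE)
  cbind(u = u, v = if (is.null(v)) integer(0) else v)
}

#' Underlying undirected graph of a digraph
#'
#' `u ~ v` iff at least one of the arcs `u -> v`, `v -> u` exists.
#'
#' @param d A `kdigraph`.
#' @return A `kgraph` on the same vertex set.
#' @export
underlying_graph <- function(d) {
  stopifnot(inherits(d, "kdigraph"))
  kgraph(d$n, digraph_arcs(d))
}
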