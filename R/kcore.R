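#' k-core predicates
#'
#' A vertex set `S` induces a k-core when it is nonempty and every member
#' has at least `k` neighbours inside `S` (Seidman's maximality and
#' connectedness requirements are deliberately dropped). A k-core is
#' *minimal* when no proper subset of its vertices induces a k-core;
#' minimality is decided by checking that every single-vertex deletion
#' peels to the empty core, which is equivalent because any proper k-core
#' subset survives the peel of some single deletion.
#'
#' @param g A `kgraph`.
#' @param S Vertex subset.
#' @param k Threshold (positive integer).
#' @return A logical scalar.
#' @export
is_kcore <- function(g, S, k) {
  S <- check_vertex_set(g, S)
  k <- check_threshold(k)
  if (!length(S)) return(FALSE)
  counts <- tabulate(unlist(g$adj[S], use.names = FALSE), nbins = g$n)
  all(counts[S] >= k)
}

#' @rdname is_kcore
#' @export
is_minimal_kcore <- function(g, S, k) {
  S <- check_vertex_set(g, S)
  k <- check_threshold(k)
  if (!is_kcore(g, S, k)) return(FALSE)
  for (v in S) {
    if (length(.cpp_peel(g$adj, setdiff(S, v), k)$core)) return(FALSE)
  }
  TRUE
}

#' Maximum k-core by greedy peeling
#'
#' Repeatedly deletes a vertex of minimum degree while that degree is below
#' `k` (ties broken on the smallest vertex id). The survivors form the
#' unique maximum k-core -- the union of all k-cores of `g` -- which may be
#' empty or disconnected.
#'
#' @inheritParams is_kcore
#' @param S Optional vertex subset to restrict `g` to before peeling
#'   (defaults to all vertices).
#' @return A `kcore_peel`: list with `core` (sorted vertex set, possibly
#'   empty), `removal_order` (data frame with columns `vertex` and `degree`,
#'   the degree at the moment of removal), and `k`.
#' @examples
#' g <- kgraph(6, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 1), c(6, 1)))
#' maximum_kcore(g, 2)$core   # the C5, vertex 6 peeled away
#' @export
maximum_kcore <- function(g, k, S = vertices(g)) {
  k <- check_threshold(k)
  S <- check_vertex_set(g, S)
  res <- .cpp_peel(g$adj, S, k)
  structure(list(core = res$core,
                 removal_order = data.frame(vertex = res$removed,
                                            degree = res$removed_degree),
                 k = k),
            class = "kcore_peel")
}

#' @export
print.kcore_peel <- function(x, ...) {
  cat(sprintf("maximum %d-core: %d vertices (%d peeled)\n",
              x$k, length(x$core), nrow(x$removal_order)))
  if (length(x$core)) cat(" ", paste(x$core, collapse = " "), "\n")
  invisible(x)
}

#' Directed k-core filter
#'
#' Extends the minimal k-core search to directed graphs by the two-stage
#' procedure: enumerate the minimal k-cores of the underlying undirected
#' graph, then keep those whose every vertex has at least `k` in-neighbours
#' (`mode = "in"`) or out-neighbours (`mode = "out"`) inside the set. Note
#' this can miss directed k-cores that are not minimal *undirected*
#' k-cores; completeness is not claimed.
#'
#' @param d A `kdigraph`.
#' @param k Threshold.
#' @param mode Count in-degree or out-degree within the set.
#' @return A list of vertex sets (possibly empty).
#' @export
directed_kcore_filter <- function(d, k, mode = c("in", "out")) {
  stopifnot(inherits(d, "kdigraph"))
  mode <- match.arg(mode)
  k <- check_threshold(k)
  g <- underlying_graph(d)
  res <- minimal_kcores(g, k)
  adj <- if (mode == "in") d$in_adj else d$out_adj
  keep <- vapply(res$cores, function(S) {
    all(vapply(S, function(v) sum(adj[[v]] %in% S), 0L) >= k)
  }, logical(1))
  res$cores[keep]
}
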