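#' Enumerate all minimal k-cores
#'
#' The central operation: lists every minimal k-core of an undirected graph
#' exactly once. The default method is a Bron-Kerbosch-style backtracking
#' search over the sets (kcore, not, candidates): the root is the maximum
#' k-core; each branch deletes one candidate vertex (ascending induced
#' degree, ties on smallest id) and peels the remainder back to a k-core;
#' branches whose peel evicts a member of the not set are pruned because
#' all minimal k-cores below them were reported earlier. A configuration is
#' reported when every single-vertex deletion peels to the empty core,
#' i.e. when it is minimal.
#'
#' Two independent baselines are provided for cross-validation:
#' `subset_oracle()` scans all `2^n` vertex subsets (guarded to `n <= 20`)
#' and `naive_enumerate()` implements the branching baseline that deletes
#' each vertex of the maximum k-core in turn, reports duplicated cores and
#' deduplicates at the end.
#'
#' @param g A `kgraph`.
#' @param k Threshold (positive integer).
#' @param method `"backtrack"` (default), `"oracle"` or `"naive"`.
#' @param max_cores Stop the backtracking search after this many cores
#'   (`Inf` = enumerate all); the result is then marked truncated.
#' @param memoize For `naive_enumerate()`: cache visited vertex-set states
#'   so each state is expanded once. The cache leaves the set of reported
#'   cores unchanged; disable it to observe the baseline's duplicate
#'   reports on small graphs.
#' @return A `kcore_enumeration`: list with `cores` (list of sorted vertex
#'   sets in lexicographic order), `n`, `k`, `method` and `stats`
#'   (`nodes` = extension calls for the backtracking method,
#'   `reports_before_dedup` for the naive method, `truncated` flag).
#' @examples
#' g <- kgraph(5, t(combn(5, 2)))     # K5
#' length(minimal_kcores(g, 2)$cores) # 10 triangles
#' @export
minimal_kcores <- function(g, k,
                           method = c("backtrack", "oracle", "naive"),
                           max_cores = Inf, memoize = TRUE) {
  method <- match.arg(method)
  switch(method,
         backtrack = enumerate_minimal_kcores(g, k, max_cores = max_cores),
         oracle = subset_oracle(g, k),
         naive = naive_enumerate(g, k, memoize = memoize))
}

#' @rdname minimal_kcores
#' @export
enumerate_minimal_kcores <- function(g, k, max_cores = Inf) {
  k <- check_threshold(k)
  mc <- if (is.finite(max_cores)) as.double(max_cores) else -1
  res <- .cpp_enumerate(g$adj, k, mc)
  new_enumeration(canonicalize_sets(res$cores), g, k, "backtrack",
                  stats = list(nodes = res$nodes, truncated = res$truncated))
}

#' @rdname minimal_kcores
#' @export
subset_oracle <- function(g, k) {
  k <- check_threshold(k)
  if (g$n > 20L) {
    stop(sprintf(
      "subset_oracle scans all 2^n subsets and is guarded to n <= 20 (got n = %d)",
      g$n))
  }
  cores <- if (g$n == 0L) list() else .cpp_subset_oracle(g$adj, k)
  new_enumeration(canonicalize_sets(cores), g, k, "oracle",
                  stats = list(subsets_scanned = 2^g$n - 1))
}

#' @rdname minimal_kcores
#' @export
naive_enumerate <- function(g, k, memoize = TRUE) {
  k <- check_threshold(k)
  if (g$n > 64L) stop("naive_enumerate is limited to n <= 64")
  res <- .cpp_naive(g$adj, k, isTRUE(memoize))
  new_enumeration(canonicalize_sets(res$cores), g, k, "naive",
                  stats = list(reports_before_dedup = res$reports,
                               states_visited = res$visits,
                               memoized = isTRUE(memoize)))
}

new_enumeration <- function(cores, g, k, method, stats) {
  structure(list(cores = cores, n = g$n, k = k, method = method,
                 stats = stats),
            class = "kcore_enumeration")
}

#' @export
print.kcore_enumeration <- function(x, max = 10L, ...) {
  cat(sprintf("%d minimal %d-core(s) of a graph on %d vertices [%s]\n",
              length(x$cores), x$k, x$n, x$method))
  for (s in utils::head(x$cores, max)) {
    cat(" ", paste(s, collapse = " "), "\n")
  }
  if (length(x$cores) > max) cat(sprintf("  ... %d more\n", length(x$cores) - max))
  invisible(x)
}
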