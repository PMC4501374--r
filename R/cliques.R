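#' Maximal cliques (Bron-Kerbosch)
#'
#' Backtracking enumeration of all maximal cliques with the classic
#' compsub/candidates/not bookkeeping. Branching is pruned with the
#' disconnection-counter heuristic: the pivot is the vertex of the
#' candidate-or-not pool disconnected from the fewest candidates (ties on
#' smallest id), and only candidates not adjacent to the pivot are
#' extended. Used here to cross-validate the clique / minimal k-core
#' relationship: every clique on `k + 1` vertices is a minimal k-core.
#'
#' @param g A `kgraph`.
#' @return List of vertex sets, each sorted, the list in lexicographic
#'   order; exactly the maximal cliques of `g`, each once.
#' @examples
#' g <- kgraph(4, rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4)))
#' maximal_cliques(g)  # K4 minus one edge: two triangles
#' @export
maximal_cliques <- function(g) {
  res <- list()
  adj <- g$adj
  extend <- function(compsub, candidates, notset) {
    if (!length(candidates) && !length(notset)) {
      res[[length(res) + 1L]] <<- sort.int(compsub)
      return(invisible())
    }
    pool <- c(candidates, notset)
    disconnections <- vapply(pool, function(u) {
      sum(!(candidates %in% c(adj[[u]], u)))
    }, 0L)
    pivot <- pool[order(disconnections, pool)][1L]
    ext <- candidates[!candidates %in% adj[[pivot]]]
    for (s in ext) {
      extend(c(compsub, s),
             intersect(candidates, adj[[s]]),
             intersect(notset, adj[[s]]))
      candidates <- setdiff(candidates, s)
      notset <- c(notset, s)
    }
    invisible()
  }
  extend(integer(0), seq_len(g$n), integer(0))
  canonicalize_sets(res)
}

# Sort a list of integer sets lexicographically (members already sorted).
canonicalize_sets <- function(sets) {
  if (!length(sets)) return(sets)
  keys <- vapply(sets, function(x) paste(sprintf("%09d", x), collapse = ","),
                 character(1))
  sets[order(keys)]
}
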