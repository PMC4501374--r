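#' Random graph generators
#'
#' `bernoulli_graph()` draws an Erdos-Renyi / Bernoulli graph G(n, p): each
#' of the `choose(n, 2)` vertex pairs is an edge independently with
#' probability `p`. `random_regular_graph()` draws a simple d-regular graph
#' by the configuration (pairing) model: `d` stubs per vertex are paired
#' uniformly and the draw is rejected and retried until it contains no
#' self-loop or multi-edge. Both use R's global random number generator, so
#' `set.seed()` makes draws reproducible.
#'
#' @param n Number of vertices.
#' @param p Edge probability in `[0, 1]`.
#' @return A `kgraph`.
#' @examples
#' set.seed(1)
#' g <- bernoulli_graph(10, 0.5)
#' n_edges(g)
#' h <- random_regular_graph(30, 5)
#' all(degree(h) == 5)
#' @export
bernoulli_graph <- function(n, p) {
  n <- as.integer(n)
  stopifnot(length(n) == 1L, n >= 1L)
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("`p` must be a probability in [0, 1]")
  }
  if (n < 2L) return(kgraph(n))
  u <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  v <- sequence((n - 1L):1L, from = 2:n)
  pick <- runif(length(u)) < p
  kgraph(n, cbind(u[pick], v[pick]))
}

#' @rdname bernoulli_graph
#' @param d Degree of every vertex; `n * d` must be even and `d < n`.
#' @param max_tries Rejection cap for the pairing model.
#' @export
random_regular_graph <- function(n, d, max_tries = 100000L) {
  n <- as.integer(n); d <- as.integer(d)
  stopifnot(length(n) == 1L, length(d) == 1L, n >= 1L, d >= 0L)
  if (d >= n) stop("`d` must be smaller than `n`")
  if ((n * d) %% 2L != 0L) stop("`n * d` must be even")
  if (d == 0L) return(kgraph(n))
  stubs <- rep.int(seq_len(n), d)
  for (. in seq_len(max_tries)) {
    s <- sample(stubs)
    u <- s[c(TRUE, FALSE)]
    v <- s[c(FALSE, TRUE)]
    if (any(u == v)) next
    key <- (pmin(u, v) - 1) * as.double(n) + pmax(u, v)
    if (anyDuplicated(key)) next
    return(kgraph(n, cbind(u, v)))
  }
  stop("pairing model failed to produce a simple graph within `max_tries`")
}
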