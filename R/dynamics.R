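#' One step of threshold activation
#'
#' The threshold function f_k maps an active vertex set S to the set of
#' vertices with at least `k` active neighbours:
#' `f_k(S) = { v : |N(v) intersect S| >= k }`. Note that members of `S` are
#' *not* retained by fiat: an active vertex with fewer than `k` active
#' neighbours drops out.
#'
#' @param g A `kgraph`.
#' @param S Active vertex set (subset of `1..n`).
#' @param k Activation threshold (positive integer): the number of active
#'   inputs a neuron needs in order to fire.
#' @return The next active set, a sorted integer vector.
#' @examples
#' g <- kgraph(4, t(combn(4, 2)))          # K4
#' threshold_step(g, c(1, 2), 2)           # -> 3 4
#' @export
threshold_step <- function(g, S, k) {
  S <- check_vertex_set(g, S)
  k <- check_threshold(k)
  if (!length(S)) return(integer(0))
  counts <- tabulate(unlist(g$adj[S], use.names = FALSE), nbins = g$n)
  which(counts >= k)
}

#' Iterate the threshold function
#'
#' Applies [threshold_step()] repeatedly from `S`, recording every state,
#' and stops at the first fixed point, at the empty set, or at the first
#' revisited state (a cycle). Termination is guaranteed by revisit
#' detection; `max_steps` is only a safety valve.
#'
#' @inheritParams threshold_step
#' @param max_steps Hard cap on the number of applications; exceeded only
#'   on pathological inputs and raised as an error.
#' @return A `threshold_trace`: list with `states` (list of vertex sets,
#'   `states[[1]]` = input), `status` (`"fixed_point"`, `"empty"` or
#'   `"cycle"`), `cycle_start` (index of the first occurrence of the
#'   repeated state, `NA` unless a cycle) and `k`.
#' @examples
#' g <- kgraph(4, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))  # C4
#' iterate_threshold(g, c(1, 3), 2)$status                    # "cycle"
#' @export
iterate_threshold <- function(g, S, k, max_steps = Inf) {
  S <- check_vertex_set(g, S)
  k <- check_threshold(k)
  states <- list(S)
  keys <- paste(S, collapse = ",")
  cur <- S
  status <- NULL
  cycle_start <- NA_integer_
  repeat {
    nxt <- threshold_step(g, cur, k)
    states[[length(states) + 1L]] <- nxt
    if (identical(nxt, cur)) {
      status <- if (length(nxt)) "fixed_point" else "empty"
      break
    }
    key <- paste(nxt, collapse = ",")
    hit <- match(key, keys)
    if (!is.na(hit)) {
      status <- "cycle"
      cycle_start <- hit
      break
    }
    keys <- c(keys, key)
    if (length(states) - 1L > max_steps) {
      stop("threshold iteration exceeded `max_steps` without terminating; ",
           "this should be unreachable with revisit detection")
    }
    cur <- nxt
  }
  structure(list(states = states, status = status,
                 cycle_start = cycle_start, k = k),
            class = "threshold_trace")
}

#' @export
print.threshold_trace <- function(x, ...) {
  cat(sprintf("threshold trace (k = %d), %d states, status: %s\n",
              x$k, length(x$states), x$status))
  for (i in seq_along(x$states)) {
    s <- x$states[[i]]
    cat(sprintf("  f^%d: {%s}\n", i - 1L, paste(s, collapse = ", ")))
  }
  if (x$status == "cycle") {
    cat(sprintf("  cycles back to state %d\n", x$cycle_start - 1L))
  }
  invisible(x)
}

#' Closure of a vertex set under threshold activation
#'
#' The closure cl_k(S) is the invariant set reached when the iteration of
#' f_k from `S` stabilises (`f^n = f^(n-1)`). A weak set's trace reaches the
#' empty set, whose closure is empty. A trace that enters a nontrivial cycle
#' has no closure; this raises a condition of class `kassembly_no_closure`
#' carrying the trace.
#'
#' @inheritParams threshold_step
#' @return The fixed-point vertex set (possibly empty).
#' @export
closure <- function(g, S, k) {
  tr <- iterate_threshold(g, S, k)
  if (tr$status == "cycle") {
    stop(errorCondition(
      "closure undefined for this set: the activation trajectory cycles without reaching a fixed point",
      class = c("kassembly_no_closure", "error"),
      trace = tr))
  }
  tr$states[[length(tr$states)]]
}

#' Classify a vertex set under threshold dynamics
#'
#' A set `S` is *invariant* if `f_k(S) = S` (a self-sustaining activation
#' pattern), *persistent* if `S` is contained in `f_k(S)` (activation never
#' loses members), and *weak* if some iterate of f_k maps it to the empty
#' set (activation dies out).
#'
#' @inheritParams threshold_step
#' @return A logical scalar.
#' @export
is_invariant <- function(g, S, k) {
  S <- check_vertex_set(g, S)
  identical(threshold_step(g, S, k), S)
}

#' @rdname is_invariant
#' @export
is_persistent <- function(g, S, k) {
  S <- check_vertex_set(g, S)
  all(S %in% threshold_step(g, S, k))
}

#' @rdname is_invariant
#' @export
is_weak <- function(g, S, k) {
  iterate_threshold(g, S, k)$status == "empty"
}

#' k-Assembly generated by a minimal k-core
#'
#' A k-assembly is the closure of a minimal k-core: the full activation
#' pattern ignited by exciting that minimal substructure. The input is
#' checked with [is_minimal_kcore()]; the result is invariant and contains
#' `M`.
#'
#' @inheritParams threshold_step
#' @param M Vertex set of a minimal k-core of `g`.
#' @return The assembly vertex set.
#' @examples
#' # triangle 1-2-3 plus vertex 4 adjacent to 1 and 2
#' g <- kgraph(4, rbind(c(1, 2), c(2, 3), c(3, 1), c(4, 1), c(4, 2)))
#' k_assembly(g, 1:3, 2)   # -> 1 2 3 4
#' @export
k_assembly <- function(g, M, k) {
  M <- check_vertex_set(g, M)
  if (!is_minimal_kcore(g, M, k)) {
    stop("`M` is not a minimal k-core of `g` at this threshold")
  }
  closure(g, M, k)
}
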