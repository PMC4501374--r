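#' Minimal k-core counts over a random graph ensemble
#'
#' Replicates the simulation design used to characterise how many minimal
#' k-cores random graphs carry: generate `replicates` graphs from a seeded
#' model, enumerate the minimal k-cores of each at every requested
#' threshold, and summarise per threshold. Following the source convention,
#' the mean count is *conditional*: it averages only over the replicates
#' that contained at least one k-core. The same replicate graphs are reused
#' across the thresholds in `k` (a paired design), so k-vs-k comparisons
#' are made on identical graphs.
#'
#' @param model `"bernoulli"` for G(n, p) or `"regular"` for random
#'   d-regular graphs.
#' @param n Number of vertices per graph.
#' @param p Edge probability (Bernoulli model).
#' @param d Vertex degree (regular model).
#' @param k Vector of thresholds.
#' @param replicates Number of graphs to generate (default 100).
#' @param seed Seed for the replicate stream; the global RNG state is
#'   restored afterwards. `NULL` continues the current RNG stream.
#' @param method Enumeration method, see [minimal_kcores()].
#' @return A `kcore_experiment`: list with `summary` (data frame with one
#'   row per threshold: `model`, `n`, `p`, `d`, `k`, `replicates`,
#'   `graphs_with_core`, `conditional_mean_count`, `sd_count`,
#'   `total_cores`) and `counts` (replicates x length(k) matrix of
#'   per-replicate core counts, for variance estimation).
#' @examples
#' ex <- run_experiment("bernoulli", n = 10, p = 1, k = 2, replicates = 3,
#'                      seed = 1)
#' ex$summary$conditional_mean_count  # choose(10, 3) = 120 triangles
#' @export
run_experiment <- function(model = c("bernoulli", "regular"), n,
                           p = NULL, d = NULL, k, replicates = 100L,
                           seed = NULL, method = "backtrack") {
  model <- match.arg(model)
  replicates <- as.integer(replicates)
  stopifnot(replicates >= 1L, length(k) >= 1L, all(k >= 1L))
  if (model == "bernoulli" && is.null(p)) stop("the bernoulli model needs `p`")
  if (model == "regular" && is.null(d)) stop("the regular model needs `d`")
  k <- vapply(k, check_threshold, integer(1))

  counts <- with_seed(seed, {
    m <- matrix(NA_integer_, replicates, length(k))
    for (r in seq_len(replicates)) {
      g <- if (model == "bernoulli") bernoulli_graph(n, p)
           else random_regular_graph(n, d)
      for (j in seq_along(k)) {
        m[r, j] <- length(minimal_kcores(g, k[j], method = method)$cores)
      }
    }
    m
  })

  summarise_k <- function(j) {
    x <- counts[, j]
    pos <- x[x > 0L]
    data.frame(model = model, n = n,
               p = if (is.null(p)) NA_real_ else p,
               d = if (is.null(d)) NA_integer_ else d,
               k = k[j], replicates = replicates,
               graphs_with_core = length(pos),
               conditional_mean_count = if (length(pos)) mean(pos) else NA_real_,
               sd_count = if (length(pos) > 1L) sd(pos) else NA_real_,
               total_cores = sum(x))
  }
  summary <- do.call(rbind, lapply(seq_along(k), summarise_k))
  structure(list(summary = summary, counts = counts,
                 config = list(model = model, n = n, p = p, d = d, k = k,
                               replicates = replicates, seed = seed,
                               method = method)),
            class = "kcore_experiment")
}

#' @export
print.kcore_experiment <- function(x, ...) {
  cat(sprintf("minimal k-core experiment: %s model, %d replicates\n",
              x$config$model, x$config$replicates))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# Run `expr` under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Overlap structure of an enumerated core collection
#'
#' Quantifies how the minimal k-cores of a graph share vertices -- the
#' observation that motivates reading them as building blocks of
#' overlapping memories: some neurons belong to several assemblies.
#'
#' @param result A `kcore_enumeration` for `g`.
#' @param g The `kgraph` the cores were enumerated on.
#' @return A `kcore_overlap`: list with `membership_count` (per vertex, the
#'   number of cores containing it), `shared_fraction` (fraction of the
#'   graph's vertices belonging to two or more cores), and
#'   `pairwise_jaccard` (|A intersect B| / |A union B| over core pairs;
#'   a 0 x 0 matrix when there are no cores).
#' @examples
#' g <- kgraph(4, t(combn(4, 2)))
#' ov <- overlap_stats(minimal_kcores(g, 2), g)
#' ov$shared_fraction  # 1: every vertex of K4 lies in three triangles
#' @export
overlap_stats <- function(result, g) {
  stopifnot(inherits(result, "kcore_enumeration"), inherits(g, "kgraph"),
            result$n == g$n)
  cores <- result$cores
  membership <- tabulate(as.integer(unlist(cores, use.names = FALSE)),
                         nbins = g$n)
  m <- length(cores)
  jac <- matrix(numeric(0), 0L, 0L)
  if (m > 0L) {
    jac <- diag(1, m)
    if (m > 1L) {
      for (i in seq_len(m - 1L)) {
        for (j in seq.int(i + 1L, m)) {
          inter <- length(intersect(cores[[i]], cores[[j]]))
          jac[i, j] <- jac[j, i] <-
            inter / (length(cores[[i]]) + length(cores[[j]]) - inter)
        }
      }
    }
  }
  structure(list(membership_count = membership,
                 shared_fraction = if (g$n) mean(membership >= 2L) else 0,
                 pairwise_jaccard = jac),
            class = "kcore_overlap")
}

#' @export
print.kcore_overlap <- function(x, ...) {
  cat(sprintf("core overlap: %d cores, shared fraction %.3f\n",
              nrow(x$pairwise_jaccard), x$shared_fraction))
  invisible(x)
}

#' Write experiment and overlap summaries as CSV
#'
#' `write_summary_csv()` writes one row per (model, k) with the summary
#' columns of [run_experiment()]; `write_overlap_csv()` one row per vertex
#' with its core membership count. Both are plain `write.csv` files that
#' round-trip through any standard CSV reader, and are byte-identical for
#' identical inputs.
#'
#' @param x A `kcore_experiment` (or its `summary` data frame) /
#'   a `kcore_overlap`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_summary_csv <- function(x, path) {
  df <- if (inherits(x, "kcore_experiment")) x$summary else as.data.frame(x)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_summary_csv
#' @export
write_overlap_csv <- function(x, path) {
  stopifnot(inherits(x, "kcore_overlap"))
  df <- data.frame(vertex = seq_along(x$membership_count),
                   membership_count = x$membership_count,
                   shared = x$membership_count >= 2L)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
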