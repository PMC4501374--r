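# kassembly

Graph-theoretic tools for studying associative memory through
**k-assemblies**: threshold activation dynamics on networks of neurons, and
the enumeration of every *minimal k-core* — the irreducible substructures
whose excitation ignites an entire memory pattern.

## The problem and who it is for

Model a neuronal network as a simple undirected graph $G = (V, E)$ (vertices
= neurons, edges = unit-strength synapses) with a firing threshold
$k$: a neuron becomes active when at least $k$ of its neighbours are
active. One step of activation spread is the threshold function

$$f_k(S) = \{\, v \in V : |N(v) \cap S| \ge k \,\},$$

and iterating $f_k$ to its fixed point gives the *closure*
$\mathrm{cl}_k(S)$ — the full cascade triggered by exciting $S$. A
**k-core** is a vertex set whose members all have at least $k$ neighbours
inside the set (no maximality or connectedness required); it is **minimal**
if no proper subset induces a k-core. A **k-assembly** is the closure of a
minimal k-core: a formalisation of Hebb's cell assembly in which only a
small, irreducible fraction of the group needs external excitation to
recruit the whole.

The package is for computational neuroscientists and network scientists who
want to (a) list *all* minimal k-cores of a graph — an NP-hard enumeration
problem, solved here with a Bron–Kerbosch-style backtracking search that
provably-by-testing reports each core exactly once — and (b) study how
minimal-core counts and overlaps behave over random graph ensembles.

What is inside:

* `threshold_step()`, `iterate_threshold()`, `closure()`, `is_invariant()`,
  `is_persistent()`, `is_weak()`, `k_assembly()` — the activation calculus;
* `maximum_kcore()` (greedy min-degree peel), `is_kcore()`,
  `is_minimal_kcore()`, `maximal_cliques()` (Bron–Kerbosch),
  `directed_kcore_filter()`;
* `minimal_kcores()` — the backtracking enumerator, plus two independent
  baselines (`subset_oracle()`, `naive_enumerate()`) used to
  cross-validate it;
* `bernoulli_graph()`, `random_regular_graph()`, edge-list I/O, and a
  seeded simulation harness `run_experiment()` / `overlap_stats()` with CSV
  output;
* a command-line front end at `inst/exec/kassembly.R` with subcommands
  `dynamics`, `peel`, `enumerate`, `experiment`, `overlap`.

## Worked example

```r
library(kassembly)
set.seed(1)
g <- bernoulli_graph(10, 0.5)
g
#> kgraph: 10 vertices, 21 edges

res <- minimal_kcores(g, 2)
res
#> 23 minimal 2-core(s) of a graph on 10 vertices [backtrack]
#>   1 2 3
#>   1 2 4 6
#>   1 2 5 6
#>   1 2 6 9
#>   ... 19 more
```

This moderately dense 10-vertex graph contains 23 distinct minimal 2-cores
(its chordless cycles: the irreducible sets able to sustain activity at
threshold 2). Exciting any one of them recruits, via the threshold
dynamics, its k-assembly — here the whole graph:

```r
k_assembly(g, res$cores[[1]], 2)
#>  [1]  1  2  3  4  5  6  7  8  9 10

overlap_stats(res, g)
#> core overlap: 23 cores, shared fraction 1.000
```

Every vertex belongs to at least two minimal cores (`shared fraction
1.000`): the substructures overlap heavily, the observation that links
minimal k-cores to associated, partially shared memories.

Ensemble behaviour, with the conditional-mean convention (averaging only
over graphs containing at least one core):

```r
run_experiment("bernoulli", n = 10, p = 0.5, k = c(2, 3),
               replicates = 100, seed = 7)
#> minimal k-core experiment: bernoulli model, 100 replicates
#>      model  n   p  d k replicates graphs_with_core conditional_mean_count  sd_count total_cores
#>  bernoulli 10 0.5 NA 2        100              100               28.71000 10.07777        2871
#>  bernoulli 10 0.5 NA 3        100               98               13.45918 10.22547        1319
```

All 100 graphs carry minimal 2-cores (mean ≈ 28.7 per graph), 98 carry
minimal 3-cores (mean ≈ 13.5): at this small size, minimal 2-cores
outnumber minimal 3-cores — an ordering that reverses on larger dense
graphs, as the test suite verifies.

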