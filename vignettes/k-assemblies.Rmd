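---
title: "Minimal k-cores, threshold dynamics and k-assemblies: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimal k-cores, threshold dynamics and k-assemblies: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kassembly)
```

## The model

A neuronal network is idealised as a simple undirected graph $G = (V, E)$:
vertices are neurons, edges are (unit-strength, symmetric) synapses. A fixed
integer threshold $k \ge 1$ governs excitation: a neuron fires at the next
step when at least $k$ of its neighbours are currently firing. Formally the
threshold function maps an active set $S \subseteq V$ to

$$f_k(S) = \{\, v \in V : |N(v) \cap S| \ge k \,\},$$

where $N(v)$ is the neighbourhood of $v$. Note that membership of $S$ buys
nothing: an active vertex with fewer than $k$ active neighbours drops out at
the next step. `threshold_step()` implements this literally; the tempting
alternative semantics $S \cup f_k(S)$ is deliberately rejected.

Iterating $f_k$ classifies a set by its fate:

* **invariant** — $f_k(S) = S$: a self-sustaining activation pattern;
* **persistent** — $S \subseteq f_k(S)$: activation never loses members,
  and the trajectory climbs monotonically to a fixed point within $|V|$
  steps;
* **weak** — some iterate is empty: the activation dies out.

The **closure** $\mathrm{cl}_k(S)$ is the fixed point reached when the
iteration stabilises. Non-persistent sets can instead enter a nontrivial
cycle (the diagonal pair of a 4-cycle at $k = 2$ oscillates between the two
diagonals forever); the model simply does not define a closure there, so
`closure()` raises a typed condition (`kassembly_no_closure`) carrying the
trace rather than guessing. `iterate_threshold()` always terminates because
revisited states are detected; the `max_steps` cap exists purely as a
safety valve and is loud when hit.

A **k-core** is a vertex set in which every member has at least $k$
neighbours inside the set — maximality and connectedness are *not*
required here, so any min-degree-$\ge k$ induced subgraph qualifies and the
unique maximum k-core may be disconnected. The empty set is excluded by
definition, so "contains a k-core" always means a nonempty one. A k-core is
**minimal** when no proper subset of its vertices induces a k-core; minimal
k-cores are necessarily connected and have at least $k + 1$ vertices. A
**k-assembly** is the closure of a minimal k-core: the full memory pattern
ignited by exciting one of the graph's irreducible excitable substructures.

### A one-sided equivalence

It is sometimes stated that $f_k(S)$ induces a k-core *iff* $S$ is
persistent. Only one direction holds unrestrictedly: if $S$ is nonempty
and persistent then $S \subseteq f_k(S)$ and every image vertex has $\ge k$
neighbours in $S \subseteq f_k(S)$, so the image is a k-core; conversely
every k-core vertex set is persistent. The full biconditional fails: in a
triangle with one active vertex at $k = 1$ the image is an edge — a
1-core — while the input is not persistent, and the empty set is vacuously
persistent with a non-k-core image. The package therefore exposes the
predicates separately and the tests assert exactly the two true
implications, which are the ones the k-assembly construction rests on.

Palm's original notion of a *tight* set (and the cell assembly as the
closure of a tight set) is stated in the source literature in a grammatically
incomplete way that admits several readings of "whose complement is not
weak". We deliberately ship no tightness predicate; `is_persistent()` and
`is_weak()` let users apply whichever reading their application needs.
Minimal k-cores are tight under every reading, which is all the pipeline
here requires.

## Algorithms

### Maximum k-core (greedy peel)

`maximum_kcore()` repeatedly removes a vertex of minimum degree while that
degree is below $k$. The surviving set is the unique maximum k-core — the
union of all k-cores — independent of tie-breaking; we break ties on the
smallest vertex id anyway so the recorded removal order is reproducible.
The peel is the workhorse primitive: minimality testing, candidate
generation and child-state construction in the enumerator are all phrased
as peels of single-vertex deletions.

### Backtracking enumeration of all minimal k-cores

`minimal_kcores()` adapts Bron–Kerbosch-style backtracking from maximal
cliques to minimal k-cores. Each search-tree node holds a peeled k-core
configuration `kcore`, a set `not` of vertices that may no longer be
deleted below this node, and a candidate set. The root is the maximum
k-core of the input graph.

At a node, the peel of every single-vertex deletion
$G[\mathit{kcore} \setminus \{v\}]$ is computed once and reused three ways:

1. **Report test.** If every deletion peels to the empty core, no proper
   subset induces a k-core — the configuration is minimal by definition —
   and it is reported. This single uniform test subsumes both the
   "candidates empty" condition and the not-set condition of the original
   formulation (reading "does not induce a k-core" as "contains no
   k-core", the only reading under which the report condition coincides
   with minimality).
2. **Candidates.** The candidates are the vertices outside `not` whose
   deletion still leaves a nonempty peel. They are processed in ascending
   induced degree (ties on smallest id) — the "smallest degree first"
   selection rule, fixed deterministically.
3. **Children.** The child state for candidate $s$ is the *peeled* maximum
   k-core of $G[\mathit{kcore} \setminus \{s\}]$. A literal deletion need
   not leave a k-core configuration, while the search's invariants
   presuppose one; peeling preserves every minimal k-core avoiding $s$, so
   completeness is unharmed. If the peel evicts a member of `not`, every
   minimal core below that child was already reported in an earlier branch
   and the child is pruned; after a child returns, $s$ joins `not`.

The no-duplication guarantee is tested, not assumed: the suite
cross-validates the enumerator against two independent routes on hundreds
of seeded random instances and on hand fixtures, and checks the structural
invariants of every reported core (minimality, connectedness, size
$\ge k + 1$, containment in the maximum k-core).

The kernels (peel, enumeration, both baselines) are implemented in C++ with
vertex sets as bit masks, as the field's graph libraries do for
exponential-search primitives; induced degrees are popcounts. Recursion
depth is bounded by $|V|$, so plain recursion is safe at the studied
scales, and output is canonicalised afterwards (each core ascending, the
list lexicographic) so reporting order carries no information.
`max_cores` allows truncated exploratory runs; the extension-call counter
is recorded so candidate-selection heuristics can be compared.

### Independent baselines

Two deliberately different routes exist purely as oracles:

* `subset_oracle()` scans all $2^n$ vertex subsets (guarded to
  $n \le 20$), keeps the k-cores, and retains those containing no smaller
  k-core — minimality by exhaustive containment, sharing no logic with the
  backtracking search.
* `naive_enumerate()` implements the branching baseline: peel to the
  maximum k-core, report it if it is minimal, otherwise recurse on every
  single-vertex deletion. Distinct deletion orders reach the same core, so
  the same minimal k-core is reported repeatedly and duplicates are removed
  at the end (on $K_5$ at $k = 2$: 20 reports of 10 distinct triangles).
  By default a visited-state cache prunes re-exploration of an
  already-visited vertex set — without it the tree is factorial in $|V|$ —
  which provably leaves the *set* of reported cores unchanged;
  `memoize = FALSE` restores the raw duplicate behaviour for small graphs.

### Maximal cliques and the directed filter

`maximal_cliques()` is the classic compsub/candidates/not backtracking with
the disconnection-counter pivot (fewest disconnections from the candidate
set, ties on smallest id). It exists for cross-validation — every clique on
$k + 1$ vertices is a minimal k-core — and is itself checked against both a
brute-force subset scan and an independent library implementation in the
test suite.

`directed_kcore_filter()` extends the search to directed graphs by the
two-stage procedure: enumerate minimal k-cores of the underlying undirected
graph, then keep those in which every vertex has $\ge k$ in-neighbours (or
out-neighbours) within the set. This inherits an acknowledged
incompleteness: a directed k-core that is not a minimal *undirected* k-core
is never examined. The filter is exact about what it claims, no more.

## Random graph models

`bernoulli_graph(n, p)` samples each pair independently (edge count is
Binomial over the pairs; the suite checks the law by chi-square).
`random_regular_graph(n, d)` uses the configuration/pairing model with
whole-draw rejection until the pairing is simple. Exact uniformity over
d-regular graphs is not needed for the qualitative ensemble claims studied
here; simplicity, seedability and transparency are, which is why the
textbook rejection sampler was chosen. Draws are not conditioned on
connectivity: a rare disconnected d-regular sample is kept, and at
$k = d$ it contributes one minimal k-core per component, which the
experiment layer makes visible rather than hiding. Both generators use R's
global RNG; `set.seed()` (or the experiment harness's `seed` argument,
which restores the caller's RNG state afterwards) gives bit-for-bit
reproducible graphs.

## The simulation harness

`run_experiment()` reproduces the ensemble design: generate `replicates`
graphs (default 100, the convention of the study design it mirrors),
enumerate minimal k-cores per graph per threshold, and summarise. The mean
count is **conditional**: averaged only over replicates that contained at
least one k-core, with the zero-core replicates reported separately as
`graphs_with_core`. One call reuses the same replicate graphs across all
requested `k` values — a paired design that is statistically valid for the
per-k means and sharpens k-vs-k comparisons (the qualitative reversal
whereby small dense graphs carry more minimal 2-cores than 3-cores while
larger dense graphs reverse the ordering). Per-replicate counts are kept
for variance estimation; `sd_count` is the cross-replicate standard
deviation among core-containing replicates.

Problem sizes in the shipped tests were chosen to make Monte-Carlo
tolerances meaningful while keeping the whole suite comfortably
interactive: 100 replicates at $n \in \{10, 15, 20\}$ for the Bernoulli
ensembles (30 at the densest $n = 20$, $p = 0.7$ corner, whose graphs carry
tens of thousands of minimal cores each), 100 random 5-regular graphs on 30
vertices, and 240 instances for the three-way enumerator cross-validation.
Monte-Carlo agreement is asserted within three cross-replicate standard
errors or 25 % relative error, whichever is looser (four standard errors
for the deliberately scaled-down sparse $n = 20$ spot check).

`overlap_stats()` quantifies the observation that motivates the whole
exercise: minimal k-cores overlap. It reports per-vertex membership counts,
the fraction of vertices lying in two or more cores, and pairwise Jaccard
similarity between cores — on $K_4$ at $k = 2$ every vertex sits in three
of the four triangles, the extreme case of shared substructure.

## What the synthetic ensembles do and do not show

Bernoulli and random regular graphs exercise the algorithms across the
density range where the count reversal happens, and regular graphs pin the
degenerate $k = d$ case (exactly one core per component). Real neuronal
networks are neither independent-edge random nor regular: they are
directed, weighted, locally clustered and heavy-tailed. Passing these
ensembles therefore validates the *combinatorics* — the enumerator, the
dynamics, the aggregation conventions — not any biological claim. The
directed extension is a filter with a documented completeness gap, and
synaptic weights are fixed at one throughout ($k$ counts inputs; a weighted
threshold is out of scope).

## Practical limits

Minimal k-core enumeration is NP-hard (cliques on $k + 1$ vertices are a
special case) and core counts grow rapidly with density: dense 25-vertex
graphs already carry hundreds of thousands of minimal cores. The
backtracking enumerator is practical to a few tens of vertices; the subset
oracle to $n \approx 20$ by construction; `naive_enumerate()` to $n \le 64$
(bit-mask states) and far less without its cache. For larger inputs,
truncation via `max_cores` or pre-partitioning the graph are the realistic
options.
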