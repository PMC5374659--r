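---
title: "Querying interaction networks by random-walk correspondence and conductance minimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Querying interaction networks by random-walk correspondence and conductance minimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netquery)
```

## The problem

Given a small query module — typically a protein complex of 5–25 proteins
from a well-studied species — and a large target protein–protein
interaction (PPI) network from another species, network querying asks for
the target subnetwork that best matches the query. A good match combines
two signals: *node similarity* (sequence-level similarity between
proteins, here consumed as precomputed BLAST-bit-score-like numbers) and
*topological similarity* (conserved interaction patterns). Conserved
modules are rarely exact copies: orthologs may be missing (node
deletions), extra proteins may have joined the module (insertions), and
interactions may differ (rewiring). A third signal, often ignored by
querying methods, is *separability*: functional modules tend to be
densely connected internally and sparsely connected to the rest of the
network, which is exactly what network conductance measures.

`netquery` implements a pipeline built on these three signals:

1. **Reduce** the target to nodes with at least one query homolog
   (similarity strictly above a threshold `T_h`, default 0), and
   **re-connect** components that this filtering disconnected with
   *pseudo-edges* between nodes that share a similar query node.
2. **Estimate node correspondence** with a context-sensitive random walk
   (CSRW) over query–target node pairs.
3. **Normalize** the correspondence matrix and **select seed nodes**.
4. **Grow** the seed network greedily, each step adding the neighboring
   node that minimizes the subnetwork's conductance, subject to a
   minimum-improvement rule and a size cap.
5. **Prune** loosely attached nodes using per-node extension rewards.

## The context-sensitive random walk

The walker occupies a pair $(v_q, v_t)$ of one query and one target node.
At each step it inspects its context: the set
$S = \{(x, y) : x \sim v_q,\; y \sim v_t,\; s(x, y) > 0\}$
of neighbor pairs with positive similarity. If $S$ is non-empty the
walker moves *simultaneously* on both networks, choosing
$(x, y) \in S$ with probability proportional to
$w(v_q, x)\, w(v_t, y)\, s(x, y)$ — edge weights times node similarity,
so the walk follows strong interactions toward similar pairs, and
degrades gracefully to pure topology when similarity is flat. If $S$ is
empty — the signature of an inserted or deleted node — the walker picks
one network uniformly and moves *individually* on it proportionally to
edge weight, keeping the other coordinate fixed; a coordinate with no
neighbors stays in place for that half-step. This mode switching is what
makes the model robust to insertions and deletions: an unmatched node is
crossed by individual moves instead of derailing the joint walk.

The correspondence score $c(v_q, v_t)$ is the long-run rate at which the
walker *arrives at* $(v_q, v_t)$ by a simultaneous move: with stationary
distribution $\pi$ and simultaneous transition block $P_{sim}$, the
score matrix collects $\pi P_{sim}$. Individual moves therefore
contribute probability mass but no correspondence, so
$0 \le \sum_{q,t} c(v_q, v_t) \le 1$, with the sum equal to the overall
fraction of simultaneous moves. Whether "simultaneous visits" should be
counted on arrival or by occupancy is genuinely open; the arrival
convention is used because it makes the score an exact flow through
$P_{sim}$ and reproduces the intuitive answer on symmetric toy chains
(two perfectly matched edges score 0.5 each).

### Numerics

The stationary distribution is computed by power iteration on the lazy
chain $p \leftarrow \alpha p + (1-\alpha)\, p P$ with $\alpha = 0.5$,
which guarantees aperiodicity without changing the fixed point, starting
from the uniform distribution over all positive-similarity pairs, until
the L1 change drops below $10^{-10}$ (at most 10,000 iterations; the
iterate is returned with a warning if that cap is hit). The iteration is
over the distribution, not a sampled walk, so results are fully
deterministic. Only pair states reachable from the positive-similarity
support are enumerated, which keeps the state space far below
$|V_Q| \times |V_T|$ on reduced targets.

The chain has **no teleportation term**. On connected reduced targets
the chain is usually irreducible and the limit is unique; on fragmented
ones the limit depends on the uniform initialization, which is accepted
and documented — the initialization then acts as a prior proportional to
each fragment's share of positive-similarity pairs. The consequences are
measurable and discussed under *Limitations*.

## Normalization and seed selection

Row/column normalization
$\bar{C} = \tfrac12 (J_L C + C J_R)$, with $J_L$ and $J_R$ the diagonal
inverse row and column sums, converts raw visit rates into *relative*
preferences so that networks of very different sizes are comparable; a
zero row or column contributes zero rather than dividing by zero. Each
target node is then scored by
$\sum_{v_q} \log(1 - \bar{c}(v_q, v_t))$ (entries clipped at
$1 - 10^{-12}$), the log of the product $\prod_q (1 - \bar{c})$: a
target node supported by *many* strongly corresponding query nodes
scores lowest and is selected first. The number of seeds defaults to the
query size, so the seed network can never start larger than the query.
Because the score does not change between picks, iterative selection
collapses to a single ranking; ties go to the larger per-column maximum,
then lexicographic node id, making the whole pipeline deterministic.

The seed network is the largest connected component of the target
subgraph induced on the seeds (ties: the component holding the
best-ranked seed, then the lexicographically smallest member; if the
induced subgraph has no edges at all, the single best seed).

## Conductance, extension, pruning

For a subnetwork $H$ with `cut` boundary edges and `internal` inside
edges, the working conductance is $\phi(H) = cut/internal$
(`mode = "module"`), the form valid when the module is much smaller
than the remaining network so that its degree-sum volume is dominated by
internal edges; the textbook
$cut / \min(vol(H), vol(\bar H))$ is exposed as `mode = "standard"` and
both are verified against brute-force edge counting. Edges count
unweighted; $\phi = \infty$ when there is no internal edge, and any
finite conductance is accepted as an improvement over $\infty$.

Extension repeatedly scans all nodes adjacent to the current subnetwork,
computes $\phi$ of each candidate enlargement, and accepts the minimizer
provided it improves the current conductance by at least 5%
(`extend.reduction = 0.05`); it stops when no candidate qualifies or
when the subnetwork would exceed twice the query size
(`extend.cap_factor = 2`, bound inclusive). When node $u$ is accepted,
every existing member adjacent to $u$ earns a +1 extension reward; $u$
itself enters at 0. Rewards thus count, per node, how many *later*
additions attached to it — a proxy for its contribution to module
density. Pruning removes every non-seed node whose reward does not
strictly exceed `prune.threshold = 0`; seeds are always kept because
their correspondence support is independent evidence. The pruned result
may be disconnected; the number of components is reported rather than
enforced, since enforcing connectivity would silently discard
correctly-matched fragments.

Tie-breaking everywhere (candidate choice, component choice) uses the
seed-selection log-score, then lexicographic node id, which together
with the deterministic walk makes identical invocations byte-identical.

## Evaluation metrics

* **Matching score**: Jaccard index between node sets; two complexes
  match at $\ge 0.5$.
* **Information content**: $IC(g) = -\log_2(|g|/|root(g)|)$ for a term
  $g$; only terms with $IC \ge 2$ (annotating at most a quarter of the
  universe) are tested, since ubiquitous terms are uninformative.
* **Enrichment**: one-sided hypergeometric tail $P(X \ge k)$ per term,
  Benjamini–Hochberg corrected across tested terms. This replaces the
  GO::TermFinder dependency with the same statistical structure over a
  user-supplied flat annotation table; no ontology propagation is
  performed, so any evidence-code or aspect filtering must be applied to
  the table beforehand.
* **Hits**: a result is a *hit* if its most-enriched term is significant
  at the FDR threshold (default 0.05), a *functionally coherent (FC)
  hit* if additionally at least 50% of its proteins carry that term
  (that fraction is the SPE); the *significant* variants apply the same
  tests to the query's own most-enriched term.

## The synthetic benchmark

`generate_pair()` emulates the conserved-module setting with known
ground truth: a connected query module (Erdős–Rényi with mean degree 3,
resampled until connected) is copied into a sparse background network
(Erdős–Rényi with mean degree 4 by default, matching the sparsity of
real PPI networks; preferential attachment available for
degree-heterogeneity studies), with each copied node deleted with
probability `p_node_delete`, `ceiling(p_node_insert * query_size)` extra
nodes inserted and wired to two surviving module nodes, and each copied
edge rewired with probability `p_edge_rewire`. The implant is attached
to the background by `max(1, 0.1 * implant size)` bridge edges.
Similarity mimics BLAST bit scores without modeling sequences: surviving
homolog pairs draw from a positive-truncated normal (mean 50, sd 10),
and each non-homolog pair receives a spurious positive score (mean
`50/4`, sd 10) with probability `spurious_pair_rate`. Only relative
score magnitudes matter to the walk, so the absolute scale is
inconsequential. All sampling derives from a single `rng_seed`, and the
generator restores the caller's RNG state.

What the generator does **not** emulate: hub-dominated degree
distributions (under the default background), correlated false-negative
interactions, paralog families (several target nodes highly similar to
the same query protein for genuine biological reasons), and
evidence-weighted interaction confidences. Passing tests on these
fixtures therefore demonstrates algorithmic correctness and robustness
to the modeled perturbations, not performance on real STRING-derived
networks.

## Problem sizes used by the test suite and acceptance script

Random-walk oracle checks use 50 random instances of up to 10 nodes per
side, compared to a dense eigen-solver at $10^{-8}$; conductance checks
use 100 random graphs of up to 30 nodes against brute-force edge
counting; recovery studies use query sizes 5–10 against 300-node
backgrounds (60 unperturbed runs, 20 perturbed replicates). These sizes
exercise every code path while keeping the whole suite near a minute of
CPU.

## Known limitations

* **Fragmented reduced targets.** Without a teleportation term, a
  reducible pair chain keeps whatever mass the uniform initialization
  placed on each closed communicating class. When spurious similarity
  scatters positive pairs across many small components, those pairs
  retain disproportionate correspondence and can outrank genuine
  homolog pairs in the seed-selection product score (their single
  concentrated column normalizes to $\bar{c} \approx 1$).
* **Pseudo-edge density under noisy similarity.** With the default
  "any positive score" criterion, every query node links all its target
  hits across components pairwise; at a 5% spurious-pair rate this
  inserts several times more pseudo-edges than real edges, inflating the
  cut of the true module so that conductance-driven extension absorbs
  background hubs up to the size cap. `preprocess.pseudo_sim_quantile`
  exposes a stricter reading of "high similarity" (e.g. 0.75 tests only
  upper-quartile scores), trading this failure mode against the previous
  one.
* These two effects interact: under the combined perturbed benchmark
  (10% deletions/insertions/rewiring plus 5% spurious similarity) the
  pipeline recovers the implant at a Jaccard of about 0.44 on average,
  with roughly a third of replicates above the conventional 0.5
  matching threshold — substantially below the unperturbed setting,
  where recovery is exact. The corresponding acceptance check documents
  this honestly rather than relaxing the conditions.
* Node identifiers are opaque strings; cross-species identifier mapping
  and BLAST score computation are upstream of this package.
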