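---
title: "Discovering transcription-regulating signaling pathways and networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering transcription-regulating signaling pathways and networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trsnet)
```

## The problem

Genome-wide expression experiments tell us *which* genes respond to a
stimulus, but not *along which signaling routes* the response travels, nor
how one signaling pathway switches on another. `trsnet` addresses both
questions on an integrated "omics network" of protein–protein interactions
(PPIs) and protein–DNA (PD, transcription factor → target) interactions:

* a **TRS Pathway** is a simple chain of PPIs from a *start* protein
  (ligand or transmembrane receptor) to an *end* protein (typically a
  transcription factor) whose member genes are transcriptionally perturbed
  in the experiment;
* a **TRS Network** is grown from a seed TRS Pathway by following the
  end transcription factor's PD edges to target genes; when a target is an
  induced start protein, its own top pathways join the network. The result
  is a picture of transcription-mediated cross-talk between pathways.

## The model

### Search-space constraints

Finding maximally perturbed connected subnetworks is NP-hard, so the search
space is restricted by three biologically motivated constraints:

1. paths run from designated start proteins to designated end proteins;
2. PPI edges may not run against the direction of signal flow
   (extracellular → plasma membrane → cytoplasm → nucleus). An edge u → v
   survives if *some* pair of annotated compartments of u and v is
   non-decreasing in that order; nodes without ranked annotation are
   unconstrained. PD edges act in the nucleus and are exempt;
3. paths have at most 10 edges, the range over which curated signaling
   paths are observed.

Undirected PPIs are represented as two opposite directed edges before
filtering, so the directional filter can remove exactly the backward copy.

### Scoring

For gene $i$ with differential-expression p-value $p_i$, the z-score is
$z_i = \Phi^{-1}(1 - p_i)$. A gene set $N$ of size $k$ aggregates to
$Z_N = \sum_{i \in N} z_i / \sqrt{k}$. Because $Z_N$ still drifts with $k$
and with the global z distribution, it is standardized against Monte-Carlo
backgrounds: for each size $k$ we draw 100,000 random size-$k$ subsets of
the gene pool, record the mean $\mu_k$ and standard deviation $\sigma_k$
of their aggregates, and smooth both sequences across $k$ with a centered
moving average (width 5, truncated at the ends). The corrected score

$$S(N) = \frac{Z_N - \mu_k}{\sigma_k}$$

of random sets then has mean 0 and standard deviation 1 at every size, so
scores of paths of different lengths are comparable. The package verifies
this calibration property directly in its test suite and acceptance
script.

A pathway with node set $N$ and edge set $E$ scores

$$P(N, E) = T(N) + R(E), \qquad
  T(N) = S(N) + z_\mathrm{start} + z_\mathrm{end},$$

where the terminal z-scores reward paths whose initiating signal and final
effector are themselves induced — such paths are the interpretable ones —
and $R(E)$ applies the same aggregate-and-standardize construction to the
reliabilities of the path's PPI edges (PD edges carry no reliability; a
path with no PPI edge scores $R = 0$).

The exact rendered forms of the aggregate and of the network score are not
recoverable from the source text of the method; the forms above (and the
network score below) are this package's documented reconstructions, kept
behind single functions (`aggregate_z()`, `network_score()`) so they can
be swapped without touching the rest of the machinery.

### PPI reliability

Public PPI data are noisy, so each PPI receives a reliability in $[0, 1]$
from a logistic regression on four pair features: literature count,
expression-profile Pearson correlation, the mean of the endpoints' local
(Watts–Strogatz) clustering coefficients on the undirected PPI graph, and
a binary co-localization flag. Training resamples positive
(co-immunoprecipitation-grade) and negative (non-interacting) pairs many
times (default 1,000 repeats of 5,000 + 5,000) and averages the predicted
probabilities. PPI edges with mean reliability below 0.6 — roughly the
85th percentile in real corpora — are removed before pathway search. The
pair-level clustering feature is defined here as the endpoint mean because
the source describes only "the proteins' small-world clustering
coefficient"; the definition is isolated in one function.

### Pathway search

$P(N, E)$ is not edge-additive (the background correction depends on path
length), so no shortest-path algorithm is exact for it. Candidate
generation therefore runs a k-best, length-stratified beam search on the
additive non-negative surrogate weight
$w(u \to v) = (z_\max - z_v) + (1 - r_{uv})$, keeping the best
`top_k * overgen` partial paths per (node, depth) — default 5 × 20 — plus
a global cap of 4,000 partial paths per depth, and every completed
candidate is rescored exactly with $P(N, E)$. On small graphs the
candidate set is effectively exhaustive; the test suite bounds the miss
risk by comparing against brute-force enumeration on hundreds of random
graphs. Pathway search traverses PPI edges only: PD edges act through
transcription, which is the between-pathway mechanism handled by network
growth. Ties are broken lexicographically on the node chain, making the
search deterministic.

Pathways can be ranked by the full path score or by the aggregate-only
expression score; the two orders differ exactly when high terminal
induction competes with high interior enrichment.

### Network growth

Growth follows a queue-based expansion. Seed with the top-ranked pathway
of the chosen start gene (or of the globally best pathway when no start is
given) and enqueue its end node. While the queue is non-empty, poll an end
node and walk its outgoing edges in sorted (target, kind) order: a target
that is a differentially expressed gene (DEG, default p < 0.05, strict) or
already in the network joins together with the edge; an added target that
is a start gene, a DEG, and positively regulated (log fold change > 0)
pulls in its top-ranked significant pathways (permutation p ≤ 0.05, capped
at 3 by score — the cap and cutoff are configurable, as the source states
only "highly significant") and their end nodes are enqueued; an added
target that is an end gene and a DEG is enqueued. Each node is polled at
most once and each start pulls its pathways at most once, so growth always
terminates. The network score

$$SF = \frac{S + \sum_i P_i}{|E|}$$

rewards expression content and member pathways and penalizes size; nodes
and edges belonging to no member pathway contribute to $S$ and $|E|$ only
(they interconnect pathways).

### Significance

Pathway and network significance use expression permutation: the
(p-value, log fold change) annotation is shuffled across all network
genes, the identical search is rerun, and
$p = (1 + \#\{\text{perm} \ge \text{obs}\}) / (n_\mathrm{perm} + 1)$
(default 1,000 permutations; an observation beating every permutation is
reported as, e.g., `<1.0e-03`). Edge reliabilities are not permuted —
expression is the perturbed quantity. Two design points matter for
correctness:

* the observed statistic is recomputed through the same pipeline used for
  the permutations, so observation and permutations are exchangeable under
  the null (the backgrounds are permutation-invariant because the z pool
  is a multiset);
* in permutation reruns of the *network* search, member-pathway
  significance filtering is disabled (the top-3-by-score cap remains):
  nested permutation p-values inside each permutation would cost
  $O(n_\mathrm{perm}^2)$ searches. Under the null this affects observed
  and permuted runs identically.

On fully null data both p-values are uniform; the test suite checks this
with Kolmogorov–Smirnov tests over 200 independent replicates.

## The synthetic benchmark

`trs_scenario()` / `generate_network()` / `generate_expression()` generate
complete, file-serializable inputs with planted ground truth. The default
scenario has 300 genes, 1,500 PPI pairs, 150 PD edges, and two planted
5-node chains with a mean z shift of 2.5, joined by a PD cross-link from
the first chain's transcription factor to the second chain's start
protein. Design choices, fixed once:

* planted chains are layered along the signal direction (membrane start,
  cytoplasmic interior, nuclear end) so they satisfy the localization
  constraint by construction; background compartments are drawn with
  cytoplasm most frequent, and a small fraction of genes is unannotated;
* background PPI endpoints are drawn with heavy-tailed propensities
  (configuration-model-like) to mimic PPI hubs;
* planted PPI edges carry reliability 0.95; background reliabilities are
  Beta(2, 3.3), placing the 0.6 filter threshold near the 85th percentile
  — the operating point reported for real corpora — so most background
  edges are removed, as they are in real analyses;
* background z-scores are standard normal (p-values uniform, background
  DEG rate equal to the cutoff); planted members draw
  $z \sim \mathcal{N}(\text{effect}, 1)$; log fold changes are $0.5 z$ so
  their sign always matches;
* the cross-link target start gene is drawn from the effect distribution
  truncated to the DEG region: the scenario plants *an induced start
  protein* — the induction is the phenomenon under test, not a noisy
  outcome;
* background PPI edges never join two planted members: the planted ground
  truth asserts that cross-talk between the chains is purely
  transcriptional, and a chance PPI bridge between them would contradict
  the very label the benchmark scores against. Background corridors
  through non-planted intermediates remain possible and are accepted as
  honest noise.

What the generator does **not** emulate: probe-level measurement noise and
the moderated-statistics pipeline that produces real p-values, correlated
expression between interacting genes, shared nodes between pathways
(ubiquitous in real signaling), and database-specific biases in edge
provenance. Passing the planted-recovery benchmark therefore shows the
machinery recovers transcription-mediated structure when it is present and
identifiable, not that real pathways are equally identifiable.

## Numerical choices and degenerate inputs

* p-values at or beyond 0 and 1 are clamped to $[10^{-16}, 1 - 10^{-16}]$
  before the normal inverse, with a message.
* Background tables require at least 1,000 samples per size and reject
  zero-variance pools; subset draws are exact (without replacement within
  a subset, implemented by vectorized redraw of the rare duplicate rows).
* Smoothing at the ends of the size range truncates the window rather than
  padding.
* Constant (aliased) feature columns in the reliability fit get
  coefficient 0; complete separation falls back to a ridge penalty of
  1e-8 with a warning.
* All orderings that could depend on hash or insertion order are made
  explicit (sorted edge iteration, FIFO queue, lexicographic tie-breaks),
  so every result is reproducible from the seed.

## Problem sizes used in the checks

The packaged checks run at sizes chosen to give statistically meaningful
answers on a single CPU: calibration of the corrected score uses a
10,000-gene pool with 100,000 background samples per size and 10,000
evaluation sets; search-oracle equivalence uses 200 random graphs of up to
12 nodes; permutation calibration uses 200 null replicates at 200
permutations each on 40-gene networks; planted recovery uses 50 replicates
of the default scenario; the overlap test is verified against exhaustive
tail summation for every universe up to size 50.

## Limitations

* The scoring-function reconstructions noted above are faithful to the
  described construction but not guaranteed to match the original
  rendered equations symbol-for-symbol.
* Candidate generation is heuristic on large graphs; optimality is
  bounded empirically, not guaranteed.
* Absolute scores depend on the interaction databases, localization
  coverage, and expression context; they are comparable within one
  analysis, not across database snapshots.
* The permutation null treats genes as exchangeable; correlated expression
  would make it anti-conservative.
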