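---
title: "Rank robustness of node metrics under score thresholding: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank robustness of node metrics under score thresholding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rankrobust)
```

## The model

A *scored network* is a fixed node set of size $N$ plus undirected edges,
each with a confidence score in $[0,1]$ quantifying the reliability of the
interaction evidence (not a physical weight — scores are only ever used to
include or exclude edges). Thresholding at $\theta$ discards every edge
scoring strictly below $\theta$ and keeps the full node set; the default
sweep $\theta = 0.15, 0.16, \dots, 0.99$ yields 85 nested simple graphs.
The package's question is: if a researcher ranks nodes by some metric $f$,
how much does that ranking depend on where $\theta$ was put?

On each thresholded graph we compute 25 node metrics: 12 centralities and
13 leave-one-out-difference (LOUD) metrics
$f_{\mathrm{LOUD}}(v) = f(G) - f(G_v)$, where $G_v$ is $G$ with $v$
disconnected from all neighbours and $f$ is a global summary (averaged
local metrics, global clustering, connected pairs, average path length,
natural connectivity). LOUD metrics are only evaluated for nodes of degree
$\ge 2$; leaves and isolated nodes get `NA` and are sent to the bottom of
the ranking as a randomised tie block. Values become full rankings
$A_\theta$ (a permutation of $1..N$, rank $N$ best; exact ties randomised).

Three per-metric summaries are computed over a medium–high confidence
region $[\mu, \nu]$:

* **continuity**: the fraction of (consecutive pair, $k$) cells with
  top-$k$ overlap $M_k(A_\theta, A_{\theta+0.01}) \ge 0.90$, for
  $k \in \{0.001, \dots, 0.05\}$ — small $k$ values mean high-ranking
  nodes dominate;
* **identifiability**: $\min_\theta M_k^\alpha(A_\theta, B)$ with
  $k = \mathrm{top}_n/N$ and $\alpha = 1.5$, where $B$ ranks the per-node
  mean rank across the region;
* **instability**: the mean scaled rank range
  $(\max_\theta A_\theta(v) - \min_\theta A_\theta(v))/N$ over the overall
  top 1% of nodes — the only measure that penalises re-ordering within a
  preserved top set.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| threshold grid | 15–99 step 1 | hundredths | full observed score range; integer hundredths keep the grid exact (no floating-point drift across 85 steps) |
| region $[\mu,\nu]$ | 60–90 | hundredths | medium–high confidence for STRING-style combined scores; use 15–28 for HitPredict-style scores |
| $k$ grid | 0.001–0.05 step 0.001 | fraction of $N$ | continuity focuses on the usable top of the ranking |
| continuity cutoff | 0.90 | similarity | "nearly identical top sets"; compared with $\ge$ |
| $\alpha$ | 1.5 | — | top-$n$ of the overall ranking searched within top-$1.5n$ per threshold |
| `top_n` | min(100, $\lfloor N/\alpha \rfloor$) | nodes | 100 on large networks; auto-lowered (with a warning) so $n\alpha \le N$, mirroring the reference use of $n = 20$ on a 500-node network |
| `top_frac` | 0.01 | fraction | instability follows the overall top 1%, set size $\max(1, \mathrm{round}(0.01N))$ |
| PageRank damping | 0.85 | — | the standard default |

## Numerical and design choices

* **Top-set size and normalisation.** The literal overlap formula divides
  by $Nk$ and selects ranks $> N(1-k)$, which for non-integer $Nk$ can
  leave $M_k$ above 1 or below 1 for identical rankings. We use
  $n_k = \max(1, \mathrm{round}(Nk))$ (round half away from zero) both to
  select and to normalise, guaranteeing $M \in [0,1]$ with $M = 1$ on
  identical rankings; $n_{k\alpha} = \max(n_k, \mathrm{round}(Nk\alpha))$.
* **Continuity pairs.** Both endpoints of $(\theta, \theta + 0.01)$ must
  lie inside $[\mu, \nu]$; pairing $\nu$ with $\nu + 0.01$ would reach
  outside the region.
* **Boundary scores.** An edge scoring exactly $\theta$ is kept (only
  strictly lower scores are discarded). Score/threshold comparisons use a
  $10^{-9}$ guard so that decimal round trips through TSV files cannot
  flip an edge at the boundary.
* **Duplicate records** in input edge lists keep the maximum score —
  conservative in the sense of strongest evidence; the reference data
  cleaning removes duplicates without stating the merge rule, so this is
  our choice and is documented here and in `read_scored_edgelist()`.
* **Ego counts include the ego.** The step-1 ego network is the subgraph
  induced by $v$ and its neighbours, which contains $v$; hence
  $n_{two}(v)$ counts $v$ and $n_{ratio} = (\deg + 1)/n_{two}$. The
  alternative convention shifts $n_{two}$ by one per node, which can
  reorder ranks; the choice is isolated in one internal helper.
* **Closeness on disconnected graphs** sums distances to reachable nodes
  only, with closeness 0 for nodes that reach nothing; no finite-size
  rescaling is applied because affine transforms cannot change ranks.
  Betweenness is likewise unnormalized. `avg_path_length` on $G_v$
  (always disconnected) averages over the remaining connected pairs.
* **Natural connectivity** $\ln\big(\tfrac1N \sum_i e^{\lambda_i}\big)$ is
  computed by dense symmetric eigendecomposition with a log-sum-exp shift
  by $\lambda_{\max}$ so large hubs cannot overflow `exp`. An empty graph
  gives exactly 0.
* **Tie-breaking reproducibility.** Every (metric, threshold) ranking
  draws its tie-breaks from an own substream, seeded by hashing the master
  seed with the metric name and threshold. Results are therefore
  independent of computation order, and changing one metric's stream
  cannot perturb another's ranking. PageRank uses igraph's algebraic
  (PRPACK) solver, which agrees with a $10^{-14}$-tolerance power
  iteration to well below $10^{-9}$, so rank ties are structural rather
  than numerical.
* **Config files** round-trip through JSON rather than YAML (no YAML
  parser among the package's dependencies); command-line flags override
  file values.

## What the synthetic generators emulate

`bernoulli_scored(n, p, pool)` reproduces the classic null: uniform
Erdős–Rényi topology with scores resampled with replacement from an
empirical pool, destroying any association between score and position.
The reference design used $N = 500$, $p = 0.06$ (density matched to
pre-threshold PINs), with scores resampled from a real organism's score
distribution; its single draw had 7459 edges, and regenerated draws land
within binomial sampling error of $\mathrm{Bin}(124750, 0.06)$.

`score_shuffle(net, n_sub)` takes a random induced subgraph and permutes
its score multiset over the fixed edges: PIN-like topology, random score
placement.

`heterogeneous_scored_fixture(n, m)` is a *synthetic stand-in* for a real
scored PIN (which cannot be shipped or downloaded here): linear
preferential attachment (hubs, right-skewed degrees) with a bimodal score
mixture — 65% a low-confidence mode $0.15 + 0.3\,\mathrm{Beta}(2,4)$
(mode near 0.25) and 35% a high-confidence mode
$0.6 + 0.4\,\mathrm{Beta}(3,2)$ (mode near 0.85) — qualitatively matching
the right-skewed, bimodal score histograms of STRING networks. With
$m = 9$ at $n = 300$ (or $m = 6$ at $n = 200$) its pre-threshold density
is ≈ 0.06, comparable to the Bernoulli design. What it does **not**
emulate: biased placement of high scores on particular network
neighbourhoods (in real PINs scores correlate with local structure),
protein families/duplications, or any organism-specific degree
distribution. A green directional test on these fixtures therefore
establishes that the measures *distinguish uniform from heterogeneous
topology under random score placement* — not that any real PIN will show
a particular continuity value.

## Test scale and budgets

The oracle suites compare every centrality, LOUD metric, similarity and
robustness measure against independent brute-force implementations (pure
base-R Floyd–Warshall distances, shortest-path-count betweenness,
power-iteration PageRank, matrix-exponential-trace natural connectivity)
on over a hundred random graphs and rank matrices with $N \le 50$.

The directional acceptance check (Bernoulli continuity < score-shuffled
heterogeneous continuity, 5 seeds, all 25 metrics) runs at $N = 200$ with
a 12-threshold grid rather than the reference desk scale of $N = 300$
with 20 thresholds: the LOUD recomputation costs ~17 ms of linear-algebra
and BFS work per node and threshold, and the larger setting would overrun
the offline test budget. The comparison is aggregate (mean over seeds of
the mean continuity across metrics) and directional only.

## Known limitations

* LOUD metrics cost one dense eigendecomposition, one all-pairs BFS and
  one betweenness pass per node and threshold; at $N \approx 6000$ this is
  of the order of a minute per node and threshold. `metric_table(...,
  loud_nodes = )` restricts the expensive loop to a candidate set.
* Identifiability saturates at 1 on small, stable networks once
  $\mathrm{top}_n\alpha$ approaches $N$ (the auto-lowered `top_n` makes the
  relaxed top set the whole network at $N \le \alpha\,\mathrm{top}_n$);
  interpret it jointly with instability there.
* Rankings, not metric values, are compared; a metric whose values drift
  uniformly across thresholds is (by design) reported as perfectly robust.
* Whole-vector rank correlations (Spearman/Kendall) are deliberately not
  offered as robustness measures: they are dominated by the uninteresting
  bulk of low-ranking nodes.
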