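# rankrobust

Measuring how robust node-metric rankings are to confidence-score
threshold choice in scored interaction networks.

## The problem

Protein interaction networks (PINs) from databases such as STRING or
HitPredict attach a confidence score `s(e) ∈ [0, 1]` to every edge.
Analyses almost always begin by choosing a threshold θ and keeping only
the edges with `s(e) ≥ θ` — but θ is a free parameter, scores are
re-calibrated between database releases, and different thresholds can
reorder the "most central" nodes that downstream work (e.g. drug-target
prioritisation) depends on. This package quantifies that sensitivity: for
any node metric `f`, it measures how consistent the node *rankings* induced
by `f` are across a sweep of thresholds.

Intended users: systems-biology and network-science researchers choosing
node centralities for scored networks, and methodologists comparing metric
stability on synthetic ensembles.

## The statistics

For a scored network on `N` nodes, thresholding at each
`θ ∈ {0.15, 0.16, …, 0.99}` gives 85 simple unweighted graphs on the
*same* node set. On each graph, 25 node metrics are computed: 12
centralities (degree, local clustering, redundancy, PageRank, closeness,
harmonic, betweenness, and five ego-network counts `e_one`, `n_two`,
`n_diff`, `n_sqdiff`, `n_ratio`) and 13 leave-one-out-difference (LOUD)
metrics `f_LOUD(v) = f(G) − f(G_v)`, where `G_v` disconnects `v` and `f`
is a global summary (average clustering, global clustering, natural
connectivity `ln((1/N)Σᵢ e^{λᵢ})`, connected pairs, average path length,
…). Metric values become full rankings `A_θ` (rank `N` = best; ties and
LOUD-`NA` nodes randomised).

Rank agreement between two rankings is the top-`k` overlap

    M_k(A, A′) = |top_k(A) ∩ top_k(A′)| / n_k ,   n_k = max(1, round(Nk)),

with an asymmetric relaxation `M_k^α(A, B)` that asks how many of the
top-`k` of a reference ranking `B` fall within the top-`kα` of `A`.
Over a medium–high confidence region `[μ, ν]` (0.60–0.90 for STRING-style
scores), three summaries are reported per metric:

* **rank continuity** — fraction of (consecutive-threshold pair, `k`)
  cells with `M_k ≥ 0.90`, for `k = 0.001 … 0.05`;
* **rank identifiability** — `min_θ M_k^α(A_θ, B)` with `k = top_n/N`,
  `α = 1.5`, against the overall ranking `B` (rank the per-node mean of
  ranks across the region);
* **rank instability** — mean over the overall top 1% of nodes of
  `(max_θ A_θ(v) − min_θ A_θ(v)) / N`.

Continuity and identifiability near 1 and instability near 0 mean the
metric's top nodes barely move as θ varies.

## Worked example

```r
library(rankrobust)

net <- heterogeneous_scored_fixture(n = 60, seed = 3)  # PIN-like fixture
net
#> <scored_network> 60 nodes, 495 scored edges
#>   score range [0.154, 0.997]

series <- threshold_series(net, lo = 60, hi = 70)      # theta in hundredths
mt     <- metric_table(series)                         # all 25 metrics
rm_    <- build_rank_matrix(mt, seed = 42)
report <- robustness_report(rm_, confidence_region(60, 70),
                            top_n = 20, seed = 42)
report[report$metric %in% c("degree", "local_clustering", "betweenness",
                            "e_one", "loud_natural_connectivity"), ]
#>                     metric continuity identifiability instability
#>                     degree      0.830               1  0.00000000
#>           local_clustering      0.760               1  0.01666667
#>                betweenness      0.982               1  0.00000000
#>                      e_one      0.812               1  0.00000000
#>  loud_natural_connectivity      0.948               1  0.00000000
```

Reading: across the 11 thresholds 0.60–0.70, 94.8% of the
(threshold-pair, k) cells for LOUD natural connectivity have top-`k`
overlap ≥ 0.90, every one of its overall top-20 nodes stays inside the
top-30 at every single threshold (identifiability 1), and its top nodes'
ranks do not move at all (instability 0). Local clustering is the least
stable of the five: lowest continuity and the only non-zero instability —
its top nodes wander by ~1.7% of the ranking range. On this small, stable
fixture identifiability is 1 for all five metrics; it separates metrics on
larger or noisier networks.

## Command line

```sh
inst/cli/rankrobust simulate --kind bernoulli --n 500 --p 0.06 --seed 1 --out gnp.tsv
inst/cli/rankrobust run --input gnp.tsv --mu 60 --nu 90 --seed 1 --out-dir out/
inst/cli/rankrobust report --ranks out/ranks.tsv --mu 65 --nu 85 --out out/report2.tsv
```

`run` writes `summaries.tsv`, `metrics.tsv`, `ranks.tsv` and `report.tsv`,
each with its parameters echoed as `#` header comments.

## Real data

Download an organism network (e.g. STRING `protein.links.txt`, keeping the
two protein columns and `combined_score`), then
`read_scored_edgelist(path, dialect = "string_v10")` and proceed as above
with `confidence_region(60, 90)`; for HitPredict-style scores use
`dialect = "generic"` and `confidence_region(15, 28)`. LOUD metrics on
networks with thousands of nodes are expensive (dense eigendecompositions
per node and threshold); use the `loud_nodes` argument of `metric_table()`
to cap the work.
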