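# crfalign

Querying and one-to-one alignment of biological networks with conditional
random fields.

Protein–protein interaction (PPI) networks from different species (or
experiments) describe overlapping biology under different identifiers,
with missing edges and lineage-specific gene duplications.  `crfalign` is
for computational biologists who need to locate a small pathway-sized
query inside a large network, or to align two whole networks one-to-one,
while balancing *biological* similarity (sequence scores) against
*structural* similarity (conserved interactions) — the regime where
sequence-only matching cannot tell paralogs apart and structure-only
matching is derailed by network noise.

## The model

Querying `G = (V, E)` in `G' = (V', E')` is a labeling problem: each query
node `v_i` gets a label `y_i ∈ V' ∪ {GAP}`, and a conditional random
field scores labelings by

    Pr(Y | G) = 1/Z(G) · ∏_i f_N(y_i) · ∏_(i,j)∈E f_E(y_i, y_j)

    f_N(y_i)      = S(v_i, y_i)                      (node similarity)
    f_E(y_i, y_j) = (S(v_i,y_i) + S(v_j,y_j))/2 · W(y_i, y_j)

where `W(y_i, y_j) = decay^(d-1)` for target distance `d ≤ dmax` (neutral
for GAP, floored for unreachable or identical labels).  `net_query()`
returns the MAP labeling — exact dynamic programming on forest queries,
damped max-product belief propagation plus a monotone local cleanup on
loopy ones; `Z(G)` is never needed.  `net_align()` turns querying into a
symmetric one-to-one aligner by iterative bi-directional mapping: query in
both directions, fix the reciprocal pairs by clamping their similarity,
repeat until no new reciprocal pair appears.  Best-hit baselines, a
gene-duplication simulator with known ground truth and the standard
evaluation measures (MP, EC, EAC, LCCS, SGO, GO coverage, HP/PAC, OP)
complete the benchmarking toolkit.

## Worked example

Simulate a duplication-evolved copy of a 100-node network, align the two,
and score the result against the known truth:

```r
library(crfalign)

base <- {set.seed(42); g <- igraph::sample_pa(100, m = 3, directed = FALSE)
  network(matrix(as.character(igraph::as_edgelist(g)), ncol = 2),
          nodes = as.character(1:100), name = "yeast_like")}

sim <- duplicate_network(base, sim_params(N = 8, p1 = 0.2, p2 = 0.1,
                                          p3 = 0.005, seed = 7))
sim
#> <dup_sim> 100 -> 108 nodes (8 duplications), 322 edges

S <- synth_similarity(base, sim$network, sim$truth)  # dup carries orig's row
res <- net_align(base, sim$network, S)
res
#> <align_result> 97 fixed pairs in 2 round(s)
#>  round fwd_size bwd_size new_fixed
#>      1       97      108        97
#>      2       97      100         0

evaluate_alignment(base, sim$network, res$mapping, truth = sim$truth, kmax = 3)
#> <evaluation_report>
#>   mp: 97
#>   ec: 99.298
#>   eac: 99.298 100 100
#>   lccs_nodes: 97
#>   lccs_edges: 283
#>   acc_dup: 0.875
#>   acc_all: 0.96
```

97 of 100 base nodes are aligned; 99.3% of their edges are conserved
(`ec`), all images are within distance 2 (`eac`), and the conserved graph
is one component of 97 nodes (`lccs`).  7 of the 8 duplicated nodes are
resolved correctly — original to original, duplicate to gap
(`acc_dup = 0.875`) — where the sequence-only baseline resolves none:

```r
accuracy_dup(best_hit_query(base, sim$network, S), sim$truth)
#> [1] 0
```

The same pipeline is scriptable from a shell via the bundled entry point
(`system.file("cli", "netq.R", package = "crfalign")`) with subcommands
`simulate`, `query`, `align`, `evaluate` and `benchmark`, e.g.

```sh
Rscript netq.R align --net1 G.tsv --net2 Gp.tsv --sim S.tsv -o align.tsv
```

All inputs are plain text: whitespace-separated edge lists, `u v score`
similarity triplets, tab-separated mappings and annotation tables.

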