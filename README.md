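# idgba — information-distance guilt-by-association subgraph extension

`idgba` expands a set of related nodes in a weighted network — a disease
module in a comorbidity graph, a gene cluster in a co-expression network —
by ranking all remaining nodes by how cheaply a random walker starting in
the seed set can *encode* them, and cutting the list off automatically
where the encoding stops beating a null model. It is aimed at network
biologists doing seed-set expansion (candidate disease-gene or
disease-disease prioritization) who want a ranking **with a principled,
data-driven stopping point** instead of a hand-picked `top-k`.

## The method

For a weighted graph $G=(V,E)$ with weights $w_{ij}$:

* transition probabilities: $p_{ij} = w_{ij} / \sum_k w_{ik}$;
* information hop distance (bits): $\mathrm{ihd}(i,j) = -\log_2 p_{ij}$;
* information distance: $\mathrm{id}(i,j) = \min_{\text{paths } i \to j}
  \sum \mathrm{ihd}$ (multi-source Dijkstra);
* null-model threshold: $T = \log_2 |V|$, the cost of naming any node with
  no structural knowledge; thresholded distance
  $\mathrm{idt} = \min(\mathrm{id}, T)$.

Candidates outside the seed set $S$ are scored by the minimum
$\mathrm{idt}$ from the *key points* of $S$ — its inner boundary (default)
or its minimal-eccentricity center — and everything scoring at or above
$T$ is "no better connected than random" and falls outside the
recommendation. Seed-set quality is reported as conductance
$\Phi(S) = \mathrm{Cut}(S,\bar S)/\min(\mathrm{Vol}(S),\mathrm{Vol}(\bar S))$.

The package also ships random-walk-with-restart (RWR) and personalized
PageRank (PPR) baselines, a repeated 80/20 hold-out NDCG evaluation
harness, builders for differential co-expression graphs (case/control
precision-matrix differences with spectral minimum-conductance cluster
selection) and disease-disease association graphs, and synthetic
generators with planted ground truth. See
`vignettes/idgba-methods.Rmd` for the full model description and design
rationale.

## Worked example

Plant a 15-node cluster in a 100-node background graph, hide three of its
members, and extend the remaining twelve:

```r
library(idgba)

res   <- planted_cluster_graph(n_nodes = 100, cluster_size = 15,
                               p_in = 0.6, p_out = 0.02, rng_seed = 42)
seeds <- res$members[1:12]          # held out: n013, n014, n015
ext   <- extend(res$graph, seeds, metric = "boundary")
ext
#> <ranked_extension> metric=boundary, 88 candidates, 66 below T=6.6439 bits
#>     1. n094  1.9928
#>     2. n063  2.4030
#>     3. n013  2.4099
#>     4. n056  2.5217
#>     5. n059  2.6123
#>     6. n015  2.6561
#>     7. n014  2.6903
#> ...
```

Every score is the number of bits needed to reach that candidate from the
seed boundary; the three held-out members surface at ranks 3, 6 and 7,
well below the 6.64-bit null threshold ($T = \log_2 100$), inside the
66-candidate automatic cutoff. The cluster itself is well isolated:

```r
conductance(res$graph, res$members)
#> phi = 0.196397 (cut = 27.748150, vol_s = 141.285948, vol_complement = 174.465638)
```

i.e. only ~20% of the weight incident to the cluster leaves it. The
hold-out harness compares methods on the same splits:

```r
rep <- run_splits(res$graph, res$members,
                  methods = c("idgba-boundary", "rwr"),
                  n_splits = 10, rng_seed = 42)
summarize_evaluation(rep)$per_method
#>           method  mean     sd ci_lo ci_hi
#> 1 idgba-boundary 0.549 0.0649 0.503 0.596
#> 2            rwr 1.000 0.0000 1.000 1.000
```

NDCG is 1 when all held-out members top the ranking. On planted-edge
graphs with i.i.d. weights the min-path score trails propagation baselines
(the vignette explains why — there is no weight contrast for it to
exploit, and that regime is exactly what its automatic cutoff is *not*
about: cutoff recall of the held-out members is still 1.0); on
weight-contrast graphs such as differential co-expression matrices both
approaches saturate.

A command-line interface wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "idgba.R", package = "idgba"))')" \
    extend --graph G.tsv --seeds S.txt --metric boundary --out ranked.csv
```

Subcommands: `extend`, `conductance`, `baselines`, `evaluate`,
`build-coexpr`, `build-disease-graph`, `synth graph`, `synth expression`.
Every run writes a `.prov.json` provenance sidecar and is byte-identical
across repeated invocations at a fixed `--seed`.

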