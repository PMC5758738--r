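# hubpanel

Nominating cross-disease biomarker genes from protein–protein interaction
(PPI) networks.

When several related diseases (the motivating case: esophageal, gastric
and colon adenocarcinomas) share part of their molecular etiology, their
reported gene lists can be intersected and the common core analyzed as one
interaction network. `hubpanel` turns that analysis — usually performed by
hand across Cytoscape apps — into a reproducible R pipeline:

* **Gene lists** — read per-disease lists, intersect them (all-way or
  "present in ≥ k lists").
* **Networks** — generic 2/3-column edge lists, SIF, and STRING
  `protein.links` tables with a combined-score threshold; component
  decomposition; neighborhood expansion around seed genes; degree
  distributions with a log–log power-law fit (the standard scale-free
  check).
* **Centralities** — degree, Brandes betweenness, closeness
  ((n−1)/Σ d), and stress (integer shortest-path counts), exact and
  unweighted, on the main component.
* **Selection rules** — hubs: degree ≥ mean + 2·SD (population SD,
  inclusive boundary); bottlenecks: top 5% by betweenness;
  hub-bottlenecks: the intersection; plus corroborating top-stress /
  top-closeness sets and a per-gene membership matrix.
* **Complexes** — an MCODE-style detector: vertex weight = k ×
  density of the highest k-core of the closed neighborhood, greedy seeded
  expansion within a node-score cutoff, haircut/fluff post-processing,
  complexes scored density × size with the seed gene reported.
* **Enrichment** — GMT annotations, upper-tail hypergeometric
  over-representation `P[X ≥ k]`, Benjamini–Hochberg correction, and
  kappa-statistic grouping of redundant terms (link terms with κ ≥ 0.4,
  groups = connected components).
* **Synthetic data** — a first-class generator that emits every input
  with planted ground truth (gene-list core, scale-free network with
  planted hubs and dense complexes, block-structured annotations), so the
  whole pipeline is testable against known answers.

## Worked example

Generate the default synthetic study (three gene lists sharing a 17-gene
core; a four-component network whose 300-node main component carries 8
planted hubs and three planted complexes; 73 annotation terms of which 43
are enriched in 9 blocks), then run the whole pipeline on the generated
files:

```r
library(hubpanel)

spec  <- synthetic_spec(rng_seed = 42)
truth <- write_synthetic_bundle(spec, "demo")

config <- pipeline_config(
  gene_lists = list(colon = "demo/colon.txt", gastric = "demo/gastric.txt",
                    esophageal = "demo/esophageal.txt"),
  network  = "demo/network.tsv",
  gmt      = "demo/annotations.gmt",
  universe = "demo/universe.txt",
  out_dir  = "demo_out", rng_seed = 42)
res <- run_pipeline(config)

res$partition
#> <component_partition> 4 component(s)
#>  component n_nodes n_edges
#>          1     300     733
#>          2      40      39
#>          3      30      29
#>          4      12      11

res$selection
#> <selection_result> cutoff 19.287 | 8 hubs | 8 hub-bottlenecks | top sets BC/CC/stress: 15/16/15

res$complexes
#> <mcode_result> 4 complex(es)
#>   #1 seed G0033: 14 nodes, density 0.769, score 10.769
#>   #2 seed G0012: 12 nodes, density 0.818, score 9.818
#>   #3 seed G0002: 11 nodes, density 0.800, score 8.800
#>   #4 seed G0001: 231 nodes, density 0.018, score 4.122

cat("significant terms:", sum(res$enrichment$significant),
    "in", attr(res$enrichment, "n_groups"), "groups\n")
#> significant terms: 43 in 9 groups
```

Reading the output: the gene-list intersection has exactly the planted 17
symbols (`res$summary$intersection_size`); the four components have the
planted sizes; the degree cutoff 19.287 (= mean + 2 population SD of main
component degrees) selects exactly the 8 planted hubs, all of which also
sit in the top-5% betweenness set, so all 8 are hub-bottlenecks; the
top-3 MCODE complexes are exactly the three planted modules with their
designated seed genes (rank 4 is the sparse hub periphery, score well
below the planted modules and excluded from the analyzed clusters); and
the enrichment of the crucial genes calls exactly the 43 planted terms,
collapsing into the 9 planted kappa groups. The per-gene membership
matrix is in `res$membership`, and every table is also written to
`demo_out/` as TSV/JSON.

Real analyses swap the generated files for their own gene lists, a
STRING export (`network_format = "string"`, with
`string_score_threshold`, default 400), and a GO/pathway GMT.

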