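# weavenet

Molecular interactions come in two flavors that are usually analyzed in
isolation: undirected physical binding between proteins (PPI networks) and
directed transcription-factor regulation (gene regulatory networks).
weavenet models both in a single *mixed graph* tied to the Gene Ontology,
and answers the question a bench biologist actually asks: *how does my
protein of interest relate, through the interactome, to a biological
process?* It is aimed at researchers working with model-organism
interactomes who want subnetwork hypotheses, motif context, and a
quantitative confidence that a protein belongs to a GO term.

## What it computes

Given a mixed graph `G`, a query protein `s` and a GO term `t`:

* **Subnetwork queries.** *K unique paths*: the `k` shortest simple paths
  (by edge count) from `s` to any protein annotated to `t`, with
  deterministic lexicographic tie-breaking; *K unique nodes*: the `k`
  annotated proteins nearest to `s` by BFS distance, each with a witness
  shortest path. Both run over a physical, regulatory, or mixed edge
  filter; regulatory edges are traversed bidirectionally but keep their
  true direction in output.
* **Mixed motif census.** Counts of five 3-node motif classes — protein
  clique, feed-forward loop (FFL), interacting coregulators, coregulated
  interactors, and mixed feedback loop (an FFL whose TFs physically
  interact; only a mixed graph can tell it from an FFL) — plus enrichment
  Z-scores and empirical p-values against connected random subgraphs of
  the background graph.
* **Annotation ranking.** Personalized PageRank
  `p = (1 - α) r + α Wᵀ p` with damping `α = 0.7`, restarting from the
  proteins annotated to `t`, scores every candidate protein; comparators
  are degree, one-hop GO overlap, and a hypergeometric tail probability.
* **Benchmark harness.** Removed-edge positives with degree-matched,
  proximity-matched negative sampling, pooled by within-trial normalized
  rank into ROC and precision-recall curves with AUCs.
* **Synthetic fixtures.** A generator for ontologies, mixed graphs and
  annotation sets with planted clusters and ground truth, so the whole
  pipeline is testable offline.

## Worked example

```r
library(weavenet)

# A synthetic organism: 120 proteins, 5 GO terms with planted clusters
fx  <- make_mixed_graph(fixture_spec(n_proteins = 120, n_terms = 5,
                                     members_per_term = 12,
                                     ppi_mean_degree = 8, cluster_tfs = 2,
                                     seed = 7))
ann <- propagate_annotations(fx$annots, fx$dag)
fx$graph
#> mixed_graph: 120 proteins, 581 physical edges, 144 regulatory edges (synthetic)

# Connect a cluster regulator to the term it drives
t1 <- fx$terms[1]                       # "GO:1000006"
tf <- fx$truth[[t1]]$cluster_tf[1]      # "P0080"
res <- run_query(fx$graph, ann, query_spec(tf, t1, k = 5))
res
#> query_subnetwork: 5 paths, 6 nodes, 5 typed edges ( k_unique_paths , mixed )
res$paths[[1]]
#> [1] "P0080" "P0001"
```

Five one-edge paths: the regulator touches five annotated cluster members
directly. Is that association strong? The walk thinks so —

```r
rank_query(fx$graph, ann, tf, t1, "random_walk")
#> ranking_report [random_walk]: P0080 vs GO:1000006 -> rank 1 of 109 (score 0.02133)
```

rank 1 of the 109 proteins not annotated to the term: the walk
concentrates on the regulator even though it carries no annotation. The
subnetwork's motif content against the organism background:

```r
cen <- motif_census(fx$graph, res$nodes$id)
motif_enrichment(cen, fx$graph, nrow(res$nodes), reps = 199, seed = 1)
#>                    class observed null_mean enrichment      z     p
#>  coregulated_interactors        2     0.151       13.3  4.25  0.035
#>  ...
```

Two coregulated-interactor motifs (the TF regulating a physically bound
pair) where a random connected 6-node subnetwork holds 0.15 — a 13-fold
enrichment, empirical p = 0.035 at 199 replicates.

## Command line

A thin CLI wraps the same functions (`inst/cli/weavenet.R`):

```sh
Rscript inst/cli/weavenet.R fixtures --out fix --seed 4 --n-proteins 120 --n-terms 5
Rscript inst/cli/weavenet.R build --ppi fix/ppi.tsv --reg fix/reg.tsv \
    --obo fix/ontology.obo --gaf fix/annotations.gaf --out bundle
Rscript inst/cli/weavenet.R query --graph bundle --protein P0001 --go GO:1000006 \
    --k 10 --mode paths --edges mixed --format cytoscape-json --out sub.cyjs
Rscript inst/cli/weavenet.R motifs --graph bundle --subnetwork sub.json --out motifs.json
Rscript inst/cli/weavenet.R rank --graph bundle --protein P0001 --go GO:1000006 \
    --method random_walk --out rank.json
Rscript inst/cli/weavenet.R evaluate --graph bundle --n-positives 50 \
    --n-negatives 50 --methods all --seed 1 --out eval/
```

Subnetworks export as JSON, GraphML, or Cytoscape JSON; the evaluator
writes the dataset, the pooled score table, curve coordinates, and ROC/PR
figures with AUCs in the legend.

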