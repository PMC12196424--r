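# neuroenrich

Regional enrichment of gene sets over a brain expression atlas, with a
weighted co-region gene network on top.

## The problem

Given a curated list of disease-associated genes (e.g. from GWAS
meta-analyses) and a gene × brain-region expression atlas in nTPM units
(such as the Human Protein Atlas brain data: ~20,000 genes × 193
regions), which regions carry *statistically more* of those genes among
their most highly expressed than a random gene list of the same size
would? And do the genes driving those regions form communities that
reveal shared versus region-private genetic architecture?

`neuroenrich` answers both questions for computational neuroscientists
and statistical geneticists working downstream of gene-list curation.

## The method

1. **Highest-expression sets.** For each gene *g* with regional values
   *x<sub>g1</sub> … x<sub>gn</sub>*, region *r* is in *g*'s
   highest-expression set iff
   *x<sub>gr</sub> > mean(x<sub>g·</sub>) + z·sd(x<sub>g·</sub>)* with
   *z* = 1.96 (sample SD; strict inequality). A gene with constant
   expression flags nothing but stays in the sampling universe.
2. **Resampling null.** For a resolved list of length *X*, each of
   *N* iterations (default 10⁶) draws *X* distinct genes uniformly
   without replacement from the whole atlas and tallies per-region
   counts. Because the draw is a uniform subset, each region's null
   count is exactly Hypergeometric(*G*, *m<sub>r</sub>*, *X*) —
   `analytic_reference()` provides this closed form as an independent
   oracle for the simulation.
3. **Scoring.** Per region: *z = (observed − μ̂)/σ̂*, one-sided normal
   tail *p*, Bonferroni correction across regions (at α = 0.05 over 193
   regions the implied critical z is ≈ 3.47), and fold-enrichment
   = observed / μ̂. Exact empirical p-values
   (1 + #{null ≥ observed})/(N + 1) are available via
   `keep_histogram`/`p_source = "empirical"` and are the recommended
   route when strict family-wise control matters (see the vignette).
4. **Network.** Contributing genes × significant regions form a 0/1
   incidence matrix; its one-mode projection is a weighted gene–gene
   graph (weight = number of shared significant regions) analysed with
   nodal strength, normalised betweenness centrality (default distance
   = 1/weight) and Louvain community detection, plus per-region cluster
   composition percentages.

A synthetic-atlas generator (per-gene log-normal baselines with planted
region-specific high-expression programs) makes the whole pipeline
testable end-to-end without downloads.

## Worked example

```r
library(neuroenrich)

gen <- generate_atlas(synthetic_spec(seed = 42))   # 2000 genes x 50 regions,
                                                   # 40-gene program in R01
gl  <- generate_gene_list(gen$truth, n_signal = 30, n_background = 70,
                          seed = 7)
res <- run_pipeline(gen$atlas, as.character(gl), "readme_run",
                    iterations = 1e4, seed = 5)
#> resolved 100/100 gene-list symbols against the atlas
#> incidence matrix: 34 genes x 1 regions
#> assaying 561 gene pairs (choose(34, 2))

res$enrichment[res$enrichment$significant,
               c("region", "observed", "ref_mean", "z", "p", "fold_enrichment")]
#>    region observed ref_mean       z            p fold_enrichment
#> 1:    R01       34   6.9137 10.9112 5.095379e-28        4.917772

res$clusters
#> ClusterAssignment: 34 nodes in 1 clusters (modularity 0.0000, resolution 1, seed 1)
round(res$composition, 1)
#>     cluster1
#> R01      100
```

Reading it: the planted region R01 holds 34 of the 100 list genes among
its highest expressed, versus 6.9 expected for a random 100-gene list —
a 4.9-fold enrichment at z ≈ 10.9, far past the Bonferroni threshold.
All 34 contributing genes share that single region, so the projected
network is one clique, Louvain returns one community and R01's
composition is 100% cluster 1. With several significant regions the same
run emits the full incidence/edge-list/GraphML/metrics/composition files
plus a `manifest.json` that reproduces the run bit-exactly.

A command-line front-end with `run` and `simulate` subcommands is
installed at `inst/scripts/neuroenrich`.

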