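---
title: "Regional gene-set enrichment and co-region networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional gene-set enrichment and co-region networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`neuroenrich` tests whether the genes of a user list are over-represented
among the *regionally most expressed* genes of individual brain regions,
against a null of equally sized random gene lists, and then asks how the
implicated genes and regions organise into communities.

**Highest-expression sets.** The atlas is a dense gene × region matrix of
non-negative nTPM values. For gene $g$ with values $x_{g1},\dots,x_{gn}$
across the $n$ regions, region $r$ belongs to $g$'s highest-expression set
iff

$$x_{gr} > \bar{x}_{g} + z \cdot s_g, \qquad z = 1.96,$$

where $\bar{x}_g$ and $s_g$ are the cross-region mean and standard
deviation of that gene. The rule is per-gene, so it is invariant to
rescaling a gene's row (units, sequencing depth) and to adding a constant;
both invariances are asserted property-style in the test suite. It is a
*relative* specificity rule: a uniformly expressed housekeeping gene flags
nothing, however high its level.

**Resampling null.** For a resolved list of length $X$, each iteration
draws $X$ distinct genes uniformly without replacement from the whole
atlas universe and counts, per region, how many carry that region in their
highest-expression set. The per-region empirical mean $\hat\mu_r$ and SD
$\hat\sigma_r$ over iterations (default $10^6$) parameterise the null.
Because an iteration is a uniform random subset, the count for a region
carried by $m_r$ of the $G$ universe genes is exactly

$$C_r \sim \mathrm{Hypergeometric}(G, m_r, X), \quad
\mathbb{E}[C_r] = X\frac{m_r}{G}, \quad
\mathrm{Var}[C_r] = X\frac{m_r}{G}\Big(1-\frac{m_r}{G}\Big)\frac{G-X}{G-1}.$$

`analytic_reference()` implements this closed form. It serves two roles:
an independent oracle that the simulation must match (the null-calibration
acceptance test), and a fast drop-in when the normal-approximation scoring
suffices. The simulated route remains the primary one because it also
yields the *joint* empirical distribution, the per-region maxima used for
degenerate cases, and exact empirical p-values.

**Scoring.** Per region, $z_r = (c_r - \hat\mu_r)/\hat\sigma_r$ with
one-sided upper-tail normal $p_r$; under Bonferroni, region $r$ is
significant iff $p_r < \alpha / n_{\text{tests}}$ (and $c_r > \hat\mu_r$).
Fold-enrichment is $c_r / \hat\mu_r$. $z^2$ is carried alongside $z$ for
reporting parity with effect-size-style displays.

**Network stage.** Contributing genes (list genes flagging at least one
significant region) × significant regions form a 0/1 incidence matrix;
its one-mode projection $I I^\top$ (diagonal zeroed) is a weighted
gene–gene graph whose edge weights count shared significant regions.
On it we compute nodal strength (sum of incident weights), betweenness
centrality normalised by $2/((n-1)(n-2))$, Louvain communities maximising
weighted modularity, and per-region cluster composition percentages.

## Parameters that matter

| parameter | default | meaning / rationale |
|---|---|---|
| `z_high` | 1.96 | highest-expression multiplier; the conventional two-sided 5% normal point |
| `sd_method` | `"sample"` | $n-1$ denominator; the common default in numerical stacks. Population ($n$) is exposed; it changes the small-$n$ attainability bound from $(n-1)/\sqrt n$ to $\sqrt{n-1}$ |
| `iterations` | $10^6$ | null resamples; tests use $10^4$–$10^5$, which the hypergeometric oracle shows is already well calibrated |
| `alpha`, `correction` | 0.05, `"bonferroni"` | family-wise level over `n_tests` regions (193 for the HPA atlas ⇒ per-test level $2.59\times10^{-4}$, implied $z^* \approx 3.47$) |
| `tail` | `"one"` | enrichment is a one-sided question; `"two"` reproduces the convention in which 1.96 is the base threshold |
| `p_source` | `"normal"` | see *Numerical choices* |
| `include_empty_genes` | `TRUE` | the null draws from *all* atlas genes, including those flagging nothing; excluding them would shrink the universe and inflate every $z$ |
| `distance_mode` | `"inverse_weight"` | betweenness path length $1/w$: more shared regions ⇒ closer. Weights here are similarities, so treating them as costs (the common library default, also exposed) would invert their meaning |
| `resolution`, `louvain_seed` | 1.0, 1 | Louvain parameters; a stability report over 10 seeds is emitted with every run |

## Numerical choices

- **Strict inequality** at the cutoff: a value exactly equal to
  $\bar{x} + z s$ is not flagged ("exceeds" read literally). The test
  suite pins this with a fixture whose cutoff is exact in binary floating
  point.
- **sd = 0 genes** flag nothing and stay in the universe.
- **Degenerate null regions** ($\hat\sigma_r = 0$): $z$ is undefined
  (reported `NA`); the region is significant only if its observed count
  exceeds the simulated maximum, and never when it equals the null mean.
  This avoids division blow-ups without silently dropping regions.
- **Normal vs empirical p.** The normal tail of the simulated null is
  accurate near the centre but *anticonservative* deep in the upper tail,
  because per-region null counts are discrete and right-skewed, so at the
  Bonferroni tail the nominal per-test level understates the true
  exceedance probability. The default stays `"normal"` (cheap, matches the method as usually
  described), but `p_source = "empirical"` with
  $p = (1 + \#\{\text{null} \ge \text{obs}\})/(N+1)$ carries the actual
  family-wise guarantee and is what the planted-signal acceptance
  criterion uses; it costs retaining the $N \times R$ count histogram
  (~770 MB at $10^6 \times 193$, trivial at test scale).
- **Small-$n$ impossibility.** With the sample SD convention the largest
  attainable per-gene $z$ over $n$ regions is $(n-1)/\sqrt n$ (attained by
  a single spike), so atlases with $\le 5$ regions can never flag at
  $z = 1.96$; this algebraic bound is swept exhaustively in the tests.
- **Louvain determinism.** The partition is computed under a fixed,
  logged seed and labels are canonicalised by descending community size
  (ties by first member), making repeated runs identical rather than
  merely equivalent up to relabeling.
- **Gene identity** is the symbol string after whitespace stripping,
  matched exactly; alias/ID mapping belongs upstream of this tool. In the
  HPA long dialect the symbol column is the key and the Ensembl id column
  is ignored.
- **Round-trip fidelity.** The wide-dialect writer emits the shortest
  decimal string that re-reads to the identical double, so
  write-then-read is bit-exact and repeated runs produce byte-identical
  outputs.

## The synthetic generator: what it does and does not emulate

`generate_atlas()` draws each gene's regional values i.i.d. log-normal
with per-gene parameters (meanlog ~ U(−1, 3), sdlog ~ U(0.5, 1.5)), then
multiplies program genes' values in their target regions by an effect
multiplier (> 1). This reproduces the features the pipeline actually
relies on: non-negativity, heavy right skew, between-gene heterogeneity
of level and dispersion, a minority of genes with region-restricted high
expression, and region set sizes that vary. Multiplicative effects
deliberately exercise the flagging rule's scale invariance. The defaults
(2000 genes × 50 regions, one 40-gene program at multiplier 50, lists of
30 signal + 70 background genes) are the stated desk-scale validation
world; `positive_control_atlas()` plants three disjoint single-region
programs to mimic tissue-specific positive-control lists.

What it does **not** model: inter-region correlation (neighbouring brain
regions co-express), gene–gene co-expression modules, measurement noise
structure of RNA-seq pipelines, or compositional constraints of TPM
normalisation. A green planted-signal test therefore establishes that the
statistics and bookkeeping are correct under the stated world — not that
the biological false-positive rate on a real, spatially correlated atlas
equals the nominal one.

## Known limitations

- Only *high*-expression enrichment is sought; depletion or low-expression
  signals are out of scope by design.
- The null is list-length-matched but not expression-level-matched; lists
  biased toward highly expressed genes inherit that bias.
- Bonferroni across regions treats 193 strongly correlated regions as
  independent comparisons — conservative for the family-wise error but
  the regional granularity of the atlas is inherited uncritically.
- Betweenness conventions on weighted similarity graphs are not
  standardised; all three distance transforms are exposed and logged, and
  ranking can differ between them.
- At full scale ($10^6$ iterations × 20,162 genes) the simulation is
  minutes of CPU; the hypergeometric reference is the instant alternative
  when only means/SDs are needed.
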