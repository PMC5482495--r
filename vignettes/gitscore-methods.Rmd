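---
title: "Network-assisted target identification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-assisted target identification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gitscore)
```

## The problem

Chemical-genomic screens in yeast grow a genome-wide collection of deletion
strains in the presence of a compound and quantify each strain's growth
defect. In a haploinsufficiency (HIP) screen, strains are heterozygous
diploids: halving the dosage of the compound's direct target makes the
strain hypersensitive, so the target is expected to show a strong fitness
defect. In a homozygous (HOP) screen, non-essential genes are fully
deleted: the hypersensitive strains are usually genes that *buffer* the
drug-target pathway rather than the target itself. Both readouts are noisy,
and the direct-target signal in HIP screens is frequently masked by
neighboring-gene effects.

The fitness-defect score for strain $i$ under compound $c$ is the log-ratio

$$\mathrm{FD}_{ic} = \log \frac{r_{ic}}{\bar r_i},$$

where $r_{ic}$ is the growth defect under treatment and $\bar r_i$ the
strain's mean growth defect over control conditions. Low, negative FD means
hypersensitivity. `compute_fd()` implements this with base-2 logarithms by
default (the convention for fitness log-ratios); the base only rescales all
downstream scores, which are linear in FD. The control mean is the
arithmetic mean over control columns; which controls enter it can be
restricted via `control_include`, since screen metadata sometimes flags
failed controls and no universal policy exists. Nonpositive or missing
growth values produce missing FD entries rather than infinities: the data
model carries an explicit missing mask end to end.

## The scoring model

A genetic interaction between genes $i$ and $j$ is the deviation of the
measured double-mutant fitness from the multiplicative expectation,

$$g_{ij} = f_{ij} - f_i f_j,$$

negative for aggravating pairs (extreme case: synthetic lethality),
positive for alleviating pairs. `build_network()` computes these from
single- and double-mutant fitness tables; any signed weighted edge list can
be supplied directly. Duplicate $(i,j)/(j,i)$ records are symmetrized by
averaging; the model treats $g_{ij}$ as a single undirected edge weight.

The one-hop score corrects a gene's own FD by the signed, weighted FDs of
its interaction partners:

$$\mathrm{GIT}^{HIP}_{ic} = \mathrm{FD}_{ic} - \sum_{j} \mathrm{FD}_{jc}\, g_{ij}.$$

The intuition: if compound $c$ inhibits gene $i$, then deleting a copy of
an aggravating partner $j$ ($g_{ij}<0$) makes cells more drug-sensitive
(low $\mathrm{FD}_{jc}$), while deleting an alleviating partner
($g_{ij}>0$) relieves the inhibition (high $\mathrm{FD}_{jc}$). Either
pattern makes the subtracted sum positive, pushing the target's score
down even when its own FD carries little signal. For HOP screens the
neighbor's raw FD is replaced by its first-order score,

$$\mathrm{GIT}^{HOP}_{ic} = \mathrm{FD}_{ic} - \sum_j \mathrm{GIT}^{1st}_{jc}\, g_{ij},
\qquad \mathrm{GIT}^{1st} \equiv \mathrm{GIT}^{HIP},$$

so the score sees two interaction hops and captures the pathway-buffer
effect. The general recursion
$\mathrm{GIT}^{(k)} = \mathrm{FD} - G\,\mathrm{GIT}^{(k-1)}$ with
$\mathrm{GIT}^{(0)} = \mathrm{FD}$ is available through `git_k()`; `git_hip()`
and `git_hop()` are $k = 1, 2$. Internally the recursion is evaluated as
dense matrix products in double precision, which the test suite checks
against the unrolled closed forms $(I - G)\,\mathrm{FD}$,
$(I - G + G^2)\,\mathrm{FD}$, $\sum_{m \le k} (-G)^m\,\mathrm{FD}$ to
$10^{-10}$.

Two baselines are provided. The plain FD-score ranks genes by their own
fitness defect. The $\rho$-score (`rho_score()`) is the Pearson correlation
between a gene's interaction-weight profile over its neighbors and the
compound's FD profile over the same neighbors; a high positive value flags
a candidate target. It uses only neighbor information and is known to be
noise-sensitive, which is why it serves as the cautionary baseline.

### Parameters that matter

* `q` (default 100): per-gene truncation of the network to the top `q`
  positive neighbors by weight and top `q` negative neighbors by absolute
  weight, applied before every propagation pass (including the inner
  first-order pass of the HOP score). Truncation is row-wise, so the
  retained relation may be asymmetric. Ties at the q-th slot keep the
  lexicographically smaller gene id, making results reproducible across
  platforms.
* `log_base` (default 2) in `compute_fd()`: pure rescaling, see above.
* `k` (order, default 1 for HIP / 2 for HOP): higher orders integrate
  longer interaction paths; on real noisy networks long paths mostly add
  noise, which is why 2 is the recommended maximum.
* `min_confidence` (default 0.4) in `read_benchmark()`: compound-target
  pairs below this confidence are excluded, with pairs exactly at the
  threshold kept.

### Missing values and degenerate inputs

A missing $\mathrm{FD}_{ic}$ yields a missing score for $(i,c)$; missing
neighbor terms contribute zero to the propagation sums, so a gene's score
stays defined whenever its own FD is observed (the $\rho$-score instead
excludes missing pairs, per its definition, and additionally requires at
least three usable neighbor pairs and nonzero variance on both sides).
Genes screened but absent from the network keep their FD unchanged; network
genes that were never screened contribute nothing. These policies coincide
with the plain formulas on complete data.

## Combining HIP and HOP

`combine_hip_hop()` standardizes each assay's scores per compound across
genes (mean 0, sample standard deviation with $n-1$) and averages the two
z-scores — boosting two complementary weak learners. Per-compound
standardization is the default because compounds differ wildly in potency;
a global variant is available behind the `scope` flag. Under the default
`union` gene policy a gene measured in only one assay keeps that assay's
z-score; `intersection` restricts to genes measured in both.

## Evaluation

`rank_genes()` orders genes per compound (ascending for low-is-hit scores,
descending for the $\rho$-score), breaking ties lexicographically and
placing missing scores last. `recovery_curves()` counts, at each cutoff
$k$, the benchmark compound–target pairs whose target ranks in the top $k$
(criterion "interactions") and the compounds with at least one target in
the top $k$ (criterion "drugs"). Benchmark pairs outside the scored
universe are excluded from the denominator rather than counted as misses,
because an unscored gene says nothing about the scoring method.

The AUC is the plain sum of counts over the integer $k$ grid (unit-width
rectangles); any monotone-equivalent area definition rescales numerator and
denominator of the normalized AUC alike, so

$$\mathrm{nAUC}^{X} = \frac{\mathrm{AUC}^{X}}{\mathrm{AUC}^{\mathrm{ref}}}$$

is insensitive to that choice. The reference defaults to the FD-score, so
nAUC > 1 means better than the raw screen readout, and the reference's own
nAUC is exactly 1 by construction. $K$ defaults to the full gene universe.

### Significance against degree structure

Because drug targets tend to be network hubs, a propagation method could
look good merely by favoring high-degree genes. `randomize_network()`
reassigns every neighbor slot of every gene to a uniformly random other
gene (no self-neighbors, no duplicates within a gene's list) while keeping
each slot's weight and sign — each gene retains exactly its positive and
negative neighbor counts and its incident-weight multiset. The randomized
relation is directed (per-gene), which is exactly how truncated
neighborhoods are consumed, so it drops into the scoring unchanged.
`empirical_pvalue()` recomputes the method's nAUC on `n_random` such
networks and reports the add-one estimate
$p = (1 + \#\{\mathrm{nAUC}_{rand} \ge \mathrm{nAUC}_{obs}\}) / (1 + n_{random})$,
which cannot be zero and matches the bounded way finite-sample empirical
p-values should be reported.

## Co-functional modules

`cluster_genes()` groups genes by k-means on their score profiles across
compounds (Euclidean distance on raw scores; per-compound standardization
optional; missing entries imputed with 0 = "no measured effect" before
clustering). `enrich_clusters()` tests every (cluster, gene set) pair with
the one-sided upper-tail hypergeometric test — equivalent to Fisher's exact
test with `alternative = "greater"` — and adjusts across *all* pairs with
Benjamini–Hochberg (a per-cluster adjustment is available behind a flag;
the global adjustment is the stricter, more common default). The
enrichment universe is the set of clustered genes, since the clusters
partition exactly those. `enriched_cluster_counts()` sweeps the FDR
threshold and counts clusters enriched in at least one set, which is
non-decreasing in the threshold.

## The synthetic study

`simulation_spec()` and its companions generate everything needed to
exercise the pipeline without external data: a signed random network,
HIP/HOP screens with planted targets, and the matching benchmark. The
defaults define the package's reference study conditions — 500 genes, 50
compounds with one target each, unit Gaussian screen noise — sizes chosen
so the complete test suite and the acceptance script run in minutes on one
CPU while leaving all rank-based comparisons well away from saturation.

* **Network**: each unordered pair is independently an edge; expected
  positive/negative degrees 6/10 (aggravating interactions outnumber
  alleviating ones in genome-scale interaction maps, roughly 2:1), with
  half-normal weight magnitudes of scale 0.2, typical of interaction
  scores.
* **HIP signal**: the target's own FD is `attenuation * target_fd`
  (default $0.5 \times -4.5 = -2.25$), calibrated so that the FD-score
  alone recovers about half of the planted targets in the top 10 — leaving
  visible headroom for the network correction. Each neighbor responds
  along its interaction sign, $-\,$`neighbor_gain`$\,\times
  \mathrm{target\_fd} \times g_{tj}$; the gain of 0.4 keeps secondary
  responses weaker than the direct effect, as in real screens.
* **HOP signal**: the target's own FD stays at noise level; the response
  sits two hops out, with sign composing along the path:
  `buffer_gain`$\,\times \mathrm{target\_fd} \times g_{tj} g_{jm}$ added to
  gene $m$'s FD. This reproduces the characteristic pattern in which the
  first-order scores of the target's positive partners come out high and
  those of its negative partners low, so that only two-hop propagation
  pinpoints the target. The gain of 2 gives the HOP assay planted signal
  comparable in strength to the HIP assay's, reflecting that the buffering
  deletions *are* the strongly responding strains in homozygous screens.
* **Noise**: i.i.d. Gaussian, `noise_sd = 1`.

All generators are bit-reproducible: every stage derives its RNG stream
from `spec$seed` plus a small fixed offset (network 0, truth +1, HIP +2,
HOP +3).

### What the generator does and does not emulate

It emulates the geometry the scoring methods rely on: signed one-hop
response patterns, two-hop buffering, attenuated direct signal, missing
values, and benchmark confidence filtering. It does **not** emulate batch
or plate effects, strain-specific growth artifacts, linkage between
neighboring deletions, correlated FD profiles across compounds, or —
importantly — noise in the interaction network itself: the scoring sees
the exact network that generated the signal. Passing tests therefore
demonstrate correctness of the computations and the qualitative ordering
of methods under clean planted signal, not performance magnitudes on real
screens.

One consequence deserves a note. On real, noisy networks, propagation
orders beyond $k = 2$ degrade because long paths accumulate spurious
contributions. Under this generator they do not: with an exactly known
network and i.i.d. screen noise, order-$k$ propagation re-accumulates the
planted signal through backtracking paths (with a geometric factor
$\sum_j g_{tj}^2 \approx 0.64$ at the defaults) faster than it accumulates
noise, so measured nAUC keeps improving slowly with $k$ at any noise
level. The recommendation to stop at $k = 2$ rests on the structure of
real data, and the corresponding robustness check in the acceptance tests
documents this limitation of the clean generator rather than a property of
the estimator.

## Numerical choices

* Propagation is dense double-precision matrix arithmetic; at the package's
  intended scales (up to a few thousand genes) this is faster and simpler
  than sparse representations in R.
* Score ties in ranking and weight ties in truncation are broken
  lexicographically by gene id — deterministic across platforms and
  sessions.
* k-means uses `stats::kmeans` with `nstart = 5` under a caller-supplied
  seed; the degenerate `n_clusters = n_genes` case bypasses k-means and
  assigns singletons.
* Matrix TSVs are written with 17 significant digits so write→read
  round-trips are bit-exact.

## Limitations

* The scoring assumes the network weights are on a scale where
  $\sum_j |g_{ij}| \lesssim 1$ per gene; wildly larger weights make the
  propagation dominated by neighbor terms (no internal normalization is
  applied, matching the method's definition).
* The $\rho$-score needs at least 3 usable neighbors; genes with smaller
  measured neighborhoods are unscored and ranked last.
* The permutation test randomizes neighbor identity only; it does not test
  against alternative null models (e.g. weight shuffling).
* Combined scoring assumes the two assays share a gene-id namespace.
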