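---
title: "Bootstrapped correlation networks: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bootstrapped correlation networks: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(netboot)
```

## The problem

Co-occurrence networks are a standard lens on community data: nodes are
features (microbial taxa, metabolites, genes), and an edge connects two
features whose abundances are strongly rank-correlated across samples.
Two questions are routinely left unanswered in network studies. First, how
*robust* is a reported network statistic — would it survive resampling of
the underlying samples? Second, are two networks built from different
conditions *statistically* different, metric by metric? `netboot` answers
both with a bootstrap: resample the samples with replacement, rebuild the
network for every replicate, and treat the per-replicate statistics as a
sampling distribution.

## The pipeline

For an $n \times p$ feature table (rows samples, columns features):

1. **Bootstrap** — draw $B$ replicates, each of $n$ rows sampled uniformly
   with replacement (`bootstrap_replicates()`, default $B = 100$). The
   resampling unit is always the whole sample row, never a feature, and a
   single seeded generator stream drives all $B$ draws so a run is
   reproducible from one integer.
2. **Correlate** — for each replicate, the $p \times p$ Spearman matrix
   (`correlation_matrix()`). Spearman is the Pearson correlation of average
   (fractional) ranks, so it is invariant to monotone transforms of the
   marginals and robust to the heavy tails typical of count data.
3. **Threshold** — an undirected signed graph keeps the pairs with
   $|\rho| \ge t$ (default $t = 0.8$, inclusive on both sides; modes
   restrict to positive-only or negative-only edges). The node set is the
   set of edge *endpoints*: isolated features are excluded, which keeps the
   node count an informative statistic rather than the constant $p$.
4. **Measure** — seven statistics per replicate (`graph_metrics()`): edge
   count, node count, average degree centrality, transitivity, average
   closeness, average betweenness, and density.
5. **Summarize and compare** — bootstrap mean and standard deviation per
   metric (`analyze_network_statistics()`); between two datasets, a
   replicate-paired exact binomial test per metric
   (`net_stat_binomial_test()`).

## Network statistics, precisely

All graph algorithms are implemented from first principles on the
unweighted skeleton (correlation magnitude decides whether an edge exists
and how it is drawn, but never path length):

- **Degree centrality** of a node is $\mathrm{deg}(v)/(N-1)$; its average
  over the $N$ nodes equals the density $2E/(N(N-1))$ identically, and the
  implementation computes both from the same integer ratio so the identity
  holds to the last bit.
- **Transitivity** is $3 \times \text{triangles} / \text{connected
  triples}$, with 0 returned when no connected triples exist.
- **Closeness** uses the Wasserman–Faust component correction: for node
  $u$ in a component of size $k_u$,
  $\frac{k_u - 1}{N - 1}\cdot\frac{k_u - 1}{\sum_v d(u,v)}$ with unweighted
  shortest-path distances inside the component. This keeps values
  comparable across the disconnected graphs bootstrap thresholds routinely
  produce, and matches the default of the mainstream graph libraries.
- **Betweenness** is accumulated by a Brandes-style BFS per source, halved
  for undirectedness, and normalized by $(N-1)(N-2)/2$.
- Per-node centralities are arithmetically averaged over the node set to
  give one number per network per replicate — the quantity the box plots
  show.
- Degenerate denominators (empty graphs, $N \le 2$, no triples) all
  return 0, so bootstrap summaries never propagate NaN.

The test suite checks these implementations against brute-force
enumeration (all triples; exhaustive shortest-path listing; Floyd–Warshall
distances) on hundreds of random graphs, and against igraph as an
independent library cross-check.

## The paired binomial test

For each metric, replicate $i$ of dataset A is paired with replicate $i$
of dataset B. Exact ties are dropped (sign-test convention — a tie is
evidence for neither direction, and integer metrics such as edge counts
tie often); among the remaining $n$ pairs, $k$ counts the pairs where A
exceeds B. Under the null of no difference $k \sim \mathrm{Binomial}(n,
1/2)$, and the two-tailed p-value is $\min(1,\, 2\min(P(X\le k), P(X\ge
k)))$. Tail sums are accumulated in log space, so the reported
$\log_{10} p$ stays finite even when the p-value underflows double
precision — with 500 replicates and one dataset always ahead,
$p = (1/2)^{499} \approx 10^{-150.2}$, which prints as 0 with an
underflow note. The reported statistic is $k/n$. Replicate-$i$-to-$i$
pairing (rather than all $B^2$ cross pairs) keeps the binomial's nominal
$n$ honest; requiring equal $B$ on both sides is enforced at
configuration time. No multiple-testing correction is applied across the
seven metrics — all raw p-values are reported so users can correct as
they see fit.

A note on the summary table: the per-metric dispersion is labelled
`std_error` and is the sample standard deviation (denominator $n-1$) of
the bootstrap metric values — the bootstrap estimate of the statistic's
standard error.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `iterations` | 100 | bootstrap replicates per dataset (500 is typical for publication-grade comparisons) |
| `threshold` | 0.8 | minimum $|\rho|$ for an edge, inclusive |
| `mode` | `"both"` | edge signs kept: both, positive-only, negative-only |
| `top_k` | 20 | nodes in the top-connectivity report |
| `pseudocount` | 1 | clr offset for count tables; clr is never applied implicitly |
| `max_degree` | unset | optional hub filter: drop nodes whose pre-filter degree exceeds it, then drop newly isolated nodes |

The clr (centered log-ratio) transform is offered as an explicit
preprocessing step for compositional count data; because Spearman is
rank-based the transform does not change within-sample rankings'
correlations, but it is the conventional scale on which microbiome
feature tables are analyzed and shipped.

## What the synthetic generator emulates — and what it does not

`synthetic_design()` builds tables from Gaussian latent factors: each
block of features shares one latent standard-normal vector per sample,
each member adds independent noise (`latent_noise_sd`, default 0.3, which
gives within-block correlations near 0.9 — comfortably above the 0.8
threshold, the regime the pipeline targets), and noise features are
independent standard normals. A block with `sign = -1` alternates member
signs (+, −, +, …), planting negative edges between opposite-sign
members. Because every downstream step is rank-based, monotone marginal
transforms are irrelevant, so Gaussian latents plant *exact* rank
correlations at zero noise; `exponentiate = TRUE` produces positive
abundance-like tables with identical rank structure for clr tests.

Defaults (30 samples, two positive blocks of 4, 8 noise features) are a
realistic small-study shape for the community datasets this kind of
pipeline is applied to. The generator deliberately does **not** emulate
sequencing depth variation, compositional closure, zero inflation, or
taxon-specific dispersion: passing tests demonstrate that the pipeline's
algorithms are correct and well calibrated, not that a 0.8 Spearman
threshold is the right instrument for any particular real dataset.

Two structural notes established while testing:

- With a *single* zero-noise block, thresholded networks recover exactly
  the planted edge set (with planted signs) on every bootstrap replicate
  with at least 3 distinct rows — a deterministic guarantee.
- With *several* independent zero-noise blocks, planted edges are still
  always recovered, but occasional spurious cross-block edges can appear
  when a replicate's resampling happens to align the two independent
  latent factors; the guarantee that is deterministic is containment, not
  exactness. Tests and the acceptance script therefore assert exactness
  on the single-block design and containment on multi-block designs.

## Numerical and design choices

- **Ties in ranks**: average (fractional) ranks, i.e. tie-corrected
  Spearman via Pearson-on-ranks — the behavior of mainstream statistics
  routines.
- **Constant columns**: bootstrap resampling of sparse data often yields
  replicates where a feature is constant; its correlations are undefined.
  They are stored as 0 — so they can never form edges — and every event is
  recorded in a degeneracy log that the workflow writes into the run log,
  rather than silently propagating NA into thresholds.
- **Threshold inclusivity**: $|\rho| \ge t$, so boundary values form
  edges.
- **Rendering determinism**: network drawings are written as SVG markup
  directly, with a seeded Fruchterman–Reingold layout and fixed-precision
  coordinates, so identical input produces byte-identical files. Node
  color is sky blue; positive edges are blue, negative red; stroke width
  grows linearly from 0.5 px at $|\rho| = t$ to 4 px at $|\rho| = 1$.
  Plots use the standardized `X1`, `X2`, … labels with the name map
  written alongside, because full taxonomy strings are unreadable at
  network scale.
- **Degree-cap semantics**: `max_degree` keeps nodes whose degree on the
  unfiltered graph is at most the cap, takes the induced subgraph, and
  drops newly isolated nodes. The top-`k` rendering keeps the selected
  nodes even if the restriction isolates them (the selection was
  explicit).
- **Tie-breaks**: top-node rankings order by degree descending, then node
  label ascending, making reports stable under node-set permutations.
- **Seeds**: the API accepts `seed = NULL` (nondeterministic), but the
  workflow layer always records the seed it used in `run_log.json`, so
  published runs are replayable; the two datasets of a comparison use
  distinct streams derived from the one configured seed.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script simulations use 12–50 samples,
8–20 features, and 100–500 bootstrap replicates (the calibration check
runs 50 repeated self-comparisons at $B = 200$; the separation check 20
seeded runs at $B = 100$). These sizes give stable Monte-Carlo estimates
for every property checked while keeping a full run in the minutes
range on a single core.

## Worked example

```{r example, eval = FALSE}
des_a <- synthetic_design(blocks = list(corr_block(4), corr_block(4)),
                          n_noise_features = 8, seed = 1)
des_b <- synthetic_design(blocks = list(corr_block(4)),
                          n_noise_features = 12, seed = 2)
tabs <- generate_paired_tables(des_a, des_b)

cfg <- run_config(tabs$a, tabs$b, iterations = 500, seed = 11,
                  out_dir = "pcos_style_run")
res <- run_compare(cfg)
res$comparison          # seven paired binomial tests
glance(res$comparison)  # one-row summary
autoplot(res$A$stats)   # bootstrap distributions, dataset A
```

## Known limitations

- Pairwise Spearman ignores compositional coupling; no SparCC-style
  correction is attempted, and no p-value is attached to individual
  correlations — edges are thresholded on magnitude only.
- Shortest paths are unweighted; correlation magnitude styles the drawing
  but does not define distances.
- The binomial comparison is pairwise (two datasets); multi-group
  comparisons must be run as pairs.
- Execution is single-threaded; the per-replicate work is embarrassingly
  parallel but not parallelized here.
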