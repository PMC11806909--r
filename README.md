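# netboot

Bootstrap construction and statistical comparison of correlation networks
for numeric feature tables — microbial taxon counts, clr-transformed
abundances, metabolite intensities, or any samples-by-features matrix.

Co-occurrence networks are widely reported without any statement of
uncertainty: a single network is built from a single dataset, and its
metrics (edge count, transitivity, centralities) are read off as if they
were exact. `netboot` targets two questions that a point estimate cannot
answer:

1. **How robust is a network statistic?** Resample the samples with
   replacement, rebuild the thresholded Spearman network for every
   replicate, and report the bootstrap distribution of each statistic.
2. **Are two networks different?** Pair replicate *i* of dataset A with
   replicate *i* of dataset B and test each metric with an exact
   two-tailed binomial test on the wins.

## The method in brief

For an *n* × *p* table, each of *B* bootstrap replicates draws *n* sample
rows with replacement. Per replicate, the *p* × *p* Spearman matrix
(Pearson on average ranks) is thresholded at |ρ| ≥ *t* (default
*t* = 0.8, signed edges, isolated features excluded), and seven
statistics are computed from first principles: edge count, node count,
average degree centrality (≡ density, 2E/(N(N−1))), transitivity
(3 · triangles / connected triples), average closeness (Wasserman–Faust
component correction), average betweenness (Brandes accumulation,
normalized by (N−1)(N−2)/2), and density.

Between two datasets, for each metric with ties dropped, *k* of *n*
paired replicates have A > B; under the null *k* ~ Binomial(*n*, ½) and
*p* = min(1, 2·min(P(X ≤ k), P(X ≥ k))), accumulated in log space so the
reported log₁₀ *p* stays finite when *p* underflows (500 straight wins →
*p* = (½)⁴⁹⁹ ≈ 10⁻¹⁵⁰·²).

## Worked example

Two synthetic datasets with known structure: A plants two blocks of 4
strongly co-varying features (12 strong pairs), B one block of 4
(6 strong pairs), equal feature counts.

```r
library(netboot)

des_a <- synthetic_design(blocks = list(corr_block(4), corr_block(4)),
                          n_noise_features = 8, seed = 1)
des_b <- synthetic_design(blocks = list(corr_block(4)),
                          n_noise_features = 12, seed = 2)
tabs <- generate_paired_tables(des_a, des_b)

cfg <- run_config(tabs$a, tabs$b, iterations = 500, seed = 11,
                  out_dir = "example_run")
res <- run_compare(cfg)
res$comparison
#> Replicate-paired binomial comparison (B = 500, alpha = 0.05)
#> # A tibble: 7 × 7
#>   metric                n_effective k_successes statistic   p_value log10_p direction
#>   <chr>                       <int>       <int>     <dbl>     <dbl>   <dbl> <chr>
#> 1 n_edges                       497         491   0.988   1.00e-136  -136.  A-greater
#> 2 n_nodes                       496         495   0.998   4.86e-147  -146.  A-greater
#> 3 avg_degree_centrality         498           2   0.00402 3.04e-145  -145.  B-greater
#> 4 transitivity                  266          19   0.0714  9.19e- 52   -51.0 B-greater
#> 5 avg_closeness                 498           2   0.00402 3.04e-145  -145.  B-greater
#> 6 avg_betweenness               265         245   0.925   2.11e- 50   -49.7 A-greater
#> 7 density                       498         2     0.00402 3.04e-145  -145.  B-greater
```

Dataset A wins on raw size — in 491 of 497 untied pairs it has more edges
(bootstrap means 10.4 vs 6.0 edges, tracking the planted 12 vs 6 strong
pairs) — while B's smaller network is relatively denser and tighter, so
the normalized metrics (degree centrality, closeness, density) point the
other way. Every call is backed by an exact p-value; `glance()` gives the
one-row summary (here: 7 of 7 metrics significant at α = 0.05).

`example_run/` then contains, per dataset, the replicate statistics CSV,
the signed network SVG (sky-blue nodes, blue positive / red negative
edges, width proportional to |ρ|), top-node and name-map tables, plus
seven cross-dataset box plots, `comparison.csv`, and a `run_log.json`
recording seed and configuration — everything needed to replay the run
exactly.

A thin command-line wrapper covers the same workflow
(`inst/cli/netboot.R`, subcommands `run`, `compare`, `synth`).

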