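# mitonet

Mitochondrial DNA mutation–cancer networks and variant-set overlap
significance.

## What it is for

Tumours accumulate mitochondrial DNA (mtDNA) variants, and the same variant
is often observed in several cancer types. `mitonet` is for analysts who have
per-sample mtDNA variant tables from two cohorts — typically a focal cohort
(e.g. gastric cancer) and a pan-cancer panel — and want to ask, cancer type by
cancer type, whether the variant sets overlap more than chance allows. The
package:

- reads per-sample variant tables (TSV; optionally VCF restricted to the
  mitochondrial contig), deduplicates calls, and derives per-cancer variant
  sets and distinct-sample carrier counts;
- merges two cohorts on shared variants, keyed by position alone or by
  position plus alternate allele, and classifies each shared variant as more
  frequent in one cohort or the other;
- annotates positions to named regions of the circular 16,569-bp rCRS
  reference (37 genes plus one control-region feature wrapping the origin,
  16024..576, so that "D-loop" covers the whole major noncoding region);
- builds the bipartite mutation–cancer network G(V, E), whose node classes
  are variant keys (u) and cancer-type labels (v), and exports it as
  edge-list TSV, GraphML, or node-link JSON for force-directed viewers;
- tests pairwise overlap with the Jaccard index and a randomization-based
  empirical p-value, and reproduces the downstream summaries (largest shared
  count, significance strata, variants recurrent across cancer types).

## The statistic

For the variant sets *A* and *B* of two cancer types, the overlap is the
Jaccard index

    JC(A, B) = |A ∩ B| / |A ∪ B|.

Significance is assessed against a randomization null: in each of *R* rounds
(default 100,000) both sets are redrawn uniformly from the merged variant
universe at their observed cardinalities — i.e. the variant–cancer
associations are randomized conditional on the per-cancer association counts
(N_A, N_B) — and the null Jaccard index is recorded. The empirical p-value is
the upper tail

    p = #{ JC_null ≥ JC_obs } / R        (raw convention)
    p = (#{ JC_null ≥ JC_obs } + 1) / (R + 1)   (plus-one convention)

with ties counting as exceedances. Results carry the three-star significance
key defined on the raw scale: `***` for p ≤ 1e-6, `**` for p < 0.01, `*`
(not significant) otherwise. A degree-preserving double-edge-swap null over
the full bipartite network is available as an alternative, and the exact
hypergeometric tail is provided as a closed-form diagnostic cross-check.

Packaged fixtures transcribe the published 22-row pairwise summary table and
the 30 shared positions with their region labels, so the published counts are
reproducible offline; a synthetic-cohort generator with planted overlaps
provides full ground truth for validating the statistics.

## Worked example

```r
library(mitonet)

tab <- load_table1_fixture()        # the 22 published pairwise overlaps
sv  <- load_shared_variant_fixture()# the 30 shared positions + somatic flags
map <- build_region_map()

summarize_regions(map, sv$position)$n_regions
#> [1] 11
max_shared(tab)
#> $count
#> [1] 8
#> $cancers
#> [1] "Kidney-RCC"    "Liver-HCC"     "Prost-AdenoCA"
names(multi_cancer_variants(tab, min_cancers = 2, significant_only = TRUE))
#>  [1] "73"    "10810" "11914" "12705" "16111" "16129" "16189" "16278"
#>  [9] "16311" "16327" "16527"
```

The 30 shared positions fall in 11 mitochondrial regions; the largest
pairwise overlap is 8 variants, attained by kidney, liver and prostate
cancers; and 11 variants are shared with at least two cancer types at
significance — the published headline counts.

On synthetic cohorts with known ground truth:

```r
sim <- generate_cohorts(synthetic_preset("table1-like", seed = 1))
net <- network_from_cohorts(sim$cohort_a, sim$cohort_b)
net
#> <mutation_cancer_network> 596 variant nodes, 23 cancer nodes, 2580 edges
res <- overlap_scan(network_variant_sets(net), "GC",
                    universe = sim$truth$universe_keys,
                    config = permutation_config(10000, seed = 1))
head(res[, c("cancer_b", "n_shared", "jaccard", "p_raw", "significance")], 3)
#>         cancer_b n_shared    jaccard  p_raw significance
#> 1 Breast-AdenoCA        4 0.05263158 0.2282            *
#> 2     Kidney-RCC        8 0.05517241 0.6618            *
#> 3      Liver-HCC        8 0.05228758 0.7380            *
```

Every planted shared count is recovered exactly (`res$n_shared` equals the
preset's planted overlaps), and the p-values reflect that in this preset the
large per-type sets make overlaps of a few variants unremarkable under the
null — see the vignette for the power analysis of this regime.

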