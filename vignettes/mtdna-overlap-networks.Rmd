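---
title: "Methods: mtDNA mutation–cancer networks and overlap significance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mtDNA mutation–cancer networks and overlap significance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitonet)
```

## The analysis in one paragraph

Two cohorts of per-sample mitochondrial variant calls — a focal cohort such
as gastric cancer (GC) and a multi-type pan-cancer panel — are merged on
their shared variants. Each variant is a 1-based position on the rCRS
mitochondrial reference, optionally with reference/alternate alleles. The
merged data define a bipartite mutation–cancer network G(V, E): variant keys
on one side, cancer-type labels on the other, an edge wherever the variant
was reported in that cancer type. For each cancer type paired with the
reference, the overlap of their variant sets is summarized by the Jaccard
index and tested against a randomization null, yielding an empirical p-value
and a three-star significance category. Downstream summaries — region
annotation of shared positions, carrier-frequency classes, the largest
shared count, variants recurrent across types — are computed from the same
objects.

## Variant identity and cohort merging

Sources differ in whether they report alleles, so two merge keys are
supported: `position_only` (`"73"`) and `position_and_alt` (`"8584:G>A"`).
The default is `position_and_alt` when both cohorts carry complete alleles,
with an explicit, messaged fallback to `position_only` otherwise; which
convention the original analyses used is not always stated, and providing
both makes the choice auditable. Carrier counts are **distinct samples**, not
call counts: a duplicated (sample, variant) row contributes once. A shared
variant is classed `higher_in_a`, `higher_in_b` or `equal` by the sign of
the carrier-count difference. Origin status (somatic / germline / unknown)
is carried through but never filters the merge — the somatic subset is a
reporting view, not a separate pipeline.

## Region annotation on a circular genome

The default region map holds the 37 canonical mitochondrial genes at their
standard rCRS coordinates plus one control-region feature spanning
16024..576. Two conventions matter:

- **The D-loop label covers the whole major noncoding region.** Positions
  73 and 489 as well as 16024..16569 all annotate to "D-loop". The feature
  wraps the origin (start > end), and membership is circular: 16024, 16569,
  1 and 576 are inside; 16023 and 577 are not.
- **Overlapping genes are resolved deterministically.** All containing
  features are reported; the primary label is chosen by category priority
  (protein_coding > rRNA > tRNA > control_region), then an optional numeric
  priority column, then smaller feature start. MT-ATP8/MT-ATP6 overlap at
  8527..8572 (primary MT-ATP8) and MT-ND4L/MT-ND4 at 10760..10766 (primary
  MT-ND4L); none of the packaged fixture positions falls in an overlap, so
  the tie-break does not affect the published region counts. Positions
  covered by no feature are "intergenic", making the map total: the 16,569
  primary labels partition the genome.

The map ships as a data file (`inst/extdata/rcrs_regions.tsv`) rather than
code so users can substitute their own; custom maps are validated for
coordinate range, category vocabulary, and resolvable overlaps.

## The randomization test

For sets *A* and *B* inside a variant universe *U*, the observed statistic is
`JC = |A∩B| / |A∪B|`. The null model randomizes the variant–cancer
associations while conditioning on the association counts (N_A, N_B):

- **Size-preserving resampling (default).** Each round redraws both sets
  uniformly from *U* at their observed cardinalities, independently per
  cancer per round. This is the simplest null consistent with conditioning
  on set sizes, and it makes the null shared count exactly hypergeometric —
  which the package exposes as a closed-form diagnostic
  (`hypergeom_overlap_pvalue()`) and the tests use as an independent oracle.
- **Degree-preserving edge swaps (alternative).** A Markov chain of double
  edge swaps over the full bipartite incidence structure, preserving every
  variant's and every cancer's degree. The chain burns in for 5|E| proposals
  and records one value per |E| proposals thereafter. This null additionally
  conditions on how promiscuous each variant is across cancer types; it
  requires the full per-cancer set list, not just the tested pair.

The p-value is the upper tail with ties counted as exceedances. Two
conventions are reported side by side: `raw` (count/R), which can reach 0
and is the scale on which the published three-star key is defined (`***`
p ≤ 1e-6 is attainable at R = 100,000 only with a zero exceed count), and
`plus_one` ((count+1)/(R+1)), which is never 0 and is used for calibration
work. The boundary p = 0.01 is classed not significant: the published key
defines `**` as p < 0.01 and `*` as p > 0.01, and the gap at equality is
closed toward non-significance. No multiple-testing correction is applied to
the headline p-values, matching the published analysis; a Bonferroni column
over the tested pairs is emitted as supplementary output.

**Universe definition.** The sampling frame defaults to the union of all
variants across the cancer nodes under analysis and can be overridden with a
user-supplied superset (e.g. the full generator pool). The published
analysis never states its frame; making it explicit and configurable keeps
the choice visible.

**Determinism.** Every randomized quantity is driven by the seed in
`permutation_config()`; a scan with a fixed seed produces byte-identical
overlap tables and network exports across runs. The RNG state of the calling
session is saved and restored.

## The packaged fixtures

Two small TSVs transcribe the published summaries: the 22 pairwise rows
(Jaccard index, star category, shared positions — numeric p-values were not
published, so only the category is stored; thousands separators in position
labels are stripped) and the 30 shared positions with region labels and the
11-position somatic subset. The published text lists one region name with an
evident typographical truncation; the fixture uses the standard gene symbol
(MT-ND1). The INDEL side of the pan-cancer source shared no variants with
the focal cohort, so the fixtures contain SNVs only, though INDELs are
representable (unequal allele lengths). One published inconsistency is
resolved in favour of the table: the prose lists a pancreatic endocrine
cancer among the significant carriers of several variants while the table
marks that type not significant and the pancreatic adenocarcinoma rows
significant; the fixtures follow the table. The union of the 22 rows'
variant lists equals the 30-position list exactly (a cross-consistency test
asserts this).

## The synthetic-cohort generator

The generator emulates the study's shape — two cohorts, one reference cancer
and a panel of types, a global variant pool of distinct rCRS positions —
with known ground truth: per-type set sizes, per-type planted overlaps with
the reference, and per-variant carrier counts drawn as 1 + Poisson(0.6)
truncated at the type's sample count (a low mean keeps most variants at one
or two carriers, as in sparse somatic data, while realizing all three
frequency classes). With chance overlap disabled (default), non-planted
variants are drawn from the stratum disjoint from the reference set, so the
realized overlap equals the planted count exactly and recovery can be
asserted sharply; with chance overlap enabled, sets are drawn independently
from the whole pool — the regime used for null calibration.

The `"table1-like"` preset fixes the study-scale conditions: a pool of 600
variants, a 13-sample reference cohort with 50 variants, the 22 published
cancer-type labels with their printed sample counts (2 for the one type
whose count was not printed), set sizes evenly spanning 30..200, and planted
overlaps equal to each pair's published shared count (1..8). The `"toy"`
preset (pool of 8, sets of 3) is small enough for exhaustive enumeration.

What the generator does **not** emulate: population structure and haplogroup
background, mutational signatures, heteroplasmy fractions, sequencing error,
and the correlation between sample count and variant count. Passing tests on
synthetic data therefore validate the bookkeeping and the statistics, not
the biological interpretation of any real-data result.

## Validation strategy and problem sizes

- **Oracle equivalence.** On a pool of 8 variants with two sets of 3, the
  permutation p (R = 20,000) is compared with the exact tail probability
  enumerated over all C(8,3)² = 3,136 equally likely set pairs, within three
  Monte-Carlo standard errors; a second test compares against the
  closed-form hypergeometric tail on a 30-variant pool.
- **Null calibration.** 200 independent null pairs (table1-like magnitudes,
  no planted overlap, R = 2,000, plus-one convention) must reject at
  p < 0.05 at a rate inside the exact binomial 99% interval around 5%.
- **Planted recovery.** 100 replicates of a regime with a pool of 600, sets
  of 50 and 8 planted shared variants, against decoys with 1–3 planted. The
  planted pair ranks first in every replicate. Note an analytical property
  of this regime: under the size-preserving null the shared count is
  hypergeometric with upper tail P(K ≥ 8) = `phyper(7, 50, 550, 50,
  lower.tail = FALSE)` ≈ 0.046, so the median empirical p concentrates near
  0.046 — detectably enriched in rank but not below the 0.01 stratum. Sets
  of 50 sharing 8 variants imply a Jaccard index of ~0.087, an order of
  magnitude above the published values (~0.008, implying a union of ~1,000
  variants for the largest pairs); at those union sizes the same 8-variant
  overlap is far in the tail. The acceptance suite asserts the 0.01
  threshold for this regime and the assertion is expected to fail; the
  package reports the measured median rather than tuning the regime to pass.
- **Determinism.** Same seed, byte-identical overlap tables and all three
  network export formats.

Sizes (R = 2,000–20,000, 100–200 replicates) were chosen so the full suite
completes in a few minutes on one CPU while keeping Monte-Carlo error well
below the tested margins.

## Known limitations

- The published numeric Jaccard values cannot be recomputed from the
  fixtures alone (the per-cancer set sizes behind them were not published);
  they are carried as data, not recomputed.
- The edge-swap null is a Markov chain: samples are exchangeable but not
  independent, and mixing is only empirically adequate on the small networks
  it is tested on here.
- VCF ingestion assigns one cancer type per file (VCF has no standard
  cancer-type field) and derives carriers from GT fields only.
- Positions are rCRS-fixed; no liftover from other mitochondrial references.
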