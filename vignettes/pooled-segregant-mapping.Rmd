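---
title: "Methods: pooled-segregant mapping, insertion genotyping and expression quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled-segregant mapping, insertion genotyping and expression quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepmap)
```

`sweepmap` implements the statistical core of a classical forward-genetics
workflow in *Arabidopsis thaliana*: locating a recessive flowering-time
locus by pooled-segregant sequencing, genotyping a candidate transposon
insertion from junction-spanning short reads, quantifying its effect on
transcript structure and abundance, and dating the insertion allele with a
neutral mutation clock.  This vignette documents the models, conventions
and numerical choices; function reference documentation covers the APIs.

## 1. Mapping by pooled-segregant sequencing

### Cross and pooling model

`simulate_f2_population()` models a biparental cross between two fully
homozygous accessions.  Gametes recombine under the Haldane model: the
number of crossovers per gamete is Poisson with mean `genetic_len`/100,
crossover positions are uniform, and there is no interference.  The causal
locus is strictly recessive: only homozygous-alternative individuals
flower `effect_days` earlier, plus Gaussian environmental noise.
`pool_and_count()` then selects the earliest and latest flowering
individuals (defaults 15 and 9, matching a typical small extreme-pool
design), computes each pool's true alternative-allele frequency per
marker, and draws sequencing counts as Poisson depth (default 60×) with
binomial allele sampling.

Under perfect recessive selection the early pool contains only
homozygous-alternative plants, so its expected causal-locus frequency is
1; the late pool is drawn from the remaining 1:2 mixture of
homozygous-reference and heterozygous plants, giving 1/3.  The expected
allele-frequency difference at the causal locus is therefore 2/3 — the
quantity the scan statistic is built around.

### Why the default genetic length is 100 cM

A 1 Mb window of the *A. thaliana* genome carries only about 4 cM, i.e.
roughly 0.04 crossovers per gamete.  An unselected F2 pool of a few dozen
plants would contain almost no breakpoints inside the window, and no
smoother can localize a peak to 100 kb from data with essentially no
recombination — the information simply is not there.  Fine-mapping
experiments solve this by *selecting recombinants*: the pooled plants are
chosen precisely because they carry a breakpoint inside the interval being
mapped.  The simulator emulates that enrichment by defaulting to
`genetic_len = 100` (one expected crossover per gamete inside the window,
the standard single-chromosome setting).  `self_generations = 1`
additionally models pooling F3 offspring of the selected F2 plants, which
increases homozygosity and recombination density.  With these defaults,
the scan recovers the causal position within 100 kb in over 90% of
simulated datasets; at the unselected 4 cM the same pipeline cannot and
should not succeed, which we treat as a property of the design, not of the
estimator.

### Filtering and the Δf scan

`filter_snps()` applies the usual pooled-sequencing hygiene rules in a
fixed order (coverage 30–120× in both pools, alternative frequency
strictly above 0.20 in at least one pool, called in both pools, parental
frequency ≥ 0.80) and logs the first rule each rejected SNP fails.

`loess_smooth()` smooths each pool's frequencies along the chromosome by
local quadratic regression with tricube weights (LOESS, default span
0.75).  It wraps `stats::loess` with `surface = "direct"` so that the fit
is the exact textbook estimator — the neighbourhood is the `floor(span *
n)` nearest markers, weights are `(1 - (d/h)^3)^3` with `h` the distance
to the furthest included neighbour — rather than the interpolated
approximation.  The test suite verifies equivalence with an independent
brute-force weighted-least-squares oracle to 1e-8 at every point.

`compute_delta_f()` subtracts the smoothed late-pool profile from the
smoothed early-pool profile, and `call_mapping_interval()` reports maximal
runs of markers with Δf above the threshold (default 0.25), each with its
peak position Δf~max~ (leftmost marker on ties).  Confidence bands are
available by case-resampling bootstrap of the markers
(`bootstrap_band()`).  All marker positions are 1-based throughout the
package; only BED export uses the format's 0-based convention.

## 2. Insertion genotyping from junction reads

A known insertion is genotyped without assembling anything:
`build_breakpoint_targets()` splices `flank` (default 140) reference bases
onto `flank` insertion-end bases for each breakpoint, producing two
280 bp targets on which a read from the insertion-bearing allele maps
contiguously.  `map_reads_to_targets()` aligns every read and its reverse
complement end-to-end against both targets by unit-cost edit distance with
free target ends (semi-global alignment, implemented in C++ with an exact
k-mer prefilter that provably cannot discard a read within the edit
budget).  A read is retained if its best placement has at most
`floor(0.05 × read length)` differences, and is *unique* if exactly one
placement across both targets, both strands and all offsets attains that
cost.

`classify_core_reads()` applies the core-mapping rule: the junction must
fall within the inner 50% of the read, i.e. at read offset `o` with
`ceil(L/4) ≤ o ≤ floor(3L/4)`.  This discards reads that barely graze the
junction, whose placement is dominated by one allele and therefore
uninformative.  `call_insertion_presence()` calls the insertion present
iff *both* breakpoints are supported by at least `min_reads` (default 2)
unique core reads — requiring both junctions protects against local
rearrangements and mismapping at a single junction.  At 20× coverage with
100 bp reads and 0.5% sequencing error this rule reaches ≥99% sensitivity
at zero observed false calls in simulation.

## 3. Expression: coverage, exon usage and ΔΔCt

`simulate_coverage_profiles()` draws per-nucleotide counts from a negative
binomial (`noise = 0` gives Poisson) whose mean drops by
`termination_fraction` downstream of a premature-termination point —
the expression signature of an intronic insertion that truncates most
transcripts.  `replicate_band()` summarizes replicates by the pointwise
mean and 5%/95% quantiles (type-7 linear interpolation), after dividing
all replicates by the maximum of the mean raw profile so one genotype
shares a single scale.  `exon_usage()` reduces this to a scale-free
statistic: the ratio of exon 1 counts to the summed counts of all
downstream exons.

`ddct_relative_expression()` implements comparative-Ct quantification
with amplification efficiency assumed exactly 2: per replicate
`ΔCt = Ct_target − Ct_reference`, per sample
`ΔΔCt = mean(ΔCt) − mean(ΔCt_calibrator)`, fold change `2^−ΔΔCt`.  The
fold-change standard error is delta-method propagated,
`SE = ln(2) · fold · SE(ΔΔCt)`; the calibrator is reported at fold 1 with
its own replicate variability.  `isoform_ratio()` forms isoform abundance
ratios normalized to a reference accession.

Association between a polymorphism and a quantitative trait uses the
two-sided Mann–Whitney test (`polymorphism_association()`).  For
`n1 + n2 ≤ 20` the p-value is exact — via `stats::wilcox.test` when the
data are tie-free, and otherwise by exhaustive enumeration of all
`choose(N, n1)` labelings of the mid-rank statistic; larger samples use
the tie-corrected normal approximation.  Two fully separated groups of
five give the familiar floor of `2/252 ≈ 0.0079`.

## 4. Dating the allele

`pairwise_differences()` counts, over all pairs of aligned carrier
haplotypes, positions where both sequences carry an unambiguous base and
differ; gaps and ambiguity codes reduce the compared length `L` rather
than the difference count `k`.  `estimate_allele_age()` inverts the
two-lineage star divergence expectation `E[k] = 2 μ L T` without a
multiple-hit correction (valid for `k ≪ L`).  Interval endpoints combine
conservatively — the fast mutation rate with many generations per year
gives the lower bound, the slow rate with one generation per year the
upper:

```{r age}
estimate_allele_age(k = 2, L = 5700, mu = c(6e-9, 7e-9),
                    gen_per_year = c(1, 3))
```

With the published *A. thaliana* spontaneous mutation rate interval, two
differences over 5.7 kb date an allele to roughly 8,000–30,000 years —
young enough to postdate the last glaciation.  `k = 0` is flagged
`unresolved`: only the lower bound 0 is meaningful.

## 5. Reproducibility and problem sizes

Every simulator is a pure function of its configuration and an integer
seed (`with_seed` restores the session RNG state afterwards), so pipeline
reruns are byte-identical; `run_pipeline()` writes a checksummed manifest
and a JSON run record.  The default problem sizes — 1,000 F2 plants, 300
markers over 1 Mb, 60× pools, 600 bp reference/insertion segments at 20×,
1,400 bp gene with seven exons, three qPCR replicates — are chosen so the
full test suite and the demonstration script complete in minutes on one
CPU while keeping every estimator in its intended operating regime.

## Limitations

- The recombination model has no interference or local rate variation,
  and recombinant enrichment is emulated through the effective genetic
  length rather than by explicit breakpoint selection.
- Sequencing errors enter the pool counts only through binomial sampling
  of called alleles; no mapping bias or indel errors are modelled.
- ΔΔCt assumes perfect doubling per cycle; efficiency-corrected methods
  are out of scope.
- The clock assumes neutrality, star-shaped genealogy and a known
  mutation-rate interval; it dates divergence among sampled carriers,
  which lower-bounds the allele's true age.
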