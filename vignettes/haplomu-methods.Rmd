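---
title: "Methods: de novo mutation rates from haploid pedigrees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: de novo mutation rates from haploid pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplomu)
```

## The estimator and its assumptions

The package estimates the spontaneous mutation rate from a pedigree in
which a diploid cross (sequenced through its two haploid parents) yields
`I` meiotic haploid progeny, each one generation (`g = 1` by default)
removed from the parental genotypes. The estimator is

$$\hat\mu = \frac{n}{G^* \times I \times g},$$

with `n` the number of accepted de novo mutations and `G*` the callable-site
total. Its validity rests on three assumptions:

1. **Counting is complete on callable sites.** A mutation at a callable
   site is detected with probability ~1 (the haploid genome shows it at
   100% allele fraction), and mutations at non-callable sites are excluded
   from both numerator and denominator, so the rate is unbiased rather than
   merely conservative.
2. **Mutations are rare and independent**, so `n` is Poisson with mean
   `µ G* I g`. Uncertainty uses the exact Garwood interval
   `[qchisq(α/2, 2n), qchisq(1−α/2, 2n+2)] / (2T)`; for `n = 0` the lower
   bound is 0 and the upper bound reduces to `−log(α/2)/T`. The interval is
   conservative (empirical coverage above the nominal 95%, typically
   96–98% at small means), which the test suite verifies by simulation.
3. **Minimal selection between meiosis and sequencing**, achieved
   experimentally by isolating progeny at a few-cell stage; the package
   takes this design as given.

## Callable-site schemes

Depths are integers, so a ">9×" coverage rule is implemented as
`min_depth = 10`. Two schemes are provided:

* **strict** (`callable_mask_strict()`): a position counts iff depth ≥
  `min_depth` in *every* required individual. `G*` is the number of
  callable positions; the exposure is `G* × I × g`.
* **quorum** (`callable_total_quorum()`): a position contributes whenever
  at least `k` individuals reach `min_depth`. Each position is weighted by
  its passing count `i`: `G* = Σ_{i ≥ k} i · N_i`, where `N_i` is the
  number of positions with exactly `i` passing individuals. Because each
  position already carries its own per-individual weight, the exposure is
  `G* × g` with no separate `× I` factor (`mutation_rate(..., I = 1)`).
  The unweighted count of distinct callable positions is reported alongside
  for callable-fraction statistics.

Positions are the unit of account. Internally both schemes run a
boundary-count sweep (tabulate interval starts and ends, cumulative-sum to
per-base counts) over run-length interval tracks; the test suite holds this
sweep equal to a naive per-base oracle on small genomes, and checks
monotonicity (raising `min_depth` or the quorum never increases `G*`) and
the strict/quorum correspondence at `k = `all individuals. Unplaced-contig
bins (a `Chr_00`-style concatenation) can be excluded by name everywhere.

## The haploid de novo filter

`find_denovo_candidates()` accepts a candidate iff, in this fixed order:

1. the position is **callable** (`not_callable` otherwise);
2. **exactly one progeny** carries any high-quality alternative read
   (`shared_carriers` otherwise — this reason also covers sites with no
   progeny carrier at all, such as parent-only variants or artifact sites
   whose only support is low-quality);
3. in that carrier the alternative allele is **100% of the coverage**
   (`partial_fraction`): any reference read in a haploid genome indicates
   somatic mosaicism. The carrier's denominator is its full reported depth,
   including any low-quality reads — the conservative reading;
4. **no other individual** — progeny, parent, or optional check
   individual — has any alternative read **even at low quality**
   (`alt_in_others`), the guard against repeat-driven mismapping. The
   low-quality alternative count is carried as its own integer field
   (`lq_alt_count`, the `LQA` FORMAT key on disk) precisely so this
   criterion can be applied after the fact.

Each site receives exactly one status and, if rejected, the first failing
reason, making reports deterministic. Multi-allelic sites need no explicit
decomposition: the long (site × individual) table keys candidates by
(chrom, pos, ref, alt), so criteria are per-allele by construction. SNVs
and short indels share identical logic. Structural candidates
(`filter_structural_candidates()`) add a fifth reason, `proximity`: a
candidate is vetoed when another individual shows a same-class variant
within `proximity_window` nt (default 1000 nt — the scale of SV breakpoint
uncertainty; clustered cross-individual calls mark locally unreliable
regions rather than de novo events).

`sensitivity_sweep()` re-runs acceptance with the fraction criterion
relaxed (e.g. ≥ 0.9 instead of = 1.0); on clean haploid data the count
must not grow, which is both a property test here and the published
robustness check.

## The synthetic pedigree generator

`simulate_pedigree()` emits the three artefacts the pipeline consumes —
variant table, coverage tracks, truth table — for a configurable pedigree.
The default configuration *is* the validation study design: a 1-Mb genome
in 20 equal chromosomes, 30 progeny, `µ_true = 1e-5`, mean depth 30×, 10%
dropout, 100 standing variants, somatic mosaics at 1e-6 per site per
progeny, repeat artifacts, sparse low-quality noise, and a 1/30
per-progeny probability of a whole-chromosome duplication. Choices worth
stating explicitly:

* **Depth is Poisson per 100-nt tile** (`depth_tile`), not per site. The
  pipeline consumes depth only through threshold crossings and window
  means, so tile-level draws preserve every behaviour that matters while
  keeping interval tracks compact; `depth_tile = 1` recovers fully
  independent per-site draws for small genomes.
* **Dropout blocks are shared across individuals**, emulating unmappable
  or repetitive regions. Independent per-individual dropout would shrink
  the 32-individual strict intersection to `0.9^32` ≈ 3% of the genome,
  which no real pedigree shows; shared blocks give the realistic ~90%
  callable fraction (real pedigrees report 58–83%).
* **Confounders are separable by construction**: somatic alternative
  counts are clamped strictly inside `(0, depth)`; standing variants
  always have a parent plus at least one progeny carrier; artifact sites
  carry only low-quality support in ≥ 2 individuals; and all special site
  classes (plus noise) occupy disjoint positions. False positives on
  synthetic data are therefore exactly zero when the filters are correct —
  the truth table is a strict oracle, and the test suite asserts zero
  accepted confounders over 200 replicate pedigrees.
* **One global seed** drives deterministic child seeds for each
  sub-generator; a fixed configuration reproduces byte-identical output.
  A reference genome may be shared across replicate pedigrees that differ
  only in seed, as repeated experiments on one organism would.

What the generator does *not* emulate — read-level errors and quality
scores, GC-coverage bias, recombination, selection during propagation,
structural variant calls — bounds what passing tests show: they validate
the accounting and filtering logic exactly, not the upstream caller's
behaviour on real reads.

## Spike-in false-negative simulation

`spike_mutations()` plants `n` mutations toward a target base (default G)
in one chromosome of the reference, on an even grid by default (the
deterministic choice; random placement is seed-controlled), recording
originals for exact reversal. `spike_variant_table()` emulates re-mapping
one individual against the spiked reference: the carrier shows the spiked
base at full local depth, everyone else shows reference only.
`evaluate_recovery()` then partitions spikes into recovered sites and
misses with causes (`non_callable`, or `filtered:<reason>`); recovered +
missed = spiked always, and on clean data every miss is `non_callable` —
the filters themselves introduce no false negatives at allele fraction 1.

## Duplication detection and dosage

`window_coverage()` tiles chromosomes with 5-kb windows (terminal windows
shorter) and computes length-weighted mean depth per window.
`detect_duplications()` forms, per chromosome, the ratio of the *median*
of its window depths to the median window depth of all other chromosomes.
Medians on both sides make the ratio robust to the duplicated chromosomes
themselves and to shared low-coverage stretches inside the tested
chromosome (a window-mean numerator under 10% dropout reads ~1.81 for a
truly doubled chromosome); `chrom_stat = "mean"` restores a plain mean
numerator. Thresholds: ratio ≥ 1.9 is `duplicated`, 1.5–1.9 is
`ambiguous` — a grey zone where an early, widely shared somatic event
cannot be excluded, flagged rather than silently dropped — and below 1.5
`normal`. Co-duplicated chromosomes in one individual count as a single
mis-segregation event in `wcd_rate()`; per-chromosome event counting is a
caller-side choice.

`dosage_ratio()` quantifies dosage (non-)compensation: genes are kept when
mean TPM exceeds `tpm_min` (default 1) in both strains; each gene's ratio
is mean test TPM over mean control TPM; the reported fold is the mean (or
median — the aggregation is configurable because either is defensible) of
those ratios over duplicated-chromosome genes divided by the same over
other genes. Multiplicative replicate noise biases both partitions
identically, so the fold is recovered without bias; the tests confirm
recovery of an injected 1.7 fold to within 0.05 under log-normal noise
(σ = 0.2, 500 genes, 20 replicate tables).

## Effective population size

`effective_population_size()` inverts `π_s = 4 Ne µ` using the unrounded
`n/T` rate; the Poisson interval on µ propagates to Ne (high µ bound →
low Ne bound). Values are indicative: demographic history can inflate or
deflate `π_s` relative to the neutral expectation.

## Problem sizes and numerical choices

The validation study uses 200 replicate pedigrees at the default
configuration for coverage-of-µ and false-positive checks, 2000 Poisson
draws for interval coverage, 100 spikes for FNR accounting, and
80-window chromosomes for duplication-ratio recovery — sizes at which every
stochastic assertion sits several standard errors from its threshold.
Degenerate inputs fail fast with the offending field named: zero callable
sites (undefined rate), empty quorum, single-chromosome duplication input
(no baseline), empty dosage partitions, mutation rates implying more than
one expected mutation per site. Ties and edge cases are fixed by
convention: depth thresholds are inclusive (`≥`), window boundaries are
0-based half-open, the terminal window is shorter, and rejection reasons
follow the fixed order above.

## Known limitations

* The generator's depth model has no GC or mappability structure, so
  callable fractions are more homogeneous than in real data.
* Structural variants are filtered but not simulated; the proximity veto
  is exercised on hand-built cases only.
* `evaluate_recovery()` matches spikes exactly on (chrom, pos, alt);
  near-miss matching (e.g. indel realignment drift) is out of scope.
* Ne estimates inherit every caveat of `π_s` as a neutrality proxy.
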