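---
title: "Models and methods behind rohsignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rohsignal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohsignal)
```

rohsignal analyses multi-population panels of bi-allelic SNP genotypes:
per-population diversity, population structure, runs of homozygosity (ROH)
and a selection-signature scan that intersects ROH sharing with
allele-frequency divergence. This vignette documents the statistical models,
the parameters that matter, the numerical choices, and what the bundled
synthetic-data generator does and does not emulate.

## The data model

Everything operates on a `genotype_matrix`: individuals × loci
alternate-allele dosages (0, 1, 2, or missing), locus metadata (chromosome,
1-based position, marker id, alleles) and sample metadata (id, population).
Phase is deliberately discarded at VCF import — no stage here uses it — and
half-called genotypes are treated as missing. Positions are 1-based
throughout (VCF convention); only the BED export converts to 0-based
half-open, so there is a single conversion point. Chromosome labels are
opaque strings: an autosome whitelist, not a naming convention, decides
what is analysed.

## Filtering

The post-variant filter chain runs in a fixed order: per-SNP call rate
(default ≥ 0.95), then per-individual call rate on the surviving loci
(default ≥ 0.80), then monomorphic removal (a locus is monomorphic when its
non-missing calls carry a single allele; missing calls are ignored
entirely), then LD pruning. SNP-before-individual is a choice, not a
theorem; the report records both counts so the order can be audited.

**LD pruning.** The LD measure is the squared Pearson correlation of
dosages over pairwise-complete individuals (`genotype_r2`); a locus
monomorphic within the comparison is assigned r² = 0, since a locus without
variance cannot be in LD. Pruning is a sequential greedy pass per
chromosome in position order: a locus is dropped when r² with *any*
retained locus among the preceding `window_snps − 1` retained positions
exceeds the threshold (defaults: 50-SNP window, r² > 0.2). Two properties
follow by construction: the later locus of an offending pair is always the
one removed (deterministic for a fixed input order), and the output passes
an exhaustive audit — no retained pair co-occurring in any placement of a
50-SNP window exceeds the threshold. The `step_snps` parameter is accepted
for interface compatibility with the common window/step parameterisation
but cannot change the result of the sequential formulation. Note this is
pairwise-r² pruning, not a variance-inflation-factor criterion.

## Diversity statistics

For a population with, at some locus, `n` callable allele copies of which a
fraction `p` are the alternate allele:

* **π (nucleotide diversity)**: `2 p (1 − p) n / (n − 1)` per locus — the
  probability that two copies drawn *without replacement* differ — averaged
  over loci with `n ≥ 2`. This small-sample correction makes the per-locus
  value exactly equal to the mean over all distinct copy pairs, which is
  how the test suite checks it (brute-force enumeration on toys up to 8
  diploids × 30 loci, agreement to 1e−12).
* **θ (Watterson)**: `S / (a · L)` with `S` the segregating-site count,
  `L` the loci with ≥ 2 callable copies, and `a` the harmonic number
  `Σ_{k<n} 1/k`. Missing data make `n` locus-specific; by default the
  *median* per-locus copy count sets the harmonic number (one global `a`,
  robust to a tail of low-call loci), with `per_locus_n = TRUE` available
  to weight each locus by its own harmonic number.
* **Raw difference π − θ** (`tajima_d_raw`): the unnormalised Tajima-style
  statistic. Negative values indicate an excess of rare variants (sweeps,
  expansion), positive an excess of intermediate frequencies (balancing
  selection, bottleneck recovery). The classical variance-normalised D is
  deliberately not computed: at these panel sizes the raw difference is
  what the accompanying χ² contrast tests. On samples drawn from the
  neutral site-frequency spectrum (allele count k with probability ∝ 1/k)
  the expectations of π and θ coincide, which the property tests exploit.
* **χ² contrast** (`pi_theta_chi2`): `(πL − θL)² / (θL)` against χ²₁. This
  is this package's own construction of a one-degree contrast on the
  locus-summed scale, and its outputs are labelled as such.
* **He**: per individual, the heterozygous fraction of its non-missing
  calls, scaled by `nsnps / ntotal`; the population value is the mean over
  individuals. `ntotal` defaults to `nsnps`, making the scale factor 1 — a
  genome length can be supplied when He should be discounted by the
  fraction of the genome the panel covers.
* **MAF**: `min(p, 1 − p)`, hence bounded by 0.5. Because panels are
  sometimes summarised on other scales, the mean alternate-allele and mean
  major-allele frequencies are emitted alongside.
* **Private alleles**: counts of (locus, allele) pairs observed in exactly
  one population, plus a per-SNP rate (count / loci).

## Population structure

**AMOVA.** A three-level decomposition — among populations, among
individuals within populations, within individuals — computed from
allele-copy sums of squares per locus and summed over loci. Working at the
allele level (each called genotype contributes two copies; a heterozygote's
copies differ) is what makes the within-individual stratum well-defined.
Variance components follow the standard nested-ANOVA expectations with the
usual unequal-size correction `n_c`; percentages may involve negative
components and are reported as computed. Significance of the
among-population component comes from permuting individuals across
populations; p-values use the `(exceedances + 1)/(n_perm + 1)` correction,
so p is never exactly zero and its resolution is bounded by the number of
permutations (on very small panels, distinct permutations are few and the
attainable minimum p is correspondingly coarse). Total and within-individual
sums of squares are permutation-invariant, which the implementation
exploits for speed.

**Fst.** Per-locus Weir–Cockerham (1984) variance components for any
number of populations; genome-wide and pairwise values combine loci as a
ratio of sums (Σ numerators / Σ denominators), the combination that
downweights low-information loci. Pairwise confidence intervals come from
a seeded bootstrap over loci (default 1000 resamples, percentile
intervals); the same seed is bit-reproducible. The
finite-sample-*uncorrected* variant of the estimator is carried separately
per locus because the neutral-distribution fit below requires the
uncorrected scale.

**Distances, trees, ordination.** Euclidean distances are computed between
population allele-frequency vectors over loci callable in both populations.
Neighbor-joining uses the Saitou–Nei algorithm (via ape); negative branch
lengths, a finite-sample artifact, are clamped to zero with the deficit
pushed onto adjacent branches. PCoA is classical scaling (eigendecomposition
of the double-centred −d²/2 matrix); all eigenvalues are reported in
descending order, axes with non-positive eigenvalues are excluded from the
coordinates, and when the input is Euclidean-embeddable the full-rank
coordinates reproduce the input distances (checked to 1e−9 in tests).

## Runs of homozygosity

The scanner is window-based. Per individual and chromosome, a window of
`window_snps` consecutive SNPs slides one SNP at a time; a window is
*homozygous* if it contains at most `window_het` heterozygous and at most
`window_missing` missing calls. Each SNP's hit fraction is the proportion
of windows covering it that are homozygous; SNPs at or above
`window_threshold` are ROH-eligible. Maximal runs of eligible,
non-heterozygous SNPs become segments (missing calls may sit inside a run),
split where the inter-SNP gap exceeds `max_gap_kb`, and filtered by
`min_snps_per_segment` and `min_length_kb`. Defaults: 50 / 1 / 5 / 0.05 /
1000 kb / 50 SNPs / 1000 kb.

Numerical and boundary choices:

* Chromosomes shorter than the window are scanned with a single truncated
  window (logged), so every SNP is covered by ≥ 1 window.
* Segment coordinates are the first and last SNP positions of the run, not
  window bounds.
* A segment-density bound (`max_density_kb_per_snp`) exists but is
  *disabled by default*: at reduced-representation densities of tens of kb
  per SNP, any fixed per-50-kb density rule would reject every segment.
* The window mechanics imply an intrinsic edge erosion: the outermost SNP
  of a true homozygous tract in a heterozygous background is covered by
  only ~2 homozygous windows of ~50, falling below a 5% threshold, so
  detected bounds sit within one window span of the truth. The recovery
  tests assert exactly this bound.
* Scan parameters should scale with panel density: for sparse panels
  (e.g. ~40 kb/SNP and islands of ~20 SNPs) a 50-SNP window can never be
  homozygous across a short island, and a scaled parameterisation
  (window 20, min 20 SNPs / 500 kb) is the appropriate configuration. All
  parameters are exposed in `roh_params()` for this reason.

**F_ROH** is total segment length divided by `genome_size_bp` (default
930,820,000 bp, a chicken-autosome total; set it to your genome).
Overlapping segments within an individual are treated as an error — the
scanner cannot produce them, so they indicate a corrupted segment table.
**ROH incidence** counts, per locus, the individuals whose segments cover
it, as a percentage of *all* individuals in the dataset (a per-population
denominator is a trivial re-aggregation of the per-sample table).
**Islands** are the loci at or above the `1 − top_fraction` incidence
quantile, ties included — with constant incidence every locus ties and all
are returned, which is the documented behaviour, not an edge-case bug.

## Selection scan

Per-locus multi-population Weir–Cockerham Fst is computed together with its
uncorrected variant and the pooled-frequency expected heterozygosity. The
neutral model is a scaled chi-square: `Fst_nocorr · df / F̄st ~ χ²_df`. The
fit excludes loci with pooled heterozygosity below `het_min` (default 0.1;
low-het loci have unstable ratio estimates), trims `trim_fraction`
(default 0.05) from each tail of the remaining Fst distribution, and
maximises the likelihood of the *truncated* scaled-χ² density between the
empirical trim bounds over (df, F̄st) — truncating the likelihood rather
than ignoring the trimming is what keeps the fit unbiased, which the
recovery test checks (df within ±15%, F̄st within ±10% at 20,000 loci).
Optimisation is Nelder–Mead on log-parameters, initialised from the
moment estimates `df₀ = 2 x̄²/s²`, `F̄st₀ = x̄`; non-convergence and
zero-spread inputs are errors, not warnings. P-values are the right tail
`P(χ²_df ≥ fst · df / F̄st)` — this scan looks for *high*-Fst outliers
only — with non-positive Fst bounded at p = 1.

Signatures are the intersection of the top 1% smallest p-values with the
top 5% highest ROH incidences. Both selections use the same
quantile-threshold rule with ties included, so the selected count can
exceed the nominal fraction when ties straddle the threshold; the rule is
deterministic and documented rather than tuned to reproduce any particular
count. Annotation is strictly local: features come from a BED/GFF file via
rtracklayer, overlaps within ±`window_kb` and the nearest feature with its
distance are attached per signature.

## The synthetic generator

`sim_config()` defaults describe the panel the analysis workflow targets:
11 populations with sizes (8, 13, 12, 10, 11, 10, 6, 12, 11, 16, 10) —
119 diploids — and 12,000 loci spread over 28 autosomes rescaled to a
930.82 Mb total; Balding–Nichols divergence parameters spanning 0.15–0.60
with the inbred-line-like populations most diverged; F_ROH targets from
0.02 (an outbred, diverse population) to 0.35 (an inbred line); 3% missing
calls; and 10 planted loci at 5× divergence, each centred in a 60-locus
island forced homozygous in half the individuals. These values were fixed
once, as a realistic livestock-panel scenario, before being used in tests.

Mechanics and their rationale:

* **Frequencies**: ancestral p ~ Uniform(0.05, 0.95); population
  frequencies Beta(p(1−F)/F, (1−p)(1−F)/F). Balding–Nichols is the minimal
  model with a direct Fst parameter, which is exactly what estimator
  recovery tests need; a coalescent simulator would add realism the tests
  do not consume. With F = 0 the population sits at the ancestral
  frequency; outlier loci multiply F (capped at 0.95).
* **Genotypes**: Hardy–Weinberg draws. With `ld_rho > 0` each haplotype is
  a Gaussian copula with AR(1) correlation along the chromosome, giving LD
  that decays with locus distance while preserving per-locus frequencies —
  enough structure for the pruning and LD-decay stages to have non-trivial
  input.
* **ROH implantation**: per individual, disjoint tracts (lengths uniform in
  `roh_interval_mb`, the last tract clipped so the total matches the
  target fraction exactly) are forced homozygous, heterozygotes resolved
  by a fair coin so allele frequencies are preserved in expectation.
  Implantation by forcing homozygosity, rather than by pedigree
  simulation, yields exact truth intervals for boundary-accuracy tests.
  Island intervals are likewise forced homozygous in a random
  `carrier_fraction` subset of all individuals.
* **Determinism**: every stage draws from a sub-seed derived from the
  config seed and a stage name; `generate_dataset()` is byte-reproducible.

What the generator does *not* emulate — and therefore what passing tests do
not establish about real data: realistic demography or site-frequency
spectra (frequencies are uniform-ancestral, so π > θ systematically),
recombination-map structure (LD decays with SNP index, not map distance),
identity-by-descent ROH (implanted tracts alternate homozygous classes
freely, which real IBD does not), genotyping error, and allele-dropout
patterns typical of reduced-representation libraries. The tests establish
estimator correctness under a controlled model, not robustness to
real-data artefacts.

## Pipeline, seeds and problem sizes

`run_pipeline()` wires the stages in a fixed order (input/simulate →
filter → diversity → structure → ROH → LD decay → selection scan), writes
every table as TSV (trees as Newick, provenance as JSON) and rejects
unknown configuration keys. One global seed feeds named substreams
(simulation, Fst bootstrap, AMOVA permutations), so reruns are identical
and stages remain pure functions of (input, config, seed).

The test suite sizes its simulations to what the checks need rather than
the largest panel the code can handle: oracle comparisons run on toys
(≤ 8 diploids × ≤ 30 loci), estimator recovery on 2 × 50 diploids × 5000
loci, neutral-fit recovery on 20,000 loci, the end-to-end dual-signal scan
on 11 populations × 10 diploids × 5000 loci × 10 replicates, and the
full-pipeline smoke test at the default study scale (119 × 12,000), which
completes in about two minutes on one CPU.
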