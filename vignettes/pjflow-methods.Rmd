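---
title: "pjflow methods: models, parameters, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pjflow methods: models, parameters, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

# Scope

`pjflow` analyses paired tumor/normal exome sequencing of pancreatic juice
cell-free DNA (PJD) from patients with intraductal papillary mucinous
neoplasms (IPMN). Malignancy signal is read out two ways: somatic mutation
burden (and its correlation with histological grade, ordered
LGD < HGD < INC) and recurrent somatic copy-number alterations. Because
protected patient data cannot ship with a package, every stage is exercised
against a seeded synthetic-cohort generator whose defaults emulate the
study conditions the pipeline was designed for. This vignette documents
the statistical model of each stage, the default parameters, what the
generator does and does not emulate, and the numerical choices that make
results reproducible to the digit.

# The synthetic cohort generator

`simulateCohort(CohortConfig(...))` produces a `PJCohort`: per-sample
paired pileups, a truth set of somatic events, true segment profiles, a
bundled reference sequence, target intervals, and binned read depths.

## Cohort composition and mutation burden

Defaults mirror a 39-patient cohort: `nSamplesPerGrade = c(LGD = 8, HGD =
20, INC = 11)`. Per-sample somatic burden is drawn from a negative
binomial whose median is calibrated per grade
(`burdenMedianByGrade = c(16, 19.5, 64)`, dispersion 8): the NB size/mu
parameterisation is inverted numerically with `qnbinom` so that the
*median* (not the mean) of the generating distribution matches the target,
because burden medians are the quantity the downstream Spearman statistic
summarises. Burden increasing with grade is therefore a property of the
defaults, not of any individual seed.

## Reads, purity, and cell-free dilution

Tumor-derived DNA fraction (purity) is Beta-distributed with mean 0.334.
Each true event carries a cellular fraction: clonal (cf = 1) with
probability 0.7, otherwise uniform on [0.3, 1). The expected tumor VAF of
a heterozygous event is `purity * cf / 2`. Site read counts are Poisson
around mean depths 168 (tumor) and 112 (normal); each read carries base
and mapping qualities, and non-variant reads are corrupted to a random
other base with probability `seqError = 1e-3`, so the caller's filters are
exercised against realistic noise. Null (non-somatic) sites and
off-target sites are included so that specificity is measurable.

## Copy-number truth and bin depths

True segment profiles assign integer log2 shifts (+1 amplification, -1
deletion) to region profiles with per-grade prevalences. Bin-level tumor
counts are Poisson with mean `depth * width / 100 * 2^(shift + e)`,
`e ~ N(0, binNoiseSd)`, i.e. read counts at a 100 bp read length. The
denominator matters: bins aggregate enough reads that Poisson counting
noise stays well below the configured `binNoiseSd = 0.1`, so the noise
parameter actually controls the bin-level log2 noise it claims to.
"Noisy" samples (4 by default, emulating samples excluded for copy-ratio
instability) inflate `binNoiseSd` five-fold.

## Artifact injection

`injectOxoG()` plants 8-oxoguanine-style artifacts into 3 samples by
default: 150 C>A events per sample on the strand where the reference
context is 5'-CC(N)-3' (appearing as G>T on the opposite strand), with
VAFs around 0.05. Artifact events are flagged in the truth set and have
no cellular fraction.

## What the generator does not emulate

Reads are exchangeable count draws, not alignments: there is no mappability
structure, GC bias, strand bias beyond the OxoG injection, germline
contamination, or FFPE deamination. Indels are represented only as
multi-base alleles in the truth set. The reference is a small random
sequence (4 chromosomes of 300 kb by default), so genomic coordinates are
illustrative. Conclusions about the pipeline's behaviour on real exomes
should treat the generator as a unit-test harness, not a sequencing
simulator.

# Somatic calling

`callSample()` aggregates pileup reads per site and allele (after dropping
reads below base quality 20 / mapping quality 30), picks the best-supported
non-reference allele, and applies filters in a fixed precedence order, each
site receiving the *first* failing label: `depth_fail` (tumor or normal
depth < 8), `min_variant_reads_fail` (< 3 tumor variant reads),
`tumor_af_fail` (tumor VAF < 0.05), `normal_af_fail` (normal VAF > 0.1),
`fisher_fail` (one-sided Fisher exact p > 0.05), else `PASS`. The Fisher
tail is computed directly from the hypergeometric distribution
(`phyper`), one-sided in the direction of tumor alt enrichment, which
matches the directional nature of somatic calling; a two-sided variant is
available. The fixed precedence makes filter strings deterministic and
testable.

# OxoG artifact sample QC

`buildSpectrum()` counts PASS SNVs into the 96 pyrimidine-collapsed
trinucleotide bins. Three per-sample evidences (`oxogEvidence()`) feed
`flagOxoGSamples()`:

* median VAF of PASS SNVs (contamination skews low),
* oxidation score: fraction of PASS SNVs that are C>A in CC(N) context
  (either strand),
* spectrum signature score: fraction of spectrum mass in the `C[C>A]N`
  bins.

Flagging is cohort-relative: evidence (a) fires below
`median - k * MAD`, (b)/(c) above `median + k * s` with `k = 3` and the
sample excluded when at least 2 of 3 evidences fire. For the two fraction
scores, `s = max(MAD, minSpread, sqrt(m(1-m)/n_pass))` with
`minSpread = 0.05`: the cohort MAD of small-count binomial fractions can
collapse to zero (many identical values) or far below the per-sample
sampling noise, so the threshold is floored both absolutely and by each
sample's binomial standard error at the cohort median `m`. A sample with
11 PASS calls needs roughly 2/11 more chance C>A events than the median to
fire, which the binomial floor correctly treats as unremarkable, while an
injected sample with a ~0.5+ oxidation score fires regardless. A sample
with zero PASS calls carries no fraction evidence.

# Copy-number pipeline

`makeBins()` partitions target intervals into bins of at most 100 kb that
never span targets. `computeCopyRatios()` forms
`log2((t_i / T) / (n_i / N))` with library-size normalisation, returning
`NA` where either count is zero.

`cbsSegment()` is circular binary segmentation: the maximal |t| over
circular arcs (with segment-global variance, precomputed so the statistic
is permutation-invariant), an early-stopping permutation test at
`alpha = 0.01`, and recursion on accepted splits. `undoSplits()` then
iteratively merges (smallest difference first) adjacent segments whose
means differ by less than 3 times the pooled per-bin residual SD of the
initial fit. Note the interaction documented here deliberately: this undo
rule compares a difference of *segment means* against a *per-bin* SD, so
any event whose observed amplitude is below ~3 noise-SD can be erased even
when the permutation test detected it overwhelmingly. With integer log2
truth shifts (amplitude 1.0) and bin noise ~0.1 the rule is safe by a wide
margin; users running data with substantially higher bin noise or diluted
event amplitudes should lower `sdMultiplier` consciously.

`filterOfftargetAndRefuse()` removes segments with no target overlap and
re-fuses adjacent segments with equal (within 1e-9) means; it is
idempotent. Segment states are `amp` / `del` when the mean log2 ratio
strictly exceeds +0.2 / falls below -0.2.

`residualVariance()` is the mean squared deviation of bin log2 ratios from
their segment means, computed over on-target bins only (off-target bins
are sparse and would dominate through counting noise alone).
`residualVarianceQC()` excludes samples above `cohort median + 3 * MAD`
(an absolute cutoff is available). Because residual variance across
samples is approximately a scaled chi-square statistic, a 3-MAD rule
retains an irreducible per-sample false-flag probability of roughly
0.002; on a 35-clean-sample cohort, perfect exclusion in every replicate
is therefore not attainable by this rule, which is a property worth
knowing before treating a single flagged sample as pathological.

# Recurrent regions

`markerMatrix()` maps per-sample segment means onto on-target bin
midpoints (uncovered markers contribute 0). The G-score per marker and
direction is a sum over samples of capped exceedances:
`sum(max(0, min(x, 2) - 0.2))` for amplifications and symmetrically for
deletions; the cap guards against single-sample outliers. The null
preserves each sample's marker autocorrelation by cyclically shifting its
marker vector by an independent random offset; observed G-scores are
compared with the pooled null (all markers, all permutations) for
empirical p-values, BH-adjusted across markers. Regions are maximal runs
of markers with q < 0.25 within a chromosome (regions never span
chromosomes); the wide interval extends the peak until G drops below the
0.90 quantile of the null's per-permutation maxima.

# Cohort statistics

* `estimateTumorFraction()`: twice the median PASS VAF, clipped to [0, 1],
  defined only when a sample has more than 10 PASS calls (`NA` otherwise);
  the doubling inverts the heterozygous-diploid VAF expectation.
* `spearmanBurdenGrade()`: Spearman rho on mid-ranks; p-value from the
  t approximation for n >= 10 and from exact permutation enumeration below
  that, where the approximation is unreliable.
* `fisherExact2xK()`: Freeman-Halton exact test by recursive enumeration
  of tables with fixed margins; switches to an `r2dtable` Monte-Carlo
  estimate (with reported standard error) when the enumeration would
  exceed `maxEnum` tables. Probability-ordering comparisons use a
  `1 + 1e-7` relative slack, the conventional guard against float ties.
* `regionGradeAssociation()`: per-region 2xK tests of altered/not against
  grade, with per-grade percentages reported under half-up decimal
  rounding (`roundHalfUp()`), because banker's rounding in base `round()`
  does not reproduce conventionally printed percentages such as 43.75.

# Numerical and reproducibility choices

* All hypergeometric/Fisher tails come from `phyper`/`dhyper` log-space
  routines rather than factorial ratios.
* Every stochastic entry point takes a seed; `runPipeline()` and
  `scripts/acceptance.R` derive all sub-seeds from a single integer, and
  derived seeds stay below 2^31.
* Half-up rounding is implemented as
  `trunc(abs(x) * 10^d + 0.5) / 10^d * sign(x)` on top of a tiny relative
  epsilon to absorb binary representation error just below .5 boundaries.
* Fixture I/O (`writeFixture()`/`readFixture()`) round-trips cohorts
  byte-identically; floating point fields are serialised at `%.17g`.

# Limitations

* The caller handles the best-supported alternate allele per site;
  multi-allelic sites yield a single call.
* Consequence classes in synthetic truth are labels, not annotations
  derived from a transcript model.
* The permutation null for recurrence pools markers across chromosomes of
  unequal marker counts; with very few markers per chromosome the
  empirical p resolution is limited by `nPerm`.
* QC rules are cohort-relative and assume a majority of unremarkable
  samples; they are not calibrated for cohorts where most samples are
  pathological.
* The generator's noise model (Poisson counts, Gaussian bin noise) is a
  deliberate simplification; see the generator section for the list of
  unmodelled artefacts.
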