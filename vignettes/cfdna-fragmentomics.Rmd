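---
title: "cfDNA fragmentomics with cfFrag: models, methods and design choices"
author: "cfFrag authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cfDNA fragmentomics with cfFrag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfFrag)
```

# The biological model

Circulating cell-free DNA is produced by a stepwise digestion of
chromatin during apoptosis. Intracellular nucleases cut between
nucleosomes, producing a ladder of fragment sizes at multiples of the
nucleosomal unit (a predominant mono-nucleosome peak near 167 bp in
healthy human plasma, with di-, tri- and tetra-nucleosome peaks near 333,
527 and 719 bp). Extracellular nucleases then nibble the DNA wrapped
around the histone core, producing a family of sub-nucleosomal fragments
whose sizes oscillate with a ~10-bp period (the helical pitch of DNA on
the nucleosome) below the mono mode, and they cut preferentially before
cytosine, so the 5' ends of circulating fragments are C-enriched relative
to the genome. Cancer shifts both features: more sub-nucleosomal
fragments, weaker C-end preference.

cfFrag treats these three signatures — ladder, sub-nucleosomal
oscillation, end-base preference — as measurable parameters, provides
detectors and summary statistics for each, and pairs them with a
generative simulator whose presets encode published profile values so
that every stage can be checked by parameter recovery.

# The generative model (`SimPreset`, `simulateFragments`)

A fragment population is described by:

* `nucWeights` — mixture weights of the mono/di/tri/tetra components
  (healthy human: 85.0/12.1/2.3/0.4 %; as printed these sum to 0.998, and
  the constructor renormalizes rounded simplexes within 0.005 of 1);
* `nucModes` (bp) — modal sizes, e.g. 167/333/527/719 (human) or
  163/362/547/728 (dog);
* `nucSds` (bp) — component spreads, defaults 6/15/20/25. The mono spread
  reproduces a sharp mode with shoulders; the higher orders broaden with
  order as additional linker cut positions accumulate;
* `subpeakPositions` (bp) and `subpeakWeight` — the sub-nucleosomal
  ladder (human: 50, 60, 70, 81, 91, 102, 111, 122, 134, 153 bp) and the
  probability that a mono-class fragment falls on it. The default weight
  0.15 produces per-rung ±1 bp ratios of order 1 %, the order of
  magnitude of healthy cohort peak ratios, while keeping the mono mode
  clearly dominant; the cancer preset doubles it;
* `subpeakJitterSd` (bp, default 1.0) — spread around each rung, keeping
  rungs sharp enough to stand out at 10-bp spacing;
* `endBaseProbs` — the distribution of the first base at the 5' ends
  (A/T/C/G order; healthy human 0.188/0.233/0.359/0.220);
* `genomeBaseProbs` — the base composition of the synthetic reference
  (human-like 0.295/0.296/0.204/0.205 by default).

Sampling proceeds per fragment: nucleosome order from `nucWeights`; a
length from the order's component (for the mono component, a discretized
Gaussian truncated to `[floor, mode + 40]`); two 5'-end target bases
drawn independently from `endBaseProbs` (one per strand of the
double-stranded molecule); a uniform strand label; and a position found
by rejection sampling until the reference base at the left coordinate
equals the Watson target and the complement of the base at the right
coordinate equals the Crick target.

Design notes:

* **Both ends are controlled.** End-motif analysis tallies both 5' ends
  of every fragment, so the simulator draws an independent end base for
  each; controlling only one end would dilute the observed end
  preference toward the genome composition by half.
* **Rejection on a composition-controlled reference**, rather than
  biasing the reference itself, keeps genome composition and end
  preference independently tunable — mirroring the contrast between
  reference composition (~20 % C) and fragment ends (~36 % C) seen in
  real data. The acceptance probability per try is
  `sum(endBaseProbs * genomeBaseProbs)` squared-ish (both ends), about
  6 % for the human preset, so placement costs ~17 uniform draws per
  fragment, vectorized.
* **Mono truncation floor.** With a subpeak ladder present, the mono
  Gaussian is truncated below at `max(subpeakPositions) + 8` bp so the
  highest rung remains a local maximum within the subpeak detection
  window; without a ladder the floor is `mode − 40`. The ceiling
  `mode + 40` bounds the supra-modal shoulder.
* **Seeding.** One `set.seed()` call followed by vectorized draws:
  identical `(preset, n, reference, seed)` give byte-identical BED
  output. (A counter-based per-fragment stream would additionally make
  prefixes stable under changes of `n`, but R has no counter-based
  generator without adding dependencies, and the determinism contract
  does not need it.)
* **Degenerate inputs** are defined, not errors: `n = 0` gives an empty
  set; zero spreads give point masses; an end base that does not occur
  in the reference raises a simulation error naming the base.

What the generator does *not* emulate: sequencing error, GC and
mappability bias, duplicate reads, tumor-fraction mixtures, chromatin
position effects (fragments are placed uniformly where the end bases
match), the C-enrichment at the *second* motif position seen in real
data (only the position-1 marginal is controlled), and any 8-mer motif
structure beyond that marginal. Passing recovery tests therefore
demonstrates the correctness of the measurement code, not robustness of
the statistics to those real-data artifacts.

The HL60 cell-line presets pin the published end-base distributions and
the presence (supernatant) or absence (pellet) of the sub-nucleosomal
ladder; their mixture weights and modal sizes are package choices
(modes 167/360/540/720 bp; pellet weights 45/30/16/9 % for a prominent
multi-nucleosomal ladder, supernatant 80/15/4/1 % for a plasma-like,
extracellularly digested profile).

# Reading real fragments (`readFragmentsBam`, `readFragmentsBed`)

From BAM, one fragment is emitted per *proper* read pair (SAM flag 0x2;
outer-coordinate span is only meaningful for concordant pairs), spanning
the outer mapped coordinates — equal to |TLEN| for proper pairs. Pairs
are dropped when either mate's MAPQ is below 30 (the conventional
cfDNA-quality cutoff, configurable) or carries the duplicate flag;
secondary/supplementary alignments are never used; orphan records are
skipped and counted in the provenance. The duplicate flag is trusted
(marked upstream by the usual tools); an optional coordinate-based
de-duplication exists for flag-less inputs, off by default. Soft-clipped
bases are outside the mapped coordinates and therefore excluded. All
contigs are retained. Internally coordinates are 1-based closed
(`GRanges` convention); BED output/input is 0-based half-open, so
fragment length is `width()` = BED `end − start` throughout.

# Size-profile analysis

`sizeHistogram()` tallies lengths into 1-bp bins on [30, 800] bp
(spanning the tetra peak with margin); out-of-range fragments are
excluded from counts *and* total, so `peakRatio()` — the ±1 bp windowed
count fraction — is exactly the published peak-amplitude proxy.

**Smoothing.** All peak detection runs on a centered 3-bp moving average
of the frequency: wide enough to suppress single-bin noise, narrow enough
to preserve 10-bp periodicity. Edges average the available bins.

**Tie-breaks.** A run of equal smoothed values that jointly exceeds its
neighbours is one maximum, placed at the highest raw frequency within the
run (3-bp smoothing flattens an isolated spike into a 3-bin plateau;
the raw profile disambiguates), remaining ties going to the lower size —
so detection is fully deterministic.

**Major peaks** (`findMajorPeaks`). The nucleosomal ladder is searched
upward from the predominant mode: the global maximum of the smoothed
profile is taken first, then the strongest local maxima at larger sizes,
greedily, with ≥100 bp pairwise separation, up to four peaks.
(Plain greedy-by-height selection would occasionally prefer a tall,
narrow sub-nucleosomal rung to the low, broad tetra-nucleosome peak;
structure below the predominant mode is by definition sub-nucleosomal
and is `findSubpeaks()`' territory.) Each peak position is then refined
by a count-weighted quadratic fit to the log-counts in a window scaled
to the peak's half-height width (1.5 estimated sigma), with one pass of
gross-outlier rejection (|log residual| > 2). A discretized Gaussian
component is exactly quadratic in log scale — truncation only removes
points — so the fitted vertex estimates the mode with near-parametric
efficiency: the tetra peak (0.4 % of fragments, sd 25 bp) is localized
to a fraction of a bp from 10^6 fragments, where a bin-argmax scatters
by several bp because the smoothed apex is flat relative to Poisson
noise. The raw local-maximum bin is reported alongside the refined
position, and `refine = FALSE` disables the fit.

**Subpeaks** (`findSubpeaks`). Strict local maxima of the smoothed
frequency within 40–160 bp; a maximum closer than 8 bp (just under the
10-bp period) to a larger retained maximum is suppressed. A flat or
empty window returns zero rows.

**Nucleosome proportions.** Cut points 250/450/650 bp with an 800 bp
ceiling sit in the valleys between ladder peaks; they are configurable
because published class proportions do not come with stated cut points,
and the cuts are the only free choice in that statistic.

# End-motif analysis

Motifs are read from the *reference* at the fragment coordinates (not
from read bases): the Watson end motif is `ref[start .. start+k−1]`, the
Crick end motif the reverse complement of `ref[end−k+1 .. end]`, with
k = 8. Both ends of every fragment are tallied by default
(`bothEnds = FALSE` restricts to the strand-designated end). Motifs
containing ambiguity codes or running off a contig are skipped and
counted. Lowercase (soft-masked) bases are uppercased. Base order is
A, T, C, G everywhere in the package. `cEndBySize()` stratifies the
position-1 C fraction by exact fragment length over 50–250 bp (the first
major peak); sizes with no ends are absent from the table rather than
zero. When a single per-sample or per-cohort C-end number is needed, the
end-count-weighted mean across sizes (the pooled C fraction) is the
stable estimator — the unweighted mean over occupied sizes is dominated
by sparsely populated tail sizes.

# Cohort statistics

Per-sample features are the ±1 bp ratios at eleven *fixed* canonical
positions (50, 60, 70, 81, 91, 102, 111, 122, 134, 144, 153 bp) — fixed
rather than re-detected per sample so that samples are comparable — plus
the per-size C-end table. A ten-position variant omitting 144 bp (a
plateau rather than a peak in the healthy human profile) is available
via `canonicalPeakPositions("ten")`.

Peak ratios are compared per position with a two-sided Mann–Whitney
U test: exact null when the combined sample size is ≤ 20 and tie-free,
otherwise the normal approximation with tie-corrected variance (and no
continuity correction, so fully tied data gives exactly p = 1). The
reported U counts cross-group pairs `a > b` plus half the ties — the
standard U of the first sample, zero when every value in A lies below
every value in B. Benjamini–Hochberg adjustment is applied across the
positions and both raw and adjusted p-values are reported, since
published per-peak significance stars typically do not state an
adjustment. Groups need ≥ 3 samples (the rank-sum test is degenerate
below that).

C-end preference is compared, by default, pairing on fragment size: the
group means of the per-sample C-end fractions are paired per shared size
and a two-sided paired t-test runs across sizes — mirroring how per-size
C-end distributions are displayed and tested in cohort figures. The
alternative `per_sample` mode collapses each sample to its weighted mean
C fraction and applies an unpaired Welch test; it is the right mode when
samples, not sizes, are the exchangeable unit. Zero-variance differences
are guarded (p = 1 for identical groups, p = 0 for a constant non-zero
shift, with a warning) rather than erroring inside `t.test`.

# Validation strategy and problem sizes

The package is validated at three levels:

1. **Exact oracles** — the U statistic against exhaustive pair
   enumeration, peak ratios against direct window tallies, the subpeak
   detector against the closed-form maxima of a 10-bp cosine profile,
   paired t against its closed form, motif extraction against hand
   reverse-complemented examples.
2. **Parameter recovery** — 10^6-fragment simulations per preset must
   return the preset's nucleosome proportions to ±0.5 percentage points,
   ladder peak positions to ±2 bp, subpeak positions to ±1 bp, and
   end-base proportions to ±0.4–0.5 percentage points. These margins are
   several sampling standard deviations wide at that depth.
3. **Statistical calibration** — 200 same-preset 5-vs-5 comparisons
   (5,000 fragments per sample) keep the rank-sum type-I error at
   α = 0.05 within 0.02–0.08; a 20-vs-20 healthy-vs-cancer cohort at
   10^5 fragments per sample must separate at the ladder rungs
   (BH-adjusted p < 0.01, cancer above healthy) and in C-end preference
   (paired p < 0.001, healthy above cancer).

The simulation depths (10^6 fragments for recovery, 10^5 per cohort
sample, 2 Mb test references / 5 Mb in the acceptance script) were chosen
so that sampling error is far inside the tolerances while a full
validation run completes in minutes on a single core.

# Known limitations

* Uniform fragment placement: no nucleosome-positioning or chromatin
  structure along the genome, so per-region analyses are out of scope.
* Only the position-1 end-base marginal is modeled and only position-1
  content is reported; CCNN-type 4-mer diversity metrics are not
  computed.
* The mono/di/tri/tetra decomposition depends on the (configurable)
  valley cut points; published proportions do not state theirs.
* The cancer preset is a stylized contrast (doubled sub-nucleosomal
  weight, C-end 0.30) intended for power and direction checks of the
  cohort statistics, not a calibrated tumor-fraction model.
* No Fourier/autocorrelation periodicity estimation and no mixture-model
  deconvolution of overlapping ladder components; detectors operate on
  the smoothed histogram directly.
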