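---
title: "Calling chromatin modules from peak-density profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling chromatin modules from peak-density profiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 3.5)
library(ramscan)
```

## The model

Active histone marks (H3K27ac, H3K4me1, H3K4me3) are not spread evenly along
chromosomes: their ChIP-seq peaks cluster into megabase-scale stretches
separated by peak-poor gaps. `ramscan` treats this modular pattern as a
segmentation problem on the *peak density* — the count of peak midpoints in a
sliding window — rather than on read coverage, which carries far more
background noise. The resulting segments are regulation-associated modules
(RAMs); the gaps between them are RAM boundaries. Unlike TADs or A/B
compartments, which are derived from Hi-C contact maps, this segmentation uses
only peak calls, so it can be computed for any sample with a peak file and a
chromosome-sizes table.

The per-sample procedure is:

1. **Density.** On a fixed grid with step $s$ (default 250 kb), count peak
   midpoints in the window $[c - w, c + w)$ around each bin center $c$, with
   flank $w = 500$ kb. Windows are truncated at chromosome ends and counts are
   not length-normalized. Midpoints, not any-overlap, are used so that each
   peak contributes to exactly the windows it is centered in — which also
   keeps the brute-force oracle used in the tests unambiguous.
2. **Smoothing.** A tricube-weighted local polynomial fit of degree 2 (the
   classic loess weights, no robustness iterations), evaluated at every bin
   from its $\lceil \alpha n \rceil$ nearest bins. The default span $\alpha$
   corresponds to 2 Mb of genome: wide enough to average over bin-level
   counting noise, narrow enough to resolve modules whose median size is
   a few Mb. The span is the single most influential free parameter and is
   user-overridable.
3. **Valleys.** Local minima of the smoothed curve, with plateaus collapsed to
   their middle bin (lower index on even lengths) and chromosome-end bins
   excluded. A *prominence* criterion then removes shallow minima: a valley is
   kept only if it sits at least `prominence` × (chromosome median smoothed
   density) below the lower of its two flanking maxima. The default 0.4 is
   chosen by a separation argument: at the module-versus-boundary density
   contrasts the method targets (several-fold), true boundary dips reach
   ~0.7 of the median, while the shallow minima that any noisy profile
   exhibits in flat stretches stay near 0.1–0.2. Without this criterion every
   long module interior contributes a noise valley per sample, and small
   cohorts cannot vote them away (see "Consensus" below). Setting
   `prominence = 0` restores the plain every-local-minimum rule.
4. **Segmentation.** Each valley becomes a boundary region one grid bin wide,
   $[c - s/2, c + s/2)$; the modules are the maximal inter-boundary intervals.
   Boundaries and modules tile each chromosome exactly, so every basepair is
   classified.

## Consensus across a cohort

Per-sample boundary calls are aggregated on the shared grid: for each bin, the
fraction of samples whose boundary set covers the bin center. Bins at or above
the occurrence threshold (default 25%, inclusive) are consensus bins; runs of
consensus bins become boundary regions; regions less than 250 kb apart are
merged by single linkage (chained merges allowed, so the rule is
order-independent); and inter-boundary intervals no larger than 250 kb are
absorbed into their flanking boundaries rather than deleted, preserving the
tiling. The surviving inter-boundary intervals are consensus modules (cRAMs).
The threshold is read as inclusive (≥ 25%) — where a strict reading would
differ, the inclusive one is the operational definition used throughout.

Consensus is what makes the caller robust: sample-private boundaries (drawn
independently per sample) occur at occurrence 1/cohort and never clear the
threshold. But consensus alone cannot remove *systematic* noise valleys —
with 10 samples, three coincident noise flags already clear 25%, which is why
the per-sample prominence criterion matters most for small cohorts. With
cohorts of ~100 samples the binomial tail does that work instead.

## Statistics over domain sets

* **Intra-domain classification.** Anchor pairs (enhancer–promoter pairs, loop
  anchors) are intra-domain when both anchor *midpoints* fall in one and the
  same module; anchors are short relative to modules, so the midpoint rule is
  the natural reading of "within the same module". Long intervals (ecDNAs,
  super-enhancer clusters) instead require *full containment*, and ecDNA-style
  analyses first drop intervals at least as long as the median module — an
  element longer than a typical module cannot be informative about
  containment. The `pair_set_comparison()` partition (intra in foreground
  only, etc.) feeds the hypergeometric enrichment below.
* **Boundary recall** between two calls counts a reference boundary as
  recovered when a query boundary center lies within one grid step — boundary
  positions are only defined to grid resolution.
* **Density contrast** at boundaries uses the two-sided Wilcoxon rank-sum
  test (midranks; exact enumeration for tie-free groups under 10, otherwise
  the continuity-corrected normal approximation), via `stats::wilcox.test()`.
* **Compartment composition** counts A/B-labeled 250-kb bins whose centers
  fall in each domain; unlabeled bins are excluded from the fractions and
  reported separately.

## Hi-C utilities

Contact lists (bin pairs with observed and expected counts) are assumed to
come from a standard processing pipeline; this package implements the
computations on top: vanilla-coverage normalization ($M_{ij}/(v_i v_j)$ with
zero-coverage rows masked and a single global rescale restoring the grand
total), Poisson contact significance $P(X \ge \mathrm{obs})$ with
$X \sim \mathrm{Poisson}(\mathrm{exp})$ reported as $\log_{10} p$ (evaluated
through the regularized gamma function, so it is stable far into the tail;
non-integer normalized counts use the next integer), per-locus degree of
significant contacts (cutoff $\log_{10} p \le -10$; the cutoff is read in
base 10, the genomics convention — a natural-log reading would be an
implausibly weak threshold at 10-kb resolution), and A/B compartment
assignment: the leading eigenvector of the contact correlation matrix is
oriented by its Pearson correlation with a transcription-activity track
(Pol II peak density, or TSS density where Pol II is unavailable), making the
labels invariant to the eigenvector's arbitrary global sign.

## Enrichment tests

The hypergeometric upper tail $P(X \ge m)$ tests whether upregulated genes
are over-represented among pairs that are intra-module in a foreground cell
type only. The two-sample proportion test compares variant counts per
boundary basepair between two boundary sets with the pooled-variance $z$
statistic and no continuity correction — the intended regime is counts in the
thousands to millions, where the correction is negligible; small-sample users
should prefer an exact test. Genome length is always an explicit argument.

## The synthetic cohort generator

`sim_config()` describes a cohort whose geometry mirrors the scales the
method targets: lognormal module lengths (median 3 Mb, truncated at 1.5 Mb),
boundary gaps (median 750 kb, truncated at 300 kb), 10 samples sharing 80% of
their boundaries, peak rates of 2 per 100 kb inside modules versus 0.2 in
boundaries (a 10-fold contrast), lognormal peak lengths (median 600 bp,
typical of narrow-peak calls), and three chromosomes of 100/80/60 Mb — enough
for roughly fifty cohort-shared boundaries, so recovery rates are measured at
~2% granularity. Matched annotations are generated from the same ground
truth: anchor pairs intra-module with probability 0.9, ecDNA-like intervals
likewise, variants with a configurable boundary density multiplier (1 =
uniform null, used for type-I calibration), and contact lists with observed
counts inflated at boundary bins.

What the generator deliberately does **not** emulate: telomeric/centromeric
peak deserts and mappability gaps, chromosome-scale covariates (GC, gene
density), correlated peak placement within super-enhancers, biological
cohort structure beyond shared/private boundaries, and read-level noise
(peaks are simulated directly, since the pipeline consumes peak calls).
Passing recovery tests therefore demonstrates correctness of the
segmentation and consensus machinery under the stated geometry — not
performance on real ChIP-seq, where span and prominence may need adjustment
against known biology.

```{r recovery-example}
cfg <- sim_config(seed = 7)
truth <- simulate_layout(cfg)
fits <- lapply(simulate_peaks(truth, cfg), ram, chrom_sizes = cfg$chrom_sizes)
cons <- consensus_ram(fits, cfg$chrom_sizes)
shared <- truth$boundaries[truth$boundaries$shared, ]
boundary_recall(shared, cons$boundaries, tolerance = cfg$step)$recall
plot(fits[[1]], chrom = "chrS3", main = "sample 1, chrS3")
```

## Numerical and degenerate-input choices

* All coordinates are 0-based half-open (BED); 1-based sources must be
  converted at the boundary of the system. Strand is ignored: no step of the
  method is strand-dependent.
* Peak files are consumed as published; no score or q-value filter is applied
  before density computation.
* The local fit requires at least 10 bins per chromosome and at least
  `degree + 2` bins per window; both violations are errors suggesting a
  larger span or step. Constant and linear profiles are reproduced exactly
  (a degree-2 fit contains them), which the tests assert to 1e-8.
* Plateau extrema resolve deterministically (middle bin, lower index on even
  ties); an all-equal profile has no extrema and yields one module per
  chromosome.
* Zero-coverage Hi-C rows are masked NA, not dropped silently; a degenerate
  leading eigen-spectrum (e.g. the identity matrix) yields an all-NA
  compartment track with a warning rather than an arbitrary vector.
* Empty inputs that make a statistic undefined (no pairs, no variants, empty
  reference boundary set, a constant activity track) are flagged or raised
  as errors, never propagated as NaN.
* Centromeric peak deserts are not masked; on real genomes they legitimately
  produce boundaries, and callers who want to exclude them should intersect
  the output with a blacklist.

## Problem sizes used by the test suite

The packaged tests and the acceptance script run the full pipeline on the
default three-chromosome, 10-sample cohort (about 4,000 peaks per sample),
cross-check the vectorized kernels against brute-force oracles at 10^3–10^4
items, and calibrate the proportion test on 1,000 simulated cohorts of
20,000 uniform variants each. These sizes exercise every code path at full
statistical resolution while keeping a complete run in well under a minute
per component.

## Known limitations

* Boundary positions are grid-quantized; sub-step localization is out of
  scope.
* The consensus weighting is unweighted voting; sample quality weights are
  not implemented.
* The per-sample boundary is fixed at one grid bin; wide consensus
  boundaries emerge only through merging across samples.
* `vc_normalize()` operates on dense in-memory matrices and is intended for
  per-chromosome blocks at coarse resolution, not genome-wide 10-kb maps.
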