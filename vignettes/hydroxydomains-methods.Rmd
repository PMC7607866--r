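---
title: "Methods: 5hmC-enriched domain analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 5hmC-enriched domain analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, the
assumptions behind each step, the tunable parameters with their defaults and
rationale, what the synthetic cohort generator does and does not emulate, and
the numerical conventions used in corner cases. It states no empirical
number that the test suite or `scripts/acceptance.R` does not itself compute.

## Coordinates and containers

All intervals live in 0-based half-open coordinates `[start, end)`, the BED
convention, held as unstranded `GRanges`. Printed 1-based inclusive loci (the
convention of prose coordinates) are converted on input via
`read_bed(..., one_based = TRUE)`. Chromosome names pass through verbatim —
no "chr" normalization is attempted, which is the caller's responsibility
when mixing sources. Strand is ignored everywhere except TSS derivation and
metagene orientation, because 5hmC is an unstranded DNA mark.

Signal is carried by `binned_track`: fixed-width bins (default 100 bp,
chosen to resolve kb-scale domains without inflating memory), last bin
truncated at the chromosome end, all values non-negative. Means and sums
over regions weight partial bins by their overlap, computed from per-chromosome
prefix sums, so a constant track yields the constant over any region and
summing signal over a stitched domain equals summing over its constituent
bins — stitching never invents signal. Track correlation matrices use 10 kb
bins by default: coarse enough to damp bin-level sampling noise, fine enough
to separate domains.

## Domain calling

**Stitching.** Peaks whose gap (next start minus previous end, exclusive of
peak lengths — the ROSE convention) is at most the stitching distance are
merged transitively per chromosome. The default distance is 12,500 bp.
`stitching_curve()` recomputes the domain count over a distance grid and
estimates the knee as the grid point with the largest perpendicular distance
to the chord between the first and last curve points *after min–max scaling
both axes*; raw-unit perpendicular distance would depend on the units of the
two axes, so the scaled form is used and documented here as a deliberate
choice.

**Scoring and ranking.** Domain signal is the aggregate bin signal over the
domain divided by a library scale, by default the track total / 1e6
(CPM-like); a spike-in-derived factor can be passed instead since the
normalization formula for spike-ins is assay-specific. Ties in signal rank
leftmost-first in (chromosome, start) order, a deterministic and documented
tie-break.

**Ranked-curve cutoff.** With scores sorted ascending and both axes min–max
scaled to [0, 1], `rose_cutoff()` walks from the strongest score leftwards
while the discrete slope exceeds 1 and cuts at the last point where it still
does; on a convex curve this is exactly the point where a unit-slope line is
tangent (the minimizer of y − x), which the tests verify against a
brute-force tangent oracle. Degenerate all-equal scores yield zero super
domains by convention. Both a fixed `top_n` (e.g. 500 per sample) and the
automatic cutoff are exposed, since either may be appropriate depending on
sequencing depth.

**Consensus.** The flattened union of all samples' domains defines the
candidate intervals; support counts distinct samples with at least 1 bp of
overlap, and intervals with support below `min_support = 2` are dropped —
i.e. a consensus domain must recur in at least two samples. Consensus
identity uses the flattened-union coordinates, not per-sample coordinates,
so each domain has a single stable span `chrom:start-end`.

**Peak caller.** A minimal Poisson bin caller ships for the synthetic
pipeline only: bins at least 2-fold over the genome-wide mean with a Poisson
upper-tail probability below 1e-5 are significant; holes of up to 2
non-significant bins inside a run are closed (bin-level noise otherwise
shatters one peak into fragments and distorts the stitching curve at small
distances), and a peak must contain at least 3 originally significant bins so
that isolated noise bins — which recur across samples at highly expressed
gene bodies — do not seed spurious consensus domains. It makes no claim to
reproduce any production caller; real peak sets enter through `read_bed()`.

## Domain–gene assignment

A domain belongs to the TAD containing its midpoint — a convention for
boundary-spanning domains; an any-overlap rule would need an additional
tie-break and midpoint assignment is stable and order-free. Candidate genes
are those with a TSS inside that TAD (the usual enhancer–gene pairing
convention, rather than body overlap) and mean RPKM ≥ 1 across the
correlation samples, filtering genes whose correlation would be noise-driven.
Pearson r is computed between log2(domain signal + 1) and log2(RPKM + 1)
across tumor-diagnosis samples only; the log transform stabilizes the heavy
right tails of both quantities and the pseudocount of 1 keeps zeros finite.
The gene with the largest r² wins, ties broken by nearest TSS; a gene
assigned to exactly one domain marks that domain gene-specific. Intra-TAD
domain pairs are correlated the same way, and a pair in which exactly one
member overlaps its assigned gene's body while the other lies entirely
outside it is flagged as a putative enhancer–gene candidate, with the
facing-edge distance reported.

## Group-specific and differential analysis

Group specificity uses a Welch two-sided t-test of log2(signal + 1), each
group against all other samples (normal donors form their own group), with
BH FDR per group across domains. Welch rather than a rank test because group
sizes go down to 4, where rank tests are degenerate; both directions are
reported so down-hydroxymethylation is symmetric with enrichment.
Zero-variance inputs get p = 1 by convention.

The diagnosis-versus-relapse test is a fully specified moderated t:
replicate columns are scaled to a common total over the analysed domains,
log2fc is the difference of mean log2(x + 1) between conditions, the pooled
within-condition variance is shrunk toward the across-domain median with 4
pseudo-degrees of freedom (df = 2·(nrep − 1) + 4 at 2 replicates per
condition), and BH FDR follows. This is a deliberate, simulation-validated
substitute for differential-binding wrappers around count-model backends;
it does not claim to reproduce their exact calls. Two contracts follow from
normalization and are tested: a uniform global shift is invisible, and
swapping condition labels negates every log2fc exactly. Heavily asymmetric
planted changes (many domains moving up) therefore bias the apparent
fold-changes of unchanged domains — visible in the fourth synthetic relapse
pair — which is inherent to library normalization, not a defect.

## Overlap null and chromatin context

The CpG overlap null draws target-sized subsets from the universe *without
replacement* (the universe is a finite chip), reporting the resample mean and
SD and an upper one-sided empirical p with the +1 convention. The null mean
converges to the hypergeometric expectation, which the tests check within
4 standard errors at 1000 resamples; the "± value" quoted alongside a null
is the SD of resample fractions.

Metagene profiles rescale each gene body to 100 positions with 2 kb absolute
flanks at track-bin resolution, orient by strand, and average within
expression classes [0,1), [1,10), [10,100), [100,∞) RPKM (closed on the
left). Genes shorter than the body bin count or with flanks off the
chromosome end are dropped. Bins at which *all* tracks are zero are excluded
from correlation matrices, since jointly uncovered genome would inflate r.

## Clinical statistics

Percent reduction is defined on means (medians behind a flag):
100·(mean(ref) − mean(test))/mean(ref), scale-invariant by construction.
Group comparisons default to the two-sided Mann–Whitney test (small-n,
distribution-free), with Welch available. Survival dichotomizes the
NDMM-at-diagnosis samples at the median analyte value, ties and the odd-n
median sample going to "low" — with 39 measured values this yields the 20/19
split. Kaplan–Meier curves, a log-rank p and a Cox fit on the binary
indicator are returned; the hazard ratio is oriented low-versus-high with a
95% Wald CI, so HR > 1 means worse outcome with less 5hmC. A group with zero
events is flagged unstable rather than silently reported.

## The synthetic cohort generator

Defaults encode the study conditions of a myeloma-style cohort: 5 normal
donors, 40 tumors (MMSET 9, CCND1 11, hyperdiploid 16, other 4; ISS
I/II/III/NA = 9/17/13/1 with one 5hmC measurement failure, so 39 measured
values), 4 diagnosis/relapse pairs with two Poisson technical replicates per
condition, a 3 × 10 Mb genome tiled into 1 Mb TADs, global 5hmC reduced 69%
in tumors (stage II and III reduced 25% and 31% versus stage I; 5mC reduced
34% with no stage effect), exponential survival with hazard × 2.6 for the
below-median-5hmC half and administrative censoring at 60 months tuned to
~40% events, a strongest planted domain–gene link at r² 0.78 (remaining
links drawn from [0.25, 0.6]) and enhancer pairs sharing activity at r²
0.88, and per-pair relapse plans whose first entry halves ~48% of the
patient's domains.

Mechanics, and the reasoning where the design was open:

* Background bin signal is Gamma(shape 2, scale 1) — non-negative by
  construction, unlike Gaussian noise, and heavy-tailed like real coverage.
* Planted domains are clusters of 3–5 peaks (1.5–2.5 kb) with gaps drawn
  uniformly from 4–12.4 kb, so the stitching-distance curve genuinely bends
  at 12.5 kb; peak bins are multiplied by `enrichment_fold` (12) times a
  per-sample log-normal activity (sd 0.6 on the natural log).
* Gene bodies get a mild multiplicative bump (≤ 1.9×) increasing with the
  gene's baseline expression class, producing the expression-ordered
  metagene profiles without creating domain-strength signal.
* Linked-gene expression is built from the *measured* log2 domain signal of
  the generated track plus Gaussian noise calibrated so the expected squared
  correlation equals the target — self-calibrating against binning and
  background, so recovery tests measure the pipeline, not the calibration.
* Survival hazard applies to the below-median half of the *measured* 5hmC
  values; the analysis split is then exactly the generative split and Cox
  coverage is interpretable.
* One RNG stream per output category (layout, tracks, expression, clinical,
  survival, relapse, CpG), each sample with its own track seed, so enlarging
  one output category does not shift the others; everything is reproducible
  from a single integer seed.
* Stage means solve the two published constraints jointly — stage ratios
  II/I = 0.75 and III/I = 0.69, and the overall measured-tumor reduction of
  69% — given the stage counts, with NA-stage samples at the weighted staged
  mean.

What it does **not** emulate, and hence what green tests do not show about
real data: read-level sampling (FASTQ/alignment), sequence context and
CpG-density structure, copy-number variation distorting domain signal,
batch or donor covariance between samples, realistic TAD size variation, or
a production peak caller's behaviour. Recovery rates on this generator are
upper bounds for field data.

## Problem sizes and numerical conventions

The test suite runs each primitive against brute-force or textbook oracles
on 100 random small instances (tolerances 1e-9 combinatorial / 1e-6
floating), planted-recovery checks over 20 full cohorts at the default
conditions, null-calibration checks on 1000-domain matrices and 1000
resamples, and Wald-CI coverage of the planted hazard ratio over 1000
clinical cohorts at n = 39 — sizes chosen so the whole suite runs in a few
minutes on one core; the acceptance script's hazard ratio is a median over
101 replicate cohorts for the same reason. Pseudocount 1 before every log2;
BH FDR via the standard step-up; empty metagene classes are omitted with a
notice; degenerate inputs (all-equal scores, zero-variance tracks,
zero-event strata) return documented conventions rather than errors where a
convention exists, and errors naming the offending input where it does not.

## Known limitations

Consensus support counts samples, not base pairs, so one sample's long
domain can bridge two neighbours' short ones into a single consensus span.
The moderated differential test assumes roughly comparable within-condition
variances across domains after the log transform. The TAD-midpoint rule can
misassign a domain straddling a boundary. CpG resampling does not match
GC/CpG-island context. No CNV-aware signal correction is attempted: copy
gains will read as hydroxymethylation gains.
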