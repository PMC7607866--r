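# hydroxydomains

Tools for cohort-scale analysis of 5-hydroxymethylcytosine (5hmC)
sequencing in plasma-cell disorders — or any setting where a sparse,
unstranded DNA-modification signal organizes into large regulatory domains.

Genome-wide 5hmC marks active chromatin, and in multiple myeloma its global
level falls with disease severity while the residual signal concentrates in
large peak clusters reminiscent of H3K27ac super-enhancers. Analysing such
data requires a chain of steps that no single existing package covers:

* **Domain calling (ROSE-style).** Per-sample 5hmC peaks separated by gaps of
  at most a stitching distance *d* (default 12.5 kb) are merged into
  *5hmC-enriched domains*; each domain is scored by its aggregate,
  library-scaled signal and ranked. On the min–max-scaled ranked curve the
  cutoff sits where a line of slope 1 is tangent; domains above it are the
  "super" domains. `stitching_curve()` reports how the domain count decays
  with *d* and estimates the knee of that curve.
* **Consensus across samples.** The flattened union of all samples' domains
  is kept where at least `min_support` samples (default 2) contribute
  overlap, yielding a domains × samples signal matrix
  (`consensus_domains()`).
* **TAD-constrained gene assignment.** Each consensus domain is assigned the
  gene, within its topologically associating domain, whose expression is most
  correlated with the domain signal: Pearson *r* on log2(x+1) across tumor
  samples (`assign_domain_gene()`), plus intra-TAD domain–domain correlation
  and flagging of genic/extragenic correlated pairs as putative
  enhancer–gene candidates (`flag_enhancer_candidates()`).
* **Group-specific and relapse-dynamic domains.** Welch t-tests of each
  molecular group against the rest with per-group BH FDR
  (`group_specific_domains()`), and a replicate-aware moderated t-test for
  diagnosis-versus-relapse changes after library-size normalization
  (`differential_domains()`).
* **Overlap nulls.** The fraction of a CpG set inside domains against a
  without-replacement resampling null from a CpG universe
  (`resampling_null()`).
* **Chromatin context.** ChromHMM-state signal distributions, binned-track
  correlation matrices, peak meta-profiles and expression-stratified
  metagene profiles.
* **Clinical statistics.** Percent reductions and rank tests on global
  MS-measured 5mC/5hmC levels, ISS stage trends, covariate checks, and
  median-dichotomized Kaplan–Meier / Cox survival analysis
  (`dichotomized_survival()`), with the hazard ratio oriented low-vs-high so
  HR > 1 means a worse outcome with less 5hmC.

A fully synthetic cohort generator (`simulate_cohort()`) plants every one of
these effects — enriched domains built from peak clusters, domain-coupled
gene expression, group-specific domains, ISS-graded global 5hmC, survival
hazard tied to the 5hmC level, and relapse fold-changes with technical
replicates — so the entire pipeline runs and is testable with no external
data.

## Worked example

```r
library(hydroxydomains)

res <- run_pipeline(cohort_config(seed = 1), out_dir = "run1")
print(res)
```

```
pipeline_result (seed 1):
  consensus domains: 39 (37 tumor-only), assigned 35, gene-specific 25
  max link R2 0.794, max pair R2 0.852, enhancer candidates 3
  5hmC reduction 67.5%, 5mC 36.1%, HR(low vs high) 0.74
  CpG overlap 41% vs null 11%
```

Reading the output: from 45 samples' peak calls the pipeline stitched and
kept 39 consensus domains (37 using tumors only); 35 of them were assigned an
expressed gene inside their TAD, 25 of those genes to exactly one domain.
The strongest domain–gene squared correlation was 0.794 (the generator
planted its top link at 0.78), and the strongest intra-TAD domain pair
reached R² 0.85 around the planted enhancer pairs. Globally, tumors showed a
67.5% lower 5hmC and 36.1% lower 5mC level than normal donors, and 41% of
the planted CpG target set fell inside consensus domains against a
resampling null of 11%. The single-cohort hazard ratio is extremely noisy at
~16 events (here 0.74 with a CI spanning an order of magnitude); the
acceptance script therefore reports the median over 101 replicate cohorts,
which recovers the planted 2.6.

Per-stage outputs (consensus BED5, signal matrix TSV, assignment,
group-specific and differential tables, overlap-null and clinical JSON, a
summary JSON and a parameter log) are written under `run1/`.

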