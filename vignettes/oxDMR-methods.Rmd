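---
title: "Methods: 5hmC estimation, DMR calling and biomarker screening from paired BS/oxBS data"
author: "oxDMR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 5hmC estimation, DMR calling and biomarker screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxDMR)
```

## The measurement model

Bisulfite treatment converts unmodified cytosine to uracil (sequenced as T),
while 5mC and 5hmC are both protected; oxidative bisulfite (oxBS) adds a
prior oxidation step that converts 5hmC so that it too reads as T.  Writing
m and h for the true 5mC and 5hmC fractions at a CpG dyad (m, h ≥ 0,
m + h ≤ 1), a read retains C with probability

* BS library: p = (m + h)(1 − ε_over) + (1 − m − h)·ε_fail
* oxBS library: p = m(1 − ε_over) + h(1 − η_ox)(1 − ε_over) + (1 − m − h)·ε_fail

where ε_fail is the bisulfite non-conversion rate (an unmodified C that
still reads C), ε_over the over-conversion rate of protected bases, and
η_ox the oxidation efficiency.  With perfect chemistry (ε = 0, η_ox = 1)
the expected methylation ratios are E[β_BS] = m + h and E[β_oxBS] = m, so
the subtraction estimator ĥ = β_BS − β_oxBS is unbiased for h; with
imperfect chemistry E[ĥ] = η_ox (1 − ε_over) h, a slight deflation.

`estimate_hmc()` / `estimate_cohort()` provide three estimators:

* **raw** — ĥ = β_BS − β_oxBS, m̂ = β_oxBS.  May be negative; unbiased, and
  therefore the default for group differences and correlations, where a
  truncation would bias small effects toward zero.
* **clamp** — ĥ = max(0, β_BS − β_oxBS), m̂ = min(β_oxBS, β_BS).  For
  reporting per-sample levels on the natural scale.
* **mle** — the maximiser of Bin(c_BS; n_BS, m + h) · Bin(c_oxBS; n_oxBS, m)
  over the constraint set.  At interior points this equals the raw
  subtraction (the binomial MLE of each proportion); when β_BS < β_oxBS the
  optimum lies on the h = 0 face where both libraries share the single
  parameter m, whose MLE is the pooled proportion
  (c_BS + c_oxBS)/(n_BS + n_oxBS).  The closed form is verified in the test
  suite against a brute-force 0.001-lattice likelihood search.

Because ĥ and m̂ share the β_oxBS term with opposite signs, their
*estimation errors* are negatively correlated even when the true levels are
independent.  This shared-noise artefact inflates any observed Δ5mC-vs-Δ5hmC
anti-correlation; the package therefore demonstrates the biological
anti-correlation with *planted coupled effects* whose truth is known, rather
than from noise alone, and the test suite asserts the artefact's sign
separately so users are aware of it.

Sites are paired per sample by inner join on (chromosome, position) with a
minimum coverage of 5 reads in *each* library by default — the usual RRBS
practice; the threshold is configurable and all drop counts are reported.

## DMR calling

The caller takes one of three per-CpG signals: 5mC (β_oxBS), 5hmC (raw ĥ),
or BS (β_BS, the entangled sum).  Steps:

1. **Presence filter.** A CpG is retained if callable in ≥ 80% of samples of
   each group (`min_group_presence`).
2. **Runs.** Retained CpGs are grouped into maximal runs with inter-CpG gaps
   ≤ 300 bp (`max_gap`), the scale at which RRBS fragments cluster.
3. **Recursive binary splitting.** Each run is split at the breakpoint
   maximising the absolute difference of the two children's mean per-CpG
   group differences, accepted only while both children keep ≥ 5 CpGs
   (`min_cpg`) and the larger child's |mean difference| improves on the
   parent's by ≥ 0.05 (`split_gain`).  Leaves are candidate regions.  This
   is a deliberately explicit, documented stand-in for de-novo segmenters of
   the metilene family: the package implements its procedure rather than
   shelling out, and no result below depends on matching any external
   tool's segmentation byte-for-byte.
4. **Region test.** Each candidate is tested by a two-sided Mann–Whitney U
   on *per-sample region means* — samples, not CpGs, are the replication
   unit, so pooling CpGs would pseudo-replicate.  Mid-rank ties; the exact
   permutation distribution over all group assignments is enumerated when
   n ≤ 12, otherwise the tie-corrected normal approximation with continuity
   correction is used (the two agree to < 0.02 at the crossover, and the
   exact branch is verified against exhaustive permutation in the tests).
5. **FDR and effect gates.** Benjamini–Hochberg adjustment is applied
   within each (contrast, mark) family — families are reported separately,
   so correcting across them would mix exchangeable hypotheses.  A region
   is a significant DMR when q < 0.05 **and** |Δ| exceeds the mark-specific
   gate: 0.2 for 5mC and for the BS signal, 0.1 for 5hmC.  The lower 5hmC
   gate reflects the mark's compressed dynamic range (5hmC levels rarely
   exceed ~0.3).

Swapping the group labels negates every mean difference and preserves every
p-value (asserted as a property test).

## Genomic annotation

Each DMR's midpoint receives exactly one category with precedence
promoter > exon > TTS > intron > intergenic.  Windows are strand-aware:
promoter = TSS −1000..+100 bp, TTS window = TTS −100..+1000 bp (HOMER-like
defaults; both configurable).  Midpoint assignment keeps the partition
property — category counts always sum to the number of DMRs — which
any-overlap schemes lose.  Gene models are read from GTF or BED12 via
`rtracklayer`, or constructed directly.

## Biomarker screening and signal comparison

A DMR's marker value in a sample is its mean signal over the region's
callable CpGs; regions are evaluated when ≥ 80% of contrast samples have a
value.  Discrimination is the rank-based AUC (Mann–Whitney U normalised by
n₁n₀, mid-rank ties): the probability that a random case exceeds a random
control.  It is apparent (in-sample) AUC by design — the screen mirrors a
univariate marker discovery step, not a validated classifier; no
cross-validation is performed.  A marker passes the screen when AUC > 0.8
and the region is itself a significant DMR.

`compare_signals()` reports AUC and group difference for 5mC, 5hmC and BS
over the same region.  When the case group shifts by +δ_m in 5mC and −δ_h
in 5hmC, the BS difference is δ_m − δ_h: with δ_h = δ_m the BS signal
cancels exactly (AUC ≈ 0.5) and in general the BS AUC falls below the 5mC
AUC — the attenuation property at the heart of the package, asserted over
seeded replicates in the acceptance tests.

For contrasts defined by expression of a marker gene (e.g. an
immune-checkpoint transcript), `median_split()` builds the two groups at
the cohort median; samples exactly at the median go to the low group by
default (configurable) — with even cohort sizes no sample sits at the
median, so the rule only matters for odd cohorts or heavy ties, and a
degenerate all-equal vector is rejected.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes, at
per-CpG count level (no read-level artefacts: no MspI digestion model, no
PCR duplicates, no mapping error):

* **CpG map.** Clustered spacing by default — islands of 10 CpGs ~50 bp
  apart separated by ~5–7.5 kb — mimicking the CpG-dense MspI fragments
  RRBS actually covers; a fixed-spacing mode exists for geometry-free
  tests.  A small deterministic gene model lays transcripts over the
  clusters so that every annotation category is realisable.
* **Baselines.** Per-CpG 5mC from a 50/50 Beta(1,10)/Beta(8,2) mixture (the
  familiar bimodal beta-value distribution: unmethylated islands, methylated
  gene bodies); 5hmC from Beta(1.2, 15) (mean ≈ 0.07, the low tissue range),
  clipped to m + h ≤ 1.  Fixed-level overrides support calibration studies.
* **Planted effects.** A region effect shifts one mark by `delta` in the
  case group, optionally shifting the other mark by `coupling` (negative
  coupling plants the anti-correlated alterations).  Region CpGs draw their
  baselines uniformly from the feasible simplex slice that leaves headroom
  for the shift — real DMRs of a given magnitude necessarily live at loci
  able to shift by it — with a small margin (0.1 on m, 0.05 on h) so that
  boundary truncation of the per-sample jitter does not erode the planted
  effect.  After all shifts, levels are clipped to m, h ≥ 0, m + h ≤ 1
  (asserted as an invariant).
* **Biological variability.** Per-sample, per-cluster Gaussian jitter with
  sd 0.10 on m and 0.05 on h, applied before clipping.  Inter-individual
  sds of 0.05–0.15 are typical for variable methylation loci; without this
  term every sample would share identical truth and region AUCs would
  saturate at 1, making discrimination comparisons meaningless.
* **Coverage.** Independent negative binomial per library (BS and oxBS are
  separate library preparations), mean 30, size 8 — RRBS depth is
  overdispersed.  Zero-coverage sites survive to the pairing step, which
  drops them.
* **Chemistry defaults.** ε_fail = 0.005, ε_over = 0.005, η_ox = 0.95 —
  chosen once as typical of bisulfite kits (non-conversion ≤ 1%) and of
  perruthenate oxidation efficiencies reported for oxBS protocols; no
  conversion-control sequencing results were available to estimate them
  from, so they are stated defaults, not estimates.
* **Determinism.** One integer seed fixes map, truth, coverage and counts;
  identical specifications produce byte-identical output files.

What passing tests on this simulator do *not* show: robustness to mapping
artefacts, fragment-boundary effects, strand-biased conversion failure, or
batch structure between BS and oxBS libraries — none of which the generator
emulates.

## Numerical and design choices

* All internal coordinates are 0-based half-open; methratio-style inputs
  (1-based) and browser region strings (1-based inclusive) are converted on
  ingestion, BED outputs are 0-based half-open.  CpG dyads are collapsed to
  one record (the + strand C) on read by default, summing counts.
* The BH step-up is implemented directly (it is asserted against the
  reference implementation to 1e-12); p-values of exactly 0 are rejected as
  invalid input.
* The MLE boundary projection is exact, not iterative; the lattice
  verification tolerance (0.002) is twice the lattice pitch.
* Degenerate inputs: empty site tables, empty DMR sets, empty gene models,
  all-tied region values and single-group contrasts all return defined
  results or informative errors, exercised in the tests.
* Ties at exactly the significance gate (|Δ| equal to the threshold) are
  *not* significant: the gates are strict inequalities.

## Problem sizes

The test suite and the acceptance script run entirely on simulated data at
desk scale, chosen to keep each property measurable with comfortable
margins: estimator recovery on 1000 CpGs at coverage 50; 200 random cases
for the MLE lattice check; 100 exhaustive-permutation comparisons (n ≤ 10);
1000 BH vectors; 50 null cohorts of 2000 CpGs at 10 vs 10 samples; 20
planted DMRs per mark at coverage 30 for recall; 100 replicates for the
attenuation property and 50 for the anti-correlation property.  Cohort-
scale results from any real study additionally depend on its sequencing
depth, cohort composition and the internals of the external tools it used,
and are not targets of these checks.

## Known limitations

* The segmentation is a greedy binary splitter: adjacent DMRs closer than
  `max_gap` with same-sign effects of different sizes may merge if the gain
  criterion is not met.
* No shrinkage across sites or samples; per-CpG estimates at coverage 5–10
  are noisy, and the region level is where inference is intended to happen.
* No covariate adjustment or paired designs in the region test.
* Conversion-error parameters are fixed inputs, not estimated from spike-in
  controls.
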