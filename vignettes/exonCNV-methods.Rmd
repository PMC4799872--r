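---
title: "Batch-normalized exon-level CNV calling: model, parameters, and design notes"
author: "exonCNV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Batch-normalized exon-level CNV calling: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exonCNV)
```

# The model

Targeted capture produces, for each sample, a vector of mean read depths
over a few hundred exon-sized intervals. Depth varies over three nuisance
scales — library size (per sample), capture efficiency (per target), and
multiplicative sequencing noise (per cell) — and over the one scale of
interest, copy number. The pipeline removes the nuisance scales in two
steps:

1. **Fractional coverage.** Each sample's depths are divided by that
   sample's total over all targets. Library size cancels exactly: the
   package tests assert bit-level invariance of the log2 ratios under
   scaling any one sample's raw depths by an arbitrary positive constant.
2. **Batch-median reference.** Within a sequencing batch, the per-target
   median of fractional coverage across samples estimates the copy-neutral
   level of that target, absorbing capture efficiency. The log2 ratio of a
   sample's fraction to the batch median is the copy-number signal:
   0 for two copies, −1 for a heterozygous loss, +0.585 for one extra copy.

The batch median *includes* the sample under test. With a batch of ten and
at most one or two true carriers per locus, the median is a robust
copy-neutral estimate; the alternative (leave-one-out medians) breaks the
useful property that a batch's log2 ratios are exactly median-centered.

Calling is deliberately simple — fixed inclusive thresholds of **+0.40 for
gains** and **−0.55 for losses**, applied per target, with maximal
same-direction runs (contiguous in genome order, one chromosome, no gap
tolerance) merged into one call. No HMM or circular binary segmentation is
used: the aim is single-exon resolution with auditable behaviour, and the
thresholds sit 4σ (losses) from a heterozygous deletion at the default
noise level. Thresholds are read as attained bounds, so a target at exactly
+0.40 or −0.55 is aberrant; the threshold semantics are pinned by tests at
machine-precision distance from the bounds.

## Why a per-target threshold, then run-merging

Whether fixed thresholds should apply to individual targets or to run
means is underdetermined by the outputs the method reports. Per-target
application followed by merging is the strictly more conservative reading
(a run mean can cross a threshold no single target reaches) and keeps
"exon 12–20"-style boundaries sharp; it is also what the brute-force oracle
in the test suite implements independently.

## Sex chromosomes

X/Y targets are normalized against same-sex batch samples only. Without
this, every male is half-depth on X relative to a mixed-batch median and
would surface as an X-deletion carrier, while a female X trisomy
(three copies vs. the female baseline of two, +log2(1.5)) would be
attenuated. A sex stratum with fewer than three samples gives an unusable
median; such targets are masked for that stratum with a warning rather than
failing the batch. Samples of unknown sex are masked on sex chromosomes.

# Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| gain threshold | +0.40 | log2 ratio | fixed operating point of the calling scheme; below the +0.585 single-copy-gain expectation |
| loss threshold | −0.55 | log2 ratio | fixed operating point; 0.45 above the −1 heterozygous-loss expectation |
| `pseudofrac` | 1e−6 | fractional coverage | see *Numerical choices* |
| batch size | 10 | samples | the processing unit the normalization was designed around; batches under 3 are refused |
| `freqCutoff` | 0.01 | carrier fraction | call loci recurring in ≥ 1% of the cohort are presumed artifacts or benign polymorphisms |
| `noiseMultiplier` | 2 | — | a call's \|mean log2\| must reach twice the non-carrier batch MAD |
| reciprocal overlap | 0.5 | fraction of targets | standard CNV locus-identity convention |

# Numerical choices

**Pseudofraction.** Ratios are computed as
`log2((f + eps)/(median + eps))`. `eps` lives on the fractional-coverage
scale so that library-size invariance stays exact, and defaults to 1e−6 —
roughly 0.1% of a typical per-target fraction on a 500-target panel. It
must be far below 1/n_targets: a pseudocount comparable to the fractions
themselves would compress a heterozygous deletion from −1 toward 0 and
destroy sensitivity. Targets whose batch-median fraction is at or below
`eps` are masked rather than called, which prevents capture dropouts from
surfacing as recurrent homozygous deletions; a true copy-0 event in an
otherwise well-captured target still scores a deep finite loss.

**Median convention.** The per-target centering is computed as the median
of `log2(f + eps)` over the stratum, subtracted. For odd strata this is
identical to dividing by the median fraction; for even strata it uses the
geometric rather than arithmetic mean of the two central order statistics.
The difference is below 1e−4 in log2, and the log-scale form makes the
median-centering invariant exact (the tests assert |stratum median| < 1e−9
for every unmasked target).

**Renormalization shift.** Because fractional coverage divides by the
sample's own total, an event shifts its carrier's denominator: a copy-1
event of fractional weight *w* lands at `−1 + log2(1/(1 − w/2))`, a female
whole-X trisomy at `log2(1.5) − log2(1 + wX/2)` (≈ −0.06 for the
simulator's 8% X share). Tests assert the closed form to 1e−9 and the
idealized value to the corresponding bound. For single-exon events on
realistic panels the shift is below 0.002 and irrelevant; it only matters
when an event spans a large fraction of the panel, where calls remain
correct in direction but attenuated in magnitude.

**Degenerate inputs.** A sample with zero total depth is an error naming
the sample (it has no fractional coverage); an all-zero target is masked;
an empty call set is a valid result everywhere downstream, including the
cohort summary, where the intragenic fraction is reported as
not-applicable rather than 0/0.

# The review surrogate

Clinical deployments of this calling scheme interpose manual review of the
per-sample plots between calling and confirmation, a step reported to raise
specificity from 37% to 87% in the hands of experienced reviewers. That
step is human judgment over patient data and cannot be reproduced here; the package replaces it with
two explicit, auditable scores per call — the cohort frequency of its locus
and its signal-to-noise ratio against non-carrier batch samples — and a
verdict (`artifact_freq` > `low_quality` > `pass`). Filtered calls are
retained with their verdict, never dropped, so the reviewer's decision
trail survives in the output.

Locus identity is same direction plus ≥ 50% reciprocal target overlap,
with loci as connected components of that relation. Recurrence additionally
requires at least two distinct carriers: a frequency rule read literally
would flag every private call in any cohort of under 100 samples, which is
clearly not what a recurrent-artifact exclusion means.

# The simulator

`simulateCohort()` generates depth as
`depth_mean × library_s × efficiency_t × (copies/baseline) × 2^η` with
lognormal library factors (sd 0.3, natural log — typical run-to-run yield
variation), lognormal capture efficiencies (sd 0.5 — the order of spread
seen across hybrid-capture exons), Gaussian log2 noise (sd 0.10 — mid-range
for well-behaved 200× panels), a panel of 2–24-exon autosomal genes plus
four X-linked genes holding ~8% of targets, sex-dependent X baselines,
recurrent artifact loci drawn at a population frequency, and injected CNVs
with at most one carrier per batch per locus. Expected log2 shifts are
exact by construction, which is what makes the analytic assertions above
possible.

What the simulator does *not* model — GC waves, mapping bias, pool-level
capture batch effects, count-level (negative binomial) noise at low depth,
related samples — bounds what passing tests show: they validate the
normalization arithmetic, the threshold semantics, and the review logic
under the stated noise regime, not performance on any particular
instrument's worst exons.

Planted artifact loci in the review tests are deletion-direction
(copy 1). A deletion artifact sits 4σ past its threshold, so every carrier
yields one clean call and the frequency filter's "remove 100%, lose 0%"
property is well-posed. Duplication-direction artifacts at the default
noise fragment into slivers with sub-50% reciprocal overlap that no
overlap-based grouping can reunite — the same fragmentation that limits
exact-boundary recovery for gains generally (next section).

# Detection performance and its limits

At the default operating point the loss margin is \|−1 − (−0.55)\| = 0.45
≈ 4σ of per-target noise: in the packaged 500-sample simulation (50
batches × 10, ~500 targets, 1000 injected events of 1–10 exons, seed 17)
every injected loss is detected and 99% of loss spans are recovered
exactly. The gain margin is only 0.585 − 0.40 = 0.185 ≈ 1.7σ, so roughly
5% of *single-exon* copy-3 gain targets fall under the threshold; overall
sensitivity measures ≈ 99.5%, multi-exon gains are detected via their
remaining targets, and gain spans fragment rather than vanish. A literal
100% over ≥ 500 events that include single-exon gains is therefore not a
statistically attainable expectation at this noise level, even though the
per-direction claim (100% for losses; 100% of detections
direction-correct) holds. Reported validation figures of 100% sensitivity
derive from small confirmation sets, where zero misses is the expected
observation.

Problem sizes throughout the test suite (500-sample detection cohorts,
200-target review cohorts, 200 random matrices for the segmentation
oracle) were chosen so each property is measured on enough events for its
expected failure count to be meaningful, while the full suite remains a
few minutes of CPU.

# Known limitations

* The ≥ 1% exclusion is applied per overlapping locus cohort-wide; the
  original per-interval tabulation is not machine-readable, so per-locus
  grouping (the standard CNV convention) was chosen.
* Pathogenic and likely pathogenic are collapsed into one tier: the
  evidence separating them (segregation, prior reports) is outside the
  data model. The classification rules are a deliberate simplification of
  full ACMG/AMP evidence combination.
* The packaged cohort composition stores the stated ARVC count of 90; an
  alternative published denominator of 99 exists for the same cohort, and
  the summary carries a note rather than silently choosing.
* Cross-batch (reference-panel) normalization, GC correction, and BAM-level
  depth computation are out of scope; the package consumes precomputed
  coverage matrices.
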