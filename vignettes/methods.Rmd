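---
title: "Methods: T-DMR analysis for MBD-enrichment methylation tiling arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: T-DMR analysis for MBD-enrichment methylation tiling arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meklchip)
```

# The experiment and the statistical model

A two-channel methylation tiling array co-hybridizes an MBD-captured
(methylated) DNA fraction against input DNA from the same sample. The
methyl-binding domain complex (MBD2b/MBD3L1) binds double-stranded
methylated DNA with sequence-independent affinity, so a probe's
enriched-channel intensity grows with its methylated-CpG content over a
broad range of CpG densities — unlike antibody-based enrichment, which is
most efficient at low density, or promoter/island arrays, which never see
low-density regions at all. The array's probes tile CpG-containing windows
genome-wide (CHARM-style design); two classes of non-genomic probes serve
QC and normalization:

* **anti-genomic probes** match no genomic sequence and measure the
  background hybridization level;
* **control probes** are expected to show equal signal in both channels
  across the full intensity range and anchor the dye-bias correction.

The per-probe quantity of interest is the relative methylation
`M = log2(enriched / input)`; the per-region quantity is `ΔM`, the
difference of group-mean M between two tissues. All coordinates in the
package are half-open and 0-based (BED convention); strand is ignored
because CpG dinucleotides are palindromic and the analysis is not
strand-specific.

## Preprocessing

Stages run in a fixed order; each is inspectable on its own.

1. **Intensity floor** (default 1.0). Non-positive or sub-floor
   intensities are clamped before any log transform, with a message; this
   only matters for externally supplied data, as the simulator emits
   strictly positive intensities.
2. **Signal score**. The fraction of genomic probes whose input-channel
   intensity exceeds the `background_quantile` (default 0.90) of the
   anti-genomic intensities. The score is a hybridization QC: good arrays
   score above the default threshold 0.85. Samples below threshold are
   *flagged, never silently dropped* — the threshold is a rule of thumb,
   and dropping is the analyst's decision.
3. **Loess dye correction**, per sample. M is regressed on
   A = ½·log2(enriched·input) over the control probes (span 0.4, local
   degree 1), and the fitted trend — evaluated at each probe's A, clamped
   to the fitted control range because local regression does not
   extrapolate reliably — is subtracted from every probe's M by rescaling
   the enriched channel. At least 50 control probes are required for a
   stable fit. After correction the control probes' M is centered on zero
   across the intensity range.
4. **Quantile normalization** across samples, applied to the genomic-probe
   M matrix (ties receive the mean of the tied reference values). We
   normalize the ratio M rather than the two channels separately: M is
   the quantity every downstream statistic consumes, and normalizing it
   directly makes the between-sample distributional assumption explicit.

## Smoothing and region calling

Genomic probes are grouped into **clusters**: consecutive probes on one
chromosome with start-to-start gaps of at most `max_gap` = 300 bp, the
experiment's average sonication fragment size. Within a cluster, each
probe's M is replaced per sample by a **triangular-kernel weighted mean**
(weight 1 at the probe, decreasing linearly to 0 at ±`window` = 300 bp).
The kernel choice keeps one convention with the local CpG density weights
(below); smoothing never crosses cluster boundaries, and singleton
clusters pass through unchanged.

Per probe, a pooled-variance two-sample t statistic compares the tissue
groups on smoothed M (two-sided p, df = n₁ + n₂ − 2; a probe with zero
pooled variance gets t = 0, p = 1 when the group means agree, and the
smallest representable positive p with a flag when they do not). T-DMRs
are **maximal runs** of consecutive probes within one cluster that share a
t sign and have p < 0.005; runs of fewer than 3 probes are discarded. Both
cutoffs are the experiment's published operating point and are exposed as
parameters (`p_cutoff`, `min_probes`).

Each region reports the mean ΔM over member probes, the area Σ|t|, and a
region-level p from a pooled t-test on per-sample region means of
smoothed M. The region p's derivation is not uniquely fixed by the
original software; the per-sample-means t-test was chosen because it uses
the same df as the probe test and is exact under the same normality
assumption. Regions rank by ascending region p, ties by descending area,
then coordinates. No multiple-testing correction is applied by default —
the published rule is a raw per-probe cutoff — and the ranking, not the
absolute p, is the primary reading.

## CpG landscape annotation

Two sequence statistics characterize where a region sits in the CpG
landscape:

* **CpG O/E** = `N_CpG / (N_C · N_G) · L`, with N bases excluded from all
  counts and from L. Ratios above 0.6 are conventionally island-like. A
  sequence with no C or no G has an undefined ratio; the package returns 0
  with a `degenerate` flag rather than raising, so batch annotation never
  aborts.
* **Local CpG density** at a nucleotide: the triangular-weighted count of
  CpG sites (weight 1 at the nucleotide, 0 at ±300 bp; a site's offset is
  measured at its C, a convention the definition leaves open). A region's
  density is the mean over every nucleotide in `[start, end)`. Windows are
  truncated at chromosome ends; the ±300 bounds are inclusive, which is a
  convention choice exposed via `half_window`.

## Concordance between high- and low-input arrays

Given regions called in a high-input reference (e.g. 250 ng, 3 vs 3
replicates) and ΔM re-measured in low-input runs (10/25/50 ng, possibly
1 vs 1), each region is classified:

* **verified** — every low-input run reproduces the reference ΔM sign;
* **dropout_1 / dropout_2plus** — exactly one / two or more disagreements.

A low-input ΔM of exactly 0 has no direction and counts as a flagged
disagreement (the tie case is not defined by the experiment; flagging
keeps it visible). The observed Pearson correlation between reference and
low-input ΔM vectors is compared against a **shuffled-pairing null**: the
pairing is permuted n times (seeded) and the null's mean, SD, 2.5/97.5
percentiles and a one-sided empirical p `(1 + #{null ≥ obs}) / (n + 1)`
are reported. Shuffling permutes *region-level* pairings — the region is
the analyzed unit — with probe-level shuffling available by applying the
same function to probe ΔM vectors. Pearson is the default coefficient;
Spearman can be obtained by ranking the inputs first.

## QPCR fold enrichment

Wet-lab enrichment checkpoints compare threshold cycles between tissues at
control loci: ΔCt = mean Ct(tissue1) − mean Ct(tissue2) and fold
enrichment 2^ΔCt. A hypermethylated control locus must show fold strictly
greater than 2; an equal-methylation (imprinted) control must sit inside
the symmetric band |log2 fold| < 1. The ΔCt orientation is explicit in
the API (`tissues` argument) because the sign convention is a common
source of silent errors. Replicate dispersion is summarized as the SEM of
replicate-wise folds — a deliberate simplification of mixed-effects
error models, which are out of scope here.

# The simulator: a stated world

No public accession exists for the original arrays, so the package
generates synthetic experiments with known truth. The generator is a pure
function of its arguments including the seed.

**Genome.** A two-state first-order nucleotide process: CpG-island
segments (elevated `P(G | C)` = 0.33, GC-rich composition; O/E ≈ 1.1)
embedded in a CpG-depleted background (`P(G | C)` = 0.012, O/E ≈ 0.07).
Islands cover `island_fraction` = 0.05 of the genome with lengths uniform
on 800–2500 bp. The background depletion is stronger than in real
mammalian genomes (O/E ≈ 0.2): it is set so that isolated background CpGs
rarely chain into probe clusters long enough (≥ 3 probes) to host false
regions under the raw p < 0.005 rule, keeping the spurious-call rate of
the demo at the few-percent level that the pipeline's recovery properties
assume. This is the simulator's single most consequential calibration and
was fixed before the test suite was frozen.

**Probes.** Candidate 50-mer windows every 35 bp; only windows fully
containing ≥ 1 CG are kept (CpG-driven design). 500 control and 500
anti-genomic probes are appended.

**Truth.** `n_dmrs` islands are planted as DMRs with methylation 0.85
vs 0.10 (baseline 0.10 elsewhere), directions assigned at random but in an
*exactly balanced* split. Balance matters: with unbalanced directions the
two tissues' M-value multisets differ systematically, and quantile
normalization then shifts null probes between groups by a small amount
with near-zero within-group variance — a genuine artifact of quantile
normalization at high DMR fractions (the demo's probes are ~20% DMR,
versus a tiny fraction on a real 2.1M-feature array, which amplifies the
effect far beyond what real data would show).

**Intensities.** Per-probe baseline abundance is log-normal (log2 scale:
N(10, 0.5) genomic, N(10, 1.5) controls so they span the A range,
N(5, 0.5) anti-genomic background). The enriched/input expectation is a
saturating, monotone capture response

```
ratio = 0.2 + 4 · g(m · c),   g(x) = x / (x + 2)
```

with m the planted methylation and c the probe's CpG count — bounded,
monotone, one parameter, consistent with affinity capture approaching
saturation at high methylated-CpG content. With the island CpG rate
(~4–5 CpGs/probe) this gives planted |ΔM| ≈ 1.3–1.7 log2 units. A smooth
quadratic dye bias in M as a function of A (amplitude 0.3, i.e. ±0.15
log2 units across the observed range) is injected into the enriched
channel; its curvature is kept gentle enough that a degree-1 loess at
span 0.4 removes it to well under 0.05 log2 units even at the sparse
edges of the control intensity range. Per-channel log2 noise SD and a
small enriched-channel dropout-to-background probability depend on input
mass:

| input (ng) | noise SD | dropout |
|-----------:|---------:|--------:|
| 250        | 0.25     | 0       |
| 50         | 0.45     | 0.01    |
| 25         | 0.55     | 0.02    |
| 10         | 0.70     | 0.04    |

These values are not measurements — the original study reports no array
noise characterization — they are chosen once so that the 250 ng demo
(3 vs 3) recovers essentially all planted DMRs at the published cutoffs
while the 1-vs-1 low-input runs show visibly inflated scatter yet retain
strongly correlated region ΔM, the qualitative regime the low-input
validation describes.

**What the simulator does not emulate** — and hence what a green test does
not establish: fragmentation-size and ligation/PCR amplification effects,
sequence-specific capture bias, spatial array artifacts, probe
cross-hybridization, and the real genome's repeat and chromatin structure.
Recovery rates on this synthetic world say the *pipeline logic* is sound,
not that the biological assay has any particular sensitivity.

# Numerical choices and degenerate inputs

* Pooled-variance t (not Welch): replicate groups are balanced and small;
  exact df under equal variance.
* Zero pooled variance: p = 1 at zero difference; smallest representable
  positive p plus a flag otherwise (arises only in noise-free synthetic
  data).
* Quantile normalization of a single sample returns it unchanged with a
  warning; an all-control bundle errors.
* Loess evaluation is clamped to the fitted control A range; applying the
  correction twice is a no-op (to < 1e-6) whenever the trend lies in the
  smoother's span — exactly true for a linear trend, and true to the
  residual tolerance for the gentle curvatures the simulator injects.
* Region scores in BED output are −log10(p) capped at 320 (p = 0
  underflow).
* Ranking ties break by descending area, then coordinates, making region
  tables fully deterministic.
* The end-to-end runner re-uses stage outputs already on disk
  (`resume = TRUE`); it recomputes light in-memory state but never
  rewrites a completed stage's files, so a completed run's manifest is
  stable. Reruns into a fresh directory from the same config and seed are
  bit-identical, manifest hashes included.

# Known limitations

* Single-chromosome genomes in the simulator (the analysis modules handle
  multiple chromosomes; clusters never span them).
* The region-level p is a convenient exact test on region means, not a
  genome-wide error-controlled quantity; treat it as a ranking statistic.
* Site-level methylation cannot be measured by this assay class at all —
  regions, not CpGs, are the unit of inference.
* The concordance module takes the low-input runs as given; it does not
  model why a region drops out (the observation that dropouts concentrate
  at low CpG density is data-specific and is reported, not asserted).
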