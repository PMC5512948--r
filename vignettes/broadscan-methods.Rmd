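---
title: "Sequence patterns and the breadth of enhancer activity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence patterns and the breadth of enhancer activity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(broadscan)
```

## The scientific question

Enhancers differ enormously in how many cellular contexts they are active
in: most transcribed enhancers are detected in a single tissue or cell
line, while a small minority are active across dozens. `broadscan`
implements an analysis pipeline that asks what short DNA sequence patterns
distinguish these *broadly active* enhancers — dinucleotide repeat motifs
(DRMs), the full spectrum of 6 bp words, and known transcription factor
(TF) binding motifs — and whether the answer reduces to simple nucleotide
composition (GC content) or carries motif-level information beyond it.

The pipeline has five cooperating parts:

1. **Motif scanning** (`drm_pwm()`, `scan()`, `score_threshold()`):
   position weight matrix (PWM) scanning against a non-uniform background
   with *exact* P-value calibration of the match threshold.
2. **Region handling** (`resize_centered()`, `split_by_breadth()`,
   `shuffle_length_matched()`, `sample_gc_matched()`): class construction
   and matched negative sets.
3. **Enrichment statistics** (`fold_enrichment()`,
   `replicate_enrichment()`, `all_kmer_enrichment()`): fold enrichment with
   replicate negative sets and rank-sum significance.
4. **Classification** (`kmer_spectrum()`, `train_linear()`,
   `cross_validate()`, `extract_weights()`): linear SVMs over DRM, 6-mer,
   or TF-motif features with cross-validated ROC/PR curves and per-feature
   weights.
5. **TF composition** (`tf_composition()`, `compare_composition()`,
   `semipartial_cpg_given_gc()`): GC/CpG content of TF motifs versus
   tissue specificity of TF expression.

A synthetic-data module (`simulation_config()`, `simulate_enhancers()`,
`simulate_tf_table()`) generates genomes, enhancer catalogs and TF tables
with known planted structure, so every stage is testable end to end
without external downloads.

## PWM scanning with exact threshold calibration

A DRM is a 6 bp perfect dinucleotide repeat — CACACA, GAGAGA, GCGCGC or
TATATA — modeled as an invariant PWM with probability one at each
position. Windows are scored as log2 odds against background nucleotide
frequencies $b$, with a pseudocount $c$ added in proportion to the
background:

$$ s(i,\beta) = \log_2 \frac{p'(i,\beta)}{b_\beta}, \qquad
   p'(i,\beta) = \frac{p(i,\beta) + c\, b_\beta}{1 + c}. $$

Defaults are the human genomic composition (42% GC, so $b_A=b_T=0.29$,
$b_C=b_G=0.21$), $c = 0.001$, and a match cutoff of $P < 1/1024$: a window
is a hit when the probability that a random background word scores at
least as high is below the cutoff.

That tail probability is computed **exactly** by dynamic programming.
Score-matrix entries are first rounded to a 1e-3-bit lattice; the
distribution of the lattice window score under the i.i.d. background is
then the convolution of the per-position score distributions over the
integer lattice, which is exact — no sampling, no normal approximation.
The rounding is part of the score definition (reported hit scores sit on
the same lattice, within 0.0005 bits/position of the unrounded value), so
threshold comparison, tail probabilities, and a brute-force enumeration
over all $4^L$ words agree to machine precision; the test suite enforces
agreement to 1e-12 on all four DRMs and on random PWMs.

Why the 1/1024 cutoff matters: under the 42% GC background the perfect TA
word has probability $0.29^6 \approx 5.9\times10^{-4}$, which is *larger*
than $1/4096$. At a stricter cutoff no TATATA match can ever be
significant; $P < 1/1024$ is the tightest power-of-4 cutoff at which all
four perfect DRM words pass. The calibration logic reproduces this
behavior exactly: `score_threshold()` signals a `broadscan_no_threshold`
condition at $\alpha = 1/4096$ for the TA DRM and `scan()` then returns
zero hits. At $\alpha = 1$ every achievable score is admitted (the strict
inequality is treated as vacuous there, matching the cutoff's intent).

Both strands are scanned, and palindromic motifs (GC, TA) deliberately
count each genomic site twice — once per strand. A flag on the density
features can collapse this, but the double-count is the default
convention. Windows containing ambiguous bases are disqualified rather
than partially scored. TF-motif scanning for classifier features uses the
same engine at $\alpha = 10^{-4}$, a conventional default for TF PWM
scanning.

## Regions, classes and matched negatives

All coordinates are BED-convention 0-based half-open. The broad class is
the top 5% of the catalog by breadth with a strict-inequality cutoff: the
boundary $b$ is the smallest breadth such that at most `top_frac`·n
records lie strictly above it ("active in more than 45 contexts"
semantics). The narrow class is a uniform random sample of single-context
enhancers sized to match; the split is invariant to input row order for a
fixed seed because records are canonicalized by id before sampling.

For classification, regions are resized to 600 bp about their centers
(center = `(start+end) %/% 2`, extra base rightward), controlling for the
positive length–breadth correlation. Negative sets come in two flavors:

* **length-matched**: uniform placement of equal-length regions among
  feasible positions, rejecting overlaps with an exclusion list (the
  positive set plus all enhancers, by default ≥ 1 bp strict overlap) and
  with already-placed outputs. Placement is unconstrained across
  chromosomes by default, with a `same_chrom` flag, since the original
  procedure's behavior on this point is not documented.
* **GC-matched**: per input region, a same-chromosome, same-length window
  whose GC content is within ±0.02 by rejection sampling (the matching
  criterion is otherwise unquantified, so the tolerance is a visible
  knob). Window GC is computed from per-chromosome cumulative counts, so
  each try is O(1). Per-region failures are collected and the run aborts
  when more than 1% of regions fail.

## Enrichment statistics

Fold enrichment is the ratio of mean per-region motif counts,
$FE = \bar{x}_{pos} / \bar{x}_{neg}$, with two-sided Wilcoxon rank-sum
P-values on the count distributions (`stats::wilcox.test`: exact for small
untied samples, normal approximation with tie/continuity correction
otherwise — verified against a permutation-enumeration oracle in the
tests). Against the genomic background, four independent negative sets
are analyzed separately and the mean and standard deviation of
$\log_2 FE$ reported; the standard error is also emitted, since published
figures sometimes display SE over the same four replicates. Depletion is
displayed in signed-fold notation ($-1/FE$) at the presentation layer
only; all computation is on $\log_2 FE$. A zero mean in either set yields
an undefined-enrichment sentinel (`NA`) by default — the honest answer for
sparse synthetic runs — with an optional count pseudocount for small
problems. No multiple-testing correction layer is applied; the per-k-mer
P-values are raw rank-sum values by design.

## The spectrum classifier

The 6-mer spectrum kernel is realized as explicit count features: all
4096 words counted by sliding window (forward strand of the given region
by default, with a reverse-complement-collapsing option; the regions being
fixed at 600 bp makes raw counts proportional to densities). A linear SVM
over these features is mathematically identical to the spectrum-kernel
SVM, and makes per-6-mer weight extraction a direct read of the primal
coefficients rather than a kernel-space reconstruction.

`train_linear()` solves the L1-loss (hinge) linear SVM by dual coordinate
descent with the bias absorbed as an augmented regularized feature, in
compiled code. It is deterministic given the seed (which fixes the
coordinate sweep order) and is validated in the tests against two
independent solvers: a box-constrained quadratic program (`kernlab::ipop`)
on the identical formulation to 1e-4, and libsvm (`e1071`) on separable
toys. The soft-margin cost defaults to C = 1 and is exposed; results in
the acceptance runs are insensitive to C across 0.01–10.

Evaluation is stratified 10-fold cross-validation. Per-fold ROC curves
and AUCs come from `pROC`; precision–recall curves and average-precision
AUCs are computed from the ranked scores. Averaged curves are vertical
means over folds on a fixed 101-point grid, evaluating each fold's
*empirical step curve* at the grid points (right-continuous for ROC; the
AP-consistent step for PR). Linear interpolation between staircase
corners was rejected because it systematically inflates the averaged-curve
area on coarse folds; with step evaluation the trapezoidal area of the
averaged ROC tracks the mean per-fold AUC to within 0.01 on the tested
problem sizes. Classifier comparisons use a two-sided paired t-test on
per-fold AUCs; the original analysis never names its comparison test, so
this stand-in is labeled as such in the output.

## TF motif composition

Motif GC content is the probability-weighted expectation
$\frac{1}{L}\sum_i [p_i(G) + p_i(C)]$ and CpG content the expected CG
dinucleotide rate $\frac{1}{L-1}\sum_i p_i(C)\,p_{i+1}(G)$; since the
source analyses do not state whether PWM probabilities or consensus
strings were used, a consensus-counting mode is provided behind a flag and
both are exercised in the tests. TFs are broad when their tissue
specificity score (TSPS; 0 = uniform expression, ~5 = single tissue) is
below 1 and specific at TSPS ≥ 1 (the boundary is specific); a TF complex
takes the greater of its components' scores, since a complex cannot be
expressed more broadly than its most specific member. Whether CpG content
informs expression breadth beyond GC is measured by the squared
semipartial correlation
$sr^2 = R^2(y \sim GC + CpG) - R^2(y \sim GC)$ with the incremental F
statistic $F = sr^2 (n-3)/(1 - R^2_{full})$ on $(1, n-3)$ df, for both a
continuous-TSPS and a broad/specific-dummy response. Exactly collinear
GC/CpG returns $sr^2 = 0$ with a `collinear` flag — a deterministic CpG
adds nothing — rather than an undefined value.

## The synthetic-data generator

The generator emulates the statistical structure the analyses assume,
with one master seed driving fixed per-stage offsets so every stage is
independently reproducible and the catalog is bit-identical for identical
configurations.

* **Genome**: i.i.d. nucleotides at 42% GC by default. Real genomes have
  isochore structure, CpG islands and repeats; none of that is mimicked,
  so passing tests demonstrate correctness of the statistical machinery,
  not performance on real chromatin.
* **Breadth distribution**: 15% of enhancers at breadth 1, and a
  geometric tail over 2–60 contexts whose decay rate is calibrated by
  root finding so the top 5% lie above 45 contexts. Only these two
  anchors of the real distribution are published; the geometric shape is
  a modeling choice and fully overridable.
* **Lengths**: base 200 bp + 2 bp per additional context + Gaussian
  noise (SD 40, truncated at 50 bp), giving the positive length–breadth
  correlation observed in real catalogs with single-context enhancers
  near 200 bp and broad ones near 320 bp.
* **GC–breadth coupling**: each enhancer is locally resampled at
  `background_gc + 0.001 · (breadth − 1)`, i.e. broad-class enhancers at
  ~48% GC. The coupling is implemented by resampling, not by motif
  planting, so GC and motif effects remain separable in tests. The slope
  was fixed at a value that yields a clearly positive GC–breadth
  correlation while keeping GC-matched background sampling feasible on a
  homogeneous synthetic genome (a real genome's GC heterogeneity makes
  matching far easier than an i.i.d. one).
* **Motif planting**: motifs overwrite background bases in place (no
  insertions), non-overlapping within a region, with per-bp densities
  interpolated linearly in breadth between the narrow (breadth 1) and
  broad (cutoff 45) endpoints; the default plants the GC DRM at a 4:1
  broad:narrow density ratio. Placement uses rejection sampling with a
  retry cap, and an infeasibly dense request fails loudly. The default
  densities are deliberately rare (0.0008 per bp in the broad class, 4:1
  over narrow) so that most enhancers carry no planted DRM, as observed
  for real DRMs — which is what makes DRM-only classifiers weak relative
  to full-spectrum ones despite strong fold enrichment. Every planted
  site is recorded in a truth table, and the tests rescan the truth
  positions to confirm exact recovery.
* **TF tables**: 563 TFs (the joined real catalog's size), broad with
  probability 313/563; target motif GC means differ by the configured
  association (defaults give 51% vs 40% for broad vs specific — published
  group means used as simulation parameters, not as claims about real
  data), with per-motif columns mixing a 0.6-weight consensus with a
  0.4-weight GC-split background so the expected motif GC equals its
  target while motifs remain informative.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the pipeline at sizes a
single core handles comfortably: catalogs of 300–4000 enhancers on 0.2–8
Mb genomes, 600 bp regions, 10-fold CV at up to ~2000 × 4096 features,
and 10–30 seed replicates for distributional checks. These are the
package's chosen desk-scale study conditions; the published corpus-scale
numbers (tens of thousands of enhancers against real genomes and motif
databases) depend on external downloads and are deliberately out of
scope, so corpus-scale quantities appear only as directional and ordering
properties here.

Other fixed numerical choices: score lattice 1e-3 bits; strict `P < α`
threshold comparison; DCD solver tolerance 1e-4 on the projected
gradient (1e-6–1e-9 in oracle-comparison tests); rejection caps of 10⁴
placement tries per region (2×10⁵ for hard GC-matching runs) and 10³ per
planted motif; quantile ties in class splitting resolved by the
strict-inequality rule above; centered-resize rounding rightward.

## Known limitations

* The i.i.d. genome understates background autocorrelation; enrichment
  variances on real genomes will be larger than the synthetic replicate
  spreads suggest.
* The paired-fold t-test for AUC differences is approximate (folds share
  training data); it is labeled a stand-in wherever reported.
* `wilcox.test`'s normal approximation is used for large tied count
  vectors, as is standard.
* Palindromic double-counting inflates GC/TA DRM densities by exactly 2×
  relative to single-strand counts; comparisons are unaffected because
  the convention is applied uniformly, but absolute densities should be
  read with the convention in mind.
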