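---
title: "Measuring poly(A)-tail lengths and their coupling to translation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring poly(A)-tail lengths and their coupling to translation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tailkit)
```

## Overview

`tailkit` implements the computational machinery of tail-length sequencing
(TAIL-seq / PAL-seq-style protocols) and of the downstream analyses that
relate a transcript's poly(A)-tail length to its translational efficiency
(TE) and stability: T-signal construction from raw sequencing intensities,
hidden-Markov segmentation of the poly(A) stretch, spike-in normalization
and tag-table summaries, terminal-uridylation profiling, coupling
statistics including a test for comparing dependent correlations, PAL-TRAP
input/eluate enrichment, and half-life estimation from 5EU
metabolic-labeling time courses. A synthetic-data generator with known
ground truth makes each stage testable end to end without any sequencing
data.

This vignette explains the models, their assumptions, the tunable
parameters, and the numerical choices made where the design was genuinely
open. It states no empirical result that the package's tests and
acceptance script do not themselves compute.

## T-signal construction

In these protocols read 2 sequences into the poly(A) tail from the RNA 3'
terminus, so the tail appears as an initial run of T incorporations. For
every cluster, each read-2 channel intensity is divided by that channel's
mean intensity over read-1 cycles 15-50 (per-cluster, per-channel gains),
and the T-signal of a cycle is

    tsignal = normT / (normA + normC + normG).

Choices and edge cases:

* **Negative raw intensities** (possible after the sequencer's background
  subtraction) are clamped to 0 before division, keeping the ratio
  nonnegative without inventing a background model.
* **Zero cycles are missing data.** A zero T-signal is repaired from the
  nearest nonzero cycles: at most 10 and at least 5 of them, expanding
  symmetrically with ties preferring the earlier cycle (the direction of
  "neighboring" is not dictated by the procedure; symmetric nearest-first
  expansion is deterministic and local). Traces with more than five zero
  cycles are discarded (`too-many-zeros`), as are traces with fewer than
  five nonzero cycles available (`unimputable`), and clusters whose
  normalizer is non-positive in any channel (`bad-normalizer`). Imputation
  never modifies nonzero cycles, and discard decisions depend only on zero
  counts and neighbor availability.
* **Log scale for decoding.** The segmentation model's emission means
  include negative values, which the nonnegative intensity ratio cannot
  attain; they are natural on a log scale. `call_tails()` therefore decodes
  `log2(tsignal)`. The synthetic generator closes the loop by drawing
  emission values `s` and manufacturing channel intensities with
  `T = 2^s * (A + C + G)`, so the computed T-signal is exactly `2^s`.
  Imputation, however, averages on the raw ratio scale, keeping the stated
  neighbor-averaging rule literal.

## The forward-only five-state HMM

Tail calling is a segmentation problem: one initiation cycle (state 0), a
strong and a weak poly(A)-tail state (1, 2), then a weak and a strong
non-tail state (3, 4). Reads start in state 0 with probability 1 and states
can only increase along the read, matching the physical layout. The initial
transition matrix and the state-conditional Gaussian emissions are the
published initializations exposed by `hmm_init()`: a single Gaussian per
state for PAL-seq (state means 100, 2, 1, -1, -2; variances 1, 0.5, 0.5,
0.5, 0.5) and a two-component mixture per state for TAIL-seq, in which the
two populations share means and variances across states but trade mixing
weight (0.95/0.05, 0.75/0.25, 0.50/0.50, 0.25/0.75 for states 1-4). The
printed state-0 weight is the same in both populations, so it cannot be
read off directly; the package normalizes weights per state and defaults
state 0 to all mass on population one, completing the complementary pattern
of states 1-4 (overridable via `state0_weight`).

* **Training** (`hmm_train()`) is standard Baum-Welch, computed entirely in
  log space for numerical robustness (emission densities at the initiation
  spike are astronomically small under other states; log-space
  forward-backward cannot underflow to an all-zero cycle). Transitions,
  means, variances and mixture weights are all re-estimated; the start
  distribution is fixed and backward transitions remain structurally zero.
  A variance floor of `1e-4` prevents degenerate spikes on imputed constant
  stretches, and a state receiving essentially no responsibility mass
  (< 1e-8) keeps its previous parameters and is flagged rather than
  producing NaNs. The training set is 1% of retained clusters, clamped to
  [5000, 50000] (`select_training_set()`), and one model is trained per
  library.
* **Decoding** (`call_tails()`) is Viterbi in log space under the
  forward-only constraint, with ties broken toward the lower-numbered
  state (deterministic; favors longer tails only at exact ties). The tail
  length is the number of cycles assigned to states 1 and 2, applied
  literally.
* The mid-run laser-intensity change of the sequencer (after cycle 50 of
  read 2 in high-throughput runs, cycle 101 in rapid runs) is handled
  downstream as a histogram correction, not inside the HMM, mirroring the
  protocol's own remedy.

## Tag tables, normalization and summaries

A poly(A) tag is a read pair identifying a transcript (via read 1) and its
tail length (via read 2). `filter_read2()` implements the protocol
variants: PAL-seq v3 removes the first 14 read-2 bases (constant + barcode
region) before requiring at least five N/T bases among the next six;
TAIL-seq and PAL-seq v4 apply the rule untrimmed.

Spike-in tail-length standards, added at fixed mass per microgram of
sample, anchor abundance comparisons across samples. `size_factors()`
computes per-sample scaling factors by the median-of-ratios estimator over
the standards (counts divided by each standard's geometric mean across
samples, geometric means in log space, standards with any zero count
excluded and logged). With a single sample the factor is 1 by construction;
exact library rescaling is recovered exactly.

`summarize_tails()` reports per-feature median tails only for features with
at least 100 tags (configurable), using the lower-median convention for
even counts (integer-valued output matching rank-based downstream use — the
original procedure does not state whether medians interpolate). Histograms
over tail lengths 0-250 get the protocol's artifact bin (50 for TAIL-seq,
101 for PAL-seq v4) replaced by the mean of its two flanking bins, then
5-nt binning (a final 6-nt bin covers 245-250 nt). Correction precedes
binning, so binned mass equals corrected unbinned mass.

Feature assignment from alignments is out of scope (annotations are
inputs); `assign_3p_features()` is a small strand-aware intersection helper
for BED-like 3'-end annotations, with an antisense mode matching the
`bedtools intersect -S` convention used when read 1 is antisense to the
mRNA.

## Terminal uridylation

Because read 2 starts at the RNA 3' terminus, non-templated uridines appear
as leading `A` calls before the poly(A) `T` stretch. A tag is called
uridylated iff at least one terminal U is present; the count is recorded so
mono- vs oligo-uridylation can be distinguished, but no count threshold is
imposed (none is defined by the procedure). `urid_frequency()` uses tags
with tails of at least 2 nt and reports the uridylated fraction per tail
length, leaving empty strata missing rather than zero.
`terminal_u_profile()` reports per-position U fractions over the first
`k` called bases; the window for "near the terminus" is not dictated, so it
defaults to 2 and is configurable.

## TE and coupling statistics

`compute_te()` counts over the CDS window that excludes the first 15 and
last 5 codons (window floored at one codon if an annotation is malformed),
applies the 30-read RNA-seq expression cutoff (no footprint cutoff), and
forms TE as footprint RPK over RNA RPK. Three normalization modes are
exposed: depth normalization over all passing genes; normalization over
mitochondrial genes only (for absolute comparisons between samples, since
mitochondrial translation is expected to be unaffected by cytosolic
perturbations); and median-centering of log2 TE (relative TEs "centered at
0"). Which mode the original oocyte panels used for the correlations is
not stated, so both are exposed; coupling is measured on ranks, where
per-sample scalar normalizations cancel.

`coupling_correlation()` reports the Spearman correlation between per-gene
median tail and TE over genes passing both the 100-tag and expression
cutoffs, ties mid-ranked.

Two coupling coefficients measured on the same genes in two conditions are
dependent; comparing them uses the modified Dunn and Clark z-test
(`compare_dependent_correlations()`). Both correlations are Fisher-z
transformed and

    z = (z1 - z2) * sqrt((n - 3) / (2 - 2*c)),

where `c` is the Dunn-Clark covariance term computed from the four
cross-correlations with the backfilled mean correlation
`rbar = (r1 + r2)/2` substituted for the two compared correlations (the
2004 modification of the 1969 statistic):

    Psi = 1/2 rbar^2 (r13^2 + r14^2 + r23^2 + r24^2) + r13 r24 + r14 r23
          - rbar (r13 r14 + r23 r24 + r13 r23 + r14 r24),
    c = Psi / (1 - rbar^2)^2.

When all cross-correlations are zero this reduces exactly to the
independent-samples Fisher z statistic, which the tests verify in closed
form; calibration under a dependent equal-coupling null is verified by
simulation (type-I error at the nominal 5% level).

`paltrap_stats()` compares tail lengths between a translating-ribosome IP
eluate and its input. Isoforms need at least 100 tags in *both* fractions;
outputs are per-isoform median pairs and differences, the fractions of
isoforms with longer (and >= 5 nt longer) eluate medians, and pooled
empirical CDFs.

## Half-life estimation from 5EU labeling

Labeled RNA approaches steady state as

    y = C + log2(1 - exp(-k (x - t0))),

with `x` the labeling time (h), `y` the log2 standard-normalized labeled
level, `k` the decay constant (t1/2 = ln 2 / k), `C = log2(S/k)` the log2
plateau, and `t0` a condition-wide offset for label uptake. Counts are
normalized to a 5EU-containing GFP standard; the steady-state level is the
mean of the two normalized input measurements and enters the fit as a
pseudo-observation at x = 9999 h — kept literal rather than substituting
the analytic limit, to reproduce the procedure exactly. Genes whose two
input measurements differ by more than 2-fold (strictly) are excluded.

Fitting uses bounded Levenberg-Marquardt least squares (via `minpack.lm`)
per gene with `C` initialized at `max(y)`, `k` at 0.23, both bounded to
(0, Inf); `t0` is selected on the grid 0.05-0.70 h (step 0.05) by the
smallest mean squared residual pooled over all genes with equal weight per
observation (no per-gene weights are dictated). Observations at `x <= t0`
have no model value; they are penalized with a large fixed negative
plateau (`2^-50` inside the log) rather than producing NaN. Convergence
tolerances (`ftol = ptol = 1e-10`, 200 iterations) are the package's own
choices — only the fitting framework is dictated; a fit whose `k` is
pinned at the lower bound is reported non-converged (the rate is
unidentifiable, e.g. from a lone steady-state observation).

## The synthetic-data generator

The generator (`sim_config()`, `simulate_truth()` and the `simulate_*`
functions) emulates every input with known truth:

* **Per-gene truth.** Median tails and TEs come from a Gaussian copula
  whose latent correlation `2 sin(pi rho/6)` attains the target Spearman
  coupling on ranks; defaults place median tails at 75 +/- 25 nt and the
  coupling at 0.62, the coupled-regime value. Abundances are lognormal
  (log-mean 3), keeping normalized steady-state levels well above 1 so the
  log2 plateau is positive — the regime the bounded fit addresses. Decay
  constants are log-uniform on [0.05, 2] /h (half-lives of roughly 20 min
  to 14 h).
* **Clusters.** Each tag's state path is one initiation cycle, its tail
  length split between states 1 and 2 (state-2 dwell geometric per the
  transition matrix), then states 3 and 4; emission values are drawn from
  the model's own emissions and converted to 4-channel intensities as
  described above, with per-cluster lognormal channel gains so read-1
  normalization is exercised nontrivially, and a configurable fraction of
  zeroed T-channel cycles to exercise imputation.
* **Standards.** Tail lengths {10, 30, 50, 80, 110, 150, 200, 250} nt at
  4% of tags: the defined lengths of the two spike-in sets are specified in
  a prior protocol rather than restated, so the defaults span the calling
  range and are configurable.
* **Time courses.** Counts are Poisson around
  `depth * 2^C * (1 - exp(-k(x - t0)))`, with an optional lognormal
  overdispersion multiplier (no noise model is dictated; Poisson is the
  counting floor), a constant labeled standard row, and two steady-state
  input columns.
* **PAL-TRAP.** Eluate tags are subsampled from input tags with capture
  probability logistic in `beta * tail_length` (`beta = 0` is the
  tail-neutral null), intercept set to a target capture fraction (default
  25%).

What the generator does **not** emulate: optics, phasing, base-calling
errors beyond zero-intensity dropout, library-prep biases, alignment
ambiguity, isoform-level 3'-end heterogeneity within a gene, or
correlations between tail length and expression level. Passing tests
therefore demonstrate correctness of the algorithms under the stated
generative model, not robustness to every artifact of real sequencing data.

## Problem sizes and determinism

The test suite and the acceptance script run at desk scale by design:
20,000 clusters of 260 cycles for tail-call recovery, 5,000 traces for EM
monotonicity, 2,000 genes for coupling recovery, 1,000 replicates for
z-test calibration, 500 genes for noisy half-life recovery, and a
2,000-cluster smoke profile for the end-to-end pipeline. All generators are
pure functions of (config, seed); the pipeline derives per-stage seeds
deterministically from one root seed, and rerunning a configuration
reproduces artifacts byte-identically (verified via checksum manifests).

## Known limitations

* Tail calling is bounded by read length; tails longer than read 2 are
  censored at the trace length (the generator refuses tails within 10
  cycles of the read end for this reason).
* The TAIL-seq mixture emissions overlap heavily between the weak-tail and
  weak-non-tail states; unsupervised training can shift the boundary
  between them, which is why calling-accuracy guarantees are stated for
  the initialization parameters.
* No posterior-marginal tail calling, per-cluster model adaptation, or
  recalibration against the standards is provided (standards serve only
  abundance normalization, as in the protocols).
* The dependent-correlation test treats sample Spearman coefficients like
  Pearson coefficients under Fisher's transform, as its published usage
  does; calibration is verified by simulation at the sizes used here.
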