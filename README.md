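# tailkit

Poly(A)-tail length calling from sequencing intensity traces, and analysis
of how tail length couples to translation and mRNA decay.

## What this is for

In oocytes and early embryos, an mRNA's poly(A)-tail length strongly
influences its translational efficiency (TE); in post-embryonic cells the
coupling disappears. Studying that regime switch requires a measurement and
analysis stack: calling tail lengths per sequencing cluster from raw
four-channel intensities (TAIL-seq / PAL-seq-style protocols), normalizing
tag counts against spike-in tail-length standards, relating per-gene median
tails to ribosome-profiling TE, comparing coupling strength across
conditions, quantifying intragenic enrichment of long-tailed isoforms in
translating-ribosome IPs (PAL-TRAP), profiling terminal uridylation, and
fitting mRNA half-lives from 5EU metabolic-labeling time courses. `tailkit`
implements this stack in R, together with a synthetic-data generator with
known ground truth so every stage is testable without sequencing data.

## The core models

**Tail calling.** For each cluster, the per-cycle T-signal is
`normT / (normA + normC + normG)` with channels normalized by read-1
window means (cycles 15–50); zero cycles are imputed from the nearest
nonzero neighbors (at most 10, at least 5), and clusters with more than
five zero cycles are discarded. A forward-only five-state hidden Markov
model — initiation (0), strong/weak poly(A)-tail (1, 2), weak/strong
non-tail (3, 4), Gaussian (PAL-seq) or two-component Gaussian-mixture
(TAIL-seq) emissions — is trained by Baum–Welch on 1% of retained clusters
(clamped to [5000, 50000]) and decoded by Viterbi in log space. The tail
length is the number of cycles in states 1 and 2.

**Coupling.** TE is footprint RPK over RNA RPK on the CDS window excluding
the first 15 and last 5 codons (30-read RNA cutoff). Coupling is the
Spearman correlation R<sub>s</sub> between per-gene median tail (genes with
≥100 tags) and TE. Two couplings measured on the same genes are compared
with the modified Dunn and Clark z-test,
`z = (z1 − z2)·sqrt((n−3)/(2−2c̄))`, with the covariance term `c̄`
computed from the four cross-correlations using the backfilled mean
correlation.

**Decay.** Labeled RNA follows `y = C + log2(1 − e^(−k(x−t0)))`; per-gene
bounded Levenberg–Marquardt fits (C init `max(y)`, k init 0.23, both in
(0, Inf)) share a `t0` selected on the grid 0.05–0.70 h; the steady state
enters as a pseudo-observation at x = 9999 h, genes with >2-fold
discordant inputs are excluded, and `t1/2 = ln 2 / k`.

## Worked example

```r
library(tailkit)

cfg   <- sim_config(seed = 1, n_genes = 300, coupling_rho = 0.62)
truth <- simulate_truth(cfg)
tags  <- simulate_tags(truth, n_tags = 5000, seed = 2)
model <- hmm_init("palseq")
cl <- simulate_clusters(tags, truth, model,
                        cycles = max(tags$tail_length) + 10L, seed = 3)
ts <- impute_tsignal(compute_tsignal(cl$intensities, cl$read1_means,
                                     cl$cluster_id))
called <- call_tails(model, ts)
keep <- is.na(ts$discarded)
err <- called$calls$tail_length - tags$tail_length[keep]
median(abs(err))                      # 0 nt
mean(abs(err) <= 5)                   # 1  (100% of calls within 5 nt)

cc <- coupling_correlation(
  data.frame(feature_id = truth$genes$gene_id, n_tags = 1000L,
             median_tail = truth$genes$median_tail),
  data.frame(gene_id = truth$genes$gene_id,
             log2_te = log2(truth$genes$te)))
cc$rs                                 # 0.618 over 300 genes

compare_dependent_correlations(0.62, 0.36,
  c(r13 = 0.8, r14 = 0.5, r23 = 0.5, r24 = 0.8), n = 3000)$z   # 20.17
```

This run retains 4789 of 5000 simulated clusters (the rest trip the
zero-cycle QC), calls every retained tail within 5 nt of truth with a
median absolute error of 0 nt, recovers the generator's tail/TE coupling
(R<sub>s</sub> = 0.618 against a target of 0.62), and shows how a drop in
coupling between two conditions measured on the same 3000 genes would be
scored (z = 20.2, p ≈ 2e-90).

The end-to-end driver writes all stage artifacts (TSVs, FASTQ, checksum
manifests) in one call:

```r
run_pipeline(list(seed = 42, n_genes = 200, n_clusters = 2000), "out/")
```

A thin command-line wrapper lives at `inst/scripts/run_pipeline.R`.

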