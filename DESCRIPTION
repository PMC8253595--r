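Package: tailkit
Title: Poly(A)-Tail Length Calling and Tail-Length/Translation Coupling Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring mRNA poly(A)-tail lengths from per-cluster
    sequencing intensity traces and for relating tail length to translation and
    decay. Converts four-channel read-2 intensities into T-signal traces, imputes
    zero cycles, and calls tail lengths with a forward-only five-state Gaussian
    (mixture) hidden Markov model trained by Baum-Welch and decoded by Viterbi.
    Downstream analyses cover spike-in standard (median-of-ratios) normalization
    of poly(A)-tag tables, tail-length histograms with laser-artifact bin
    correction, terminal-uridylation frequency profiles, ribosome-profiling
    translational efficiency, tail-length/efficiency coupling statistics
    including a modified Dunn and Clark z-test for dependent correlations,
    PAL-TRAP input/eluate enrichment summaries, and half-life estimation from
    5EU metabolic-labeling time courses. A synthetic-data generator with known
    ground truth exercises the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    yaml,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
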