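## Poly(A)-tag table construction, filtering, normalization and summaries.

#' Read-2 quality filter (and protocol-specific trimming)
#'
#' PAL-seq v3 reads carry a 14-base constant/barcode region at the start of
#' read 2 that is removed first; TAIL-seq and PAL-seq v4 reads are used
#' untrimmed. A read is kept iff at least `min_nt` of the first 6 remaining
#' bases are `N` or `T` (the expected start of the poly(A) stretch).
#'
#' @param read2 Character vector of read-2 base calls (each >= 20 nt).
#' @param protocol `"tailseq"`, `"palseq_v3"` or `"palseq_v4"`.
#' @param min_nt Minimum combined N/T count among the first 6 bases.
#' @return Data frame `keep` (logical), `trimmed` (character).
#' @export
filter_read2 <- function(read2, protocol = c("tailseq", "palseq_v3",
                                             "palseq_v4"),
                         min_nt = 5L) {
  protocol <- match.arg(protocol)
  stopifnot(all(nchar(read2) >= 20L))
  trimmed <- if (protocol == "palseq_v3") substring(read2, 15L) else read2
  first6 <- substr(trimmed, 1L, 6L)
  nt <- vapply(strsplit(first6, ""), function(b) sum(b %in% c("N", "T")), 1L)
  data.frame(keep = nt >= min_nt, trimmed = trimmed, stringsAsFactors = FALSE)
}

#' Median-of-ratios size factors from spike-in standards
#'
#' For each sample, the scaling factor is the median over standards of
#' `count / geometric mean across samples`, the median-of-ratios estimator.
#' Standards with a zero count in any sample are excluded from the median
#' (their geometric mean is computed in log space and is undefined at zero);
#' the excluded set is attached as an attribute. Normalized counts are
#' `raw / factor`.
#'
#' @param standard_counts Numeric matrix, standards x samples.
#' @return Named numeric vector of per-sample size factors, with attribute
#'   `excluded` listing dropped standards.
#' @export
size_factors <- function(standard_counts) {
  m <- as.matrix(standard_counts)
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  usable <- rowSums(m == 0) == 0
  if (!any(usable)) stop("every standard has a zero count in some sample")
  gm <- apply(m[usable, , drop = FALSE], 1, geomean)
  ratios <- m[usable, , drop = FALSE] / gm
  f <- apply(ratios, 2, median)
  attr(f, "excluded") <- rownames(m)[!usable]
  f
}

#' Tail-length histogram (counts by tail length 0..250)
#'
#' @param tails Integer vector of tail lengths.
#' @param max_tail Largest tail length tracked.
#' @return Integer vector indexed by tail length `0:max_tail` (names are
#'   the tail lengths).
#' @export
tail_histogram <- function(tails, max_tail = 250L) {
  tails <- pmin(tails, max_tail)
  tabulate(tails + 1L, nbins = max_tail + 1L) |>
    setNames(0:max_tail)
}

#' Correct the laser-intensity artifact bin
#'
#' The sequencer raises laser intensities mid-run (after 50 cycles of read 2
#' for TAIL-seq high-throughput runs; after 101 cycles for PAL-seq v4
#' rapid runs), mildly depleting calls at that exact tail length. The
#' affected histogram value is replaced by the mean of its two flanking
#' values. PAL-seq v3 has no corrected bin.
#'
#' @param hist Named numeric vector from [tail_histogram()].
#' @param protocol `"tailseq"`, `"palseq_v3"` or `"palseq_v4"`.
#' @return The corrected histogram.
#' @export
correct_artifact_bin <- function(hist, protocol = c("tailseq", "palseq_v3",
                                                    "palseq_v4")) {
  protocol <- match.arg(protocol)
  bin <- switch(protocol, tailseq = 50L, palseq_v4 = 101L, palseq_v3 = NULL)
  if (is.null(bin)) return(hist)
  i <- match(as.character(bin), names(hist))
  if (!is.na(i) && i > 1L && i < length(hist))
    hist[i] <- mean(c(hist[i - 1L], hist[i + 1L]))
  hist
}

#' 5-nt binning of a tail-length histogram
#'
#' Bins 0-4, 5-9, ..., 240-244 nt plus a terminal 6-nt bin 245-250 nt.
#'
#' @param hist Named numeric vector over tail lengths 0..250.
#' @return Data frame `bin_start, bin_end, count`.
#' @export
bin_tail_histogram <- function(hist) {
  len <- as.integer(names(hist))
  starts <- c(seq(0L, 240L, by = 5L))
  ends <- c(seq(4L, 244L, by = 5L), 250L)
  starts <- c(starts, 245L)
  data.frame(bin_start = starts, bin_end = ends,
             count = vapply(seq_along(starts), function(i)
               sum(hist[len >= starts[i] & len <= ends[i]]), numeric(1)))
}

#' Per-feature median tails and corrected histograms
#'
#' Reports the (lower-)median tail length for features with at least
#' `min_tags` tags, and per-sample tail-length histograms with the
#' protocol's artifact bin corrected and 5-nt binning applied afterwards.
#'
#' @param tags Tag table with `feature_id`, `sample_id`, `tail_length`.
#' @param min_tags Minimum tags per feature for median reporting.
#' @param protocol Protocol label for artifact correction.
#' @param max_tail Largest tail length tracked in histograms.
#' @return List: `medians` (data frame `feature_id, n_tags, median_tail`),
#'   `histograms` (per-sample list with `raw`, `corrected`, `binned`).
#' @export
summarize_tails <- function(tags, min_tags = 100L,
                            protocol = c("tailseq", "palseq_v3", "palseq_v4"),
                            max_tail = 250L) {
  protocol <- match.arg(protocol)
  stopifnot(nrow(tags) > 0)
  counts <- table(tags$feature_id)
  keep <- names(counts)[counts >= min_tags]
  med <- vapply(keep, function(f)
    median_lower(tags$tail_length[tags$feature_id == f]), numeric(1))
  medians <- data.frame(feature_id = keep,
                        n_tags = as.integer(counts[keep]),
                        median_tail = med, stringsAsFactors = FALSE,
                        row.names = NULL)
  histograms <- lapply(split(tags$tail_length, tags$sample_id), function(tl) {
    raw <- tail_histogram(tl, max_tail)
    corrected <- correct_artifact_bin(raw, protocol)
    list(raw = raw, corrected = corrected,
         binned = bin_tail_histogram(corrected))
  })
  list(medians = medians, histograms = histograms)
}

#' Assign tag 3'-end positions to annotated features
#'
#' Intersects point-like tag 3'-end positions with BED-like annotations
#' (0-based, half-open) strand-awareness as in `bedtools intersect`:
#' `same` matches features on the same strand, `antisense` on the opposite
#' strand (the `-S` convention used when read 1 is antisense to the mRNA).
#' Positions hitting no feature or more than one get `NA`.
#'
#' @param positions Data frame `chrom, pos` (0-based), `strand`.
#' @param bed Data frame in BED6 layout: `chrom, start, end, name, score,
#'   strand` (0-based half-open).
#' @param strand_mode `"same"` or `"antisense"`.
#' @return Character vector of feature names (one per position).
#' @export
assign_3p_features <- function(positions, bed,
                               strand_mode = c("same", "antisense")) {
  strand_mode <- match.arg(strand_mode)
  flip <- c(`+` = "-", `-` = "+")
  qstrand <- if (strand_mode == "antisense")
    flip[positions$strand] else positions$strand
  q <- GenomicRanges::GRanges(positions$chrom,
                              IRanges::IRanges(positions$pos + 1L, width = 1L),
                              strand = qstrand)
  s <- GenomicRanges::GRanges(bed$chrom,
                              IRanges::IRanges(bed$start + 1L, bed$end),
                              strand = bed$strand)
  hits <- GenomicRanges::findOverlaps(q, s, ignore.strand = FALSE)
  qh <- S4Vectors::queryHits(hits)
  out <- rep(NA_character_, nrow(positions))
  tab <- tabulate(qh, nbins = nrow(positions))
  uniq <- which(tab == 1L)
  one <- qh %in% uniq
  out[qh[one]] <- bed$name[S4Vectors::subjectHits(hits)[one]]
  out
}
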