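## Translational efficiency, tail-length/TE coupling, dependent-correlation
## comparison, and PAL-TRAP statistics.

#' Compute translational efficiency (TE)
#'
#' TE is footprint reads-per-kilobase over RNA reads-per-kilobase, computed
#' on the CDS counting window that excludes the first 15 and last 5 codons.
#' Genes with fewer than `min_rna_reads` RNA-seq reads are dropped (no
#' cutoff on footprints). Normalization modes:
#' \describe{
#'   \item{`all-genes`}{each library is scaled by its total counts over all
#'     passing genes (depth normalization on the full reference set).}
#'   \item{`mito-only`}{each library is scaled by its total counts over
#'     mitochondrial genes only, so non-mitochondrial TE is expressed
#'     relative to the mitochondrial reference set.}
#'   \item{`median-centered`}{relative TEs: the median log2 TE is
#'     subtracted (manual centering at 0).}
#' }
#'
#' @param rna_counts,fp_counts Named numeric vectors (or single-column
#'   matrices) of RNA-seq and footprint counts per gene.
#' @param cds_lengths CDS length in nt per gene (same order); lengths not
#'   divisible by 3 are floored to codons with a warning, and the counting
#'   window is floored at 1 codon.
#' @param mito_flags Logical; which genes are mitochondrial.
#' @param mode Normalization mode.
#' @param min_rna_reads RNA-seq expression cutoff.
#' @return Data frame `gene_id, rna_rpk, fp_rpk, log2_te` for passing genes.
#' @export
compute_te <- function(rna_counts, fp_counts, cds_lengths, mito_flags,
                       mode = c("all-genes", "mito-only", "median-centered"),
                       min_rna_reads = 30L) {
  mode <- match.arg(mode)
  rna <- as.numeric(rna_counts); fp <- as.numeric(fp_counts)
  gene_id <- names(rna_counts)
  if (is.null(gene_id)) gene_id <- sprintf("g%04d", seq_along(rna))
  stopifnot(length(fp) == length(rna), length(cds_lengths) == length(rna),
            length(mito_flags) == length(rna))
  if (any(cds_lengths %% 3 != 0))
    warning(sum(cds_lengths %% 3 != 0),
            " CDS length(s) not divisible by 3; floored to whole codons")
  window_nt <- 3 * pmax(cds_lengths %/% 3 - 20L, 1L)
  pass <- rna >= min_rna_reads
  if (!any(pass)) stop("no gene passes the RNA-seq expression cutoff")
  scale_set <- switch(mode,
    "mito-only" = pass & mito_flags,
    pass)
  if (mode == "mito-only" && !any(scale_set))
    stop("mito-only normalization requires mitochondrial genes passing the cutoff")
  rna_n <- rna / sum(rna[scale_set])
  fp_n <- fp / sum(fp[scale_set])
  rna_rpk <- rna_n[pass] / (window_nt[pass] / 1000)
  fp_rpk <- fp_n[pass] / (window_nt[pass] / 1000)
  log2_te <- log2(fp_rpk) - log2(rna_rpk)
  if (mode == "median-centered")
    log2_te <- log2_te - median(log2_te[is.finite(log2_te)])
  data.frame(gene_id = gene_id[pass], rna_rpk = rna_rpk, fp_rpk = fp_rpk,
             log2_te = log2_te, stringsAsFactors = FALSE, row.names = NULL)
}

#' Tail-length/TE coupling (Spearman)
#'
#' Inner-joins per-gene median tails (features with at least `min_tags`
#' tags) with a TE table and reports the Spearman rank correlation (ties
#' mid-ranked) with the number of genes used.
#'
#' @param median_tails Data frame `feature_id, n_tags, median_tail` (as
#'   from [summarize_tails()]).
#' @param te_table Data frame `gene_id, log2_te` (as from [compute_te()]).
#' @param min_tags Minimum tags per gene.
#' @return List `rs` (Spearman correlation; `NA` if degenerate), `n`.
#' @export
coupling_correlation <- function(median_tails, te_table, min_tags = 100L) {
  mt <- median_tails[median_tails$n_tags >= min_tags, , drop = FALSE]
  j <- merge(mt, te_table, by.x = "feature_id", by.y = "gene_id")
  if (nrow(j) < 3L) stop("fewer than 3 genes after joining tables")
  if (length(unique(j$median_tail)) < 2L || length(unique(j$log2_te)) < 2L)
    return(list(rs = NA_real_, n = nrow(j)))
  list(rs = cor(j$median_tail, j$log2_te, method = "spearman"), n = nrow(j))
}

#' Modified Dunn and Clark z-test for dependent, nonoverlapping correlations
#'
#' Compares two correlations measured on the same n subjects but between
#' disjoint variable pairs (e.g. tail/TE coupling in two conditions assayed
#' on the same genes): `r1 = cor(x1, y1)` vs `r2 = cor(x2, y2)`. Both are
#' Fisher-z transformed and
#' \deqn{z = (z_1 - z_2) \sqrt{(n-3)/(2 - 2\bar c)}}
#' where \eqn{\bar c} is the Dunn-Clark covariance term evaluated with the
#' backfilled mean correlation \eqn{\bar r = (r_1 + r_2)/2} substituted for
#' both compared correlations (the Silver-Hittner-May modification):
#' \deqn{\bar c = \bar\Psi / (1 - \bar r^2)^2} with
#' \deqn{\bar\Psi = \tfrac12 \bar r^2 (r_{13}^2 + r_{14}^2 + r_{23}^2 +
#'   r_{24}^2) + r_{13} r_{24} + r_{14} r_{23}
#'   - \bar r (r_{13} r_{14} + r_{23} r_{24} + r_{13} r_{23} +
#'   r_{14} r_{24}).}
#' With all cross-correlations zero this reduces to the independent-samples
#' Fisher z statistic.
#'
#' @param r1,r2 The two correlations, each in (-1, 1).
#' @param r_cross The four cross-correlations, in the order `r13 =
#'   cor(x1, x2)`, `r14 = cor(x1, y2)`, `r23 = cor(y1, x2)`, `r24 =
#'   cor(y1, y2)` (names, if present, are honored).
#' @param n Number of subjects shared by the two correlations (`> 5`).
#' @return List `z`, `p` (two-sided), `c_bar`.
#' @export
compare_dependent_correlations <- function(r1, r2, r_cross, n) {
  stopifnot(length(r_cross) == 4L, n > 5)
  if (any(abs(c(r1, r2)) >= 1) || any(abs(r_cross) >= 1))
    stop("correlations must lie strictly within (-1, 1)")
  if (!is.null(names(r_cross)))
    r_cross <- r_cross[c("r13", "r14", "r23", "r24")]
  r13 <- r_cross[[1]]; r14 <- r_cross[[2]]
  r23 <- r_cross[[3]]; r24 <- r_cross[[4]]
  rbar <- (r1 + r2) / 2
  psi <- 0.5 * rbar^2 * (r13^2 + r14^2 + r23^2 + r24^2) +
    r13 * r24 + r14 * r23 -
    rbar * (r13 * r14 + r23 * r24 + r13 * r23 + r14 * r24)
  c_bar <- psi / (1 - rbar^2)^2
  z1 <- atanh(r1); z2 <- atanh(r2)
  z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * c_bar))
  list(z = z, p = 2 * pnorm(-abs(z)), c_bar = c_bar)
}

#' PAL-TRAP input/eluate statistics
#'
#' For mRNA isoforms represented by at least `min_tags` poly(A) tags in
#' both the input and the eluate, reports per-isoform median tail lengths
#' and their difference (eluate - input), the fraction of isoforms with a
#' longer eluate median, the fraction longer by at least `long_diff` nt,
#' and pooled tail-length empirical CDFs.
#'
#' @param input_tags,eluate_tags Tag tables (`feature_id, tail_length`,
#'   optionally `is_standard`; standards are excluded).
#' @param min_tags Minimum tags per isoform in each fraction.
#' @param long_diff Threshold (nt) for the "much longer" fraction.
#' @return List: `isoforms` (data frame `feature_id, n_input, n_eluate,
#'   median_input, median_eluate, diff`), `frac_longer`,
#'   `frac_longer_by_5`, `ecdf_input`, `ecdf_eluate`, `median_input_pooled`,
#'   `median_eluate_pooled`.
#' @export
paltrap_stats <- function(input_tags, eluate_tags, min_tags = 100L,
                          long_diff = 5L) {
  stopifnot(nrow(input_tags) > 0, nrow(eluate_tags) > 0)
  drop_std <- function(t) if ("is_standard" %in% names(t))
    t[!t$is_standard, , drop = FALSE] else t
  input_tags <- drop_std(input_tags); eluate_tags <- drop_std(eluate_tags)
  ci <- table(input_tags$feature_id); ce <- table(eluate_tags$feature_id)
  feats <- intersect(names(ci)[ci >= min_tags], names(ce)[ce >= min_tags])
  med_in <- vapply(feats, function(f)
    median_lower(input_tags$tail_length[input_tags$feature_id == f]),
    numeric(1))
  med_el <- vapply(feats, function(f)
    median_lower(eluate_tags$tail_length[eluate_tags$feature_id == f]),
    numeric(1))
  iso <- data.frame(feature_id = feats,
                    n_input = as.integer(ci[feats]),
                    n_eluate = as.integer(ce[feats]),
                    median_input = med_in, median_eluate = med_el,
                    diff = med_el - med_in,
                    stringsAsFactors = FALSE, row.names = NULL)
  list(isoforms = iso,
       frac_longer = if (nrow(iso)) mean(iso$diff > 0) else NA_real_,
       frac_longer_by_5 = if (nrow(iso)) mean(iso$diff >= long_diff) else NA_real_,
       ecdf_input = ecdf(input_tags$tail_length),
       ecdf_eluate = ecdf(eluate_tags$tail_length),
       median_input_pooled = median_lower(input_tags$tail_length),
       median_eluate_pooled = median_lower(eluate_tags$tail_length))
}
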