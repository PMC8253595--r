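## T-signal construction and QC.
##
## The T-signal of a cycle is the read-1-normalized T-channel intensity
## divided by the sum of the normalized intensities of the other three
## channels; it is high within the poly(A) stretch of read 2. Cycles whose
## T-signal is exactly zero are treated as missing and repaired from
## neighboring cycles; clusters with too many zero cycles are discarded.

CHANNELS <- c("A", "C", "G", "T")

#' Per-channel read-1 normalizer means
#'
#' Averages each channel's read-1 intensities over a cycle window
#' (positions 15-50, 1-based inclusive, by default) to obtain the
#' per-cluster, per-channel normalization factors for read 2.
#'
#' @param read1 Numeric array `clusters x cycles x 4` (channels A,C,G,T).
#' @param window Integer length-2 vector, first and last cycle of the
#'   normalization window (clamped to the available cycles).
#' @return Numeric matrix `clusters x 4`.
#' @export
read1_window_means <- function(read1, window = c(15L, 50L)) {
  stopifnot(length(dim(read1)) == 3L, dim(read1)[3] == 4L)
  w <- max(1L, window[1]):min(dim(read1)[2], window[2])
  out <- apply(read1[, w, , drop = FALSE], c(1, 3), mean)
  colnames(out) <- CHANNELS
  out
}

#' Compute T-signal traces from read-2 intensities
#'
#' Divides each read-2 channel intensity by its cluster's read-1 window mean
#' and forms, for every cycle, `normT / (normA + normC + normG)`. Negative
#' raw intensities are clamped to 0 before division. Clusters whose
#' normalizer is non-positive in any channel are discarded with reason
#' `"bad-normalizer"`. A cycle whose T-signal is 0 (or whose denominator is
#' 0) is left at 0, to be repaired by [impute_tsignal()].
#'
#' @param intensities Numeric array `clusters x cycles x 4` of raw read-2
#'   intensities, channels ordered A,C,G,T.
#' @param read1_means Numeric matrix `clusters x 4` of read-1 window means.
#' @param cluster_id Optional cluster identifiers.
#' @return A `tsignal_set`: list with `cluster_id`, `tsignal` (matrix,
#'   clusters x cycles), `imputed` (logical matrix), and `discarded`
#'   (character; `NA` for retained clusters, else the reason).
#' @export
compute_tsignal <- function(intensities, read1_means, cluster_id = NULL) {
  stopifnot(length(dim(intensities)) == 3L, dim(intensities)[3] == 4L,
            nrow(read1_means) == dim(intensities)[1])
  n <- dim(intensities)[1]; T_ <- dim(intensities)[2]
  if (T_ < 1L) stop("intensity matrix must have at least one cycle")
  if (is.null(cluster_id)) cluster_id <- sprintf("cl%06d", seq_len(n))
  discarded <- rep(NA_character_, n)
  discarded[apply(read1_means <= 0, 1, any)] <- "bad-normalizer"
  x <- pmax(intensities, 0)
  norm <- sweep(x, c(1, 3), read1_means, "/")
  denom <- norm[, , 1] + norm[, , 2] + norm[, , 3]
  denom <- matrix(denom, n, T_)
  tnum <- matrix(norm[, , 4], n, T_)
  tsig <- ifelse(denom > 0, tnum / denom, 0)
  tsig[!is.na(discarded), ] <- NA_real_
  structure(list(cluster_id = cluster_id, tsignal = tsig,
                 imputed = matrix(FALSE, n, T_), discarded = discarded),
            class = "tsignal_set")
}

# deterministic nearest-first neighbor selection: among nonzero cycles,
# order by |distance| with ties preferring the earlier cycle
nearest_nonzero <- function(pos, nonzero_pos, k) {
  d <- abs(nonzero_pos - pos)
  nonzero_pos[order(d, nonzero_pos)][seq_len(min(k, length(nonzero_pos)))]
}

#' Impute zero T-signal cycles
#'
#' For each zero cycle of a trace, substitutes the mean of the nearest
#' nonzero cycles' T-signal values, taking at most `max_neighbors` (default
#' 10) and requiring at least `min_neighbors` (default 5) to exist in the
#' trace. A cluster with more than `max_zero_cycles` (default 5) zero cycles
#' is discarded with reason `"too-many-zeros"`; one without enough nonzero
#' neighbors is discarded with reason `"unimputable"`. Neighbor means always
#' use the original nonzero values, never previously imputed ones.
#'
#' @param ts A `tsignal_set` from [compute_tsignal()].
#' @param max_neighbors,min_neighbors,max_zero_cycles Imputation limits.
#' @return The `tsignal_set` with zeros imputed, `imputed` flags set, and
#'   discard reasons filled in.
#' @export
impute_tsignal <- function(ts, max_neighbors = 10L, min_neighbors = 5L,
                           max_zero_cycles = 5L) {
  stopifnot(inherits(ts, "tsignal_set"))
  n <- nrow(ts$tsignal)
  for (i in seq_len(n)) {
    if (!is.na(ts$discarded[i])) next
    v <- ts$tsignal[i, ]
    zero <- which(v == 0)
    if (!length(zero)) next
    if (length(zero) > max_zero_cycles) {
      ts$discarded[i] <- "too-many-zeros"
      next
    }
    nonzero <- which(v != 0)
    if (length(nonzero) < min_neighbors) {
      ts$discarded[i] <- "unimputable"
      next
    }
    for (p in zero) {
      nb <- nearest_nonzero(p, nonzero, max_neighbors)
      ts$tsignal[i, p] <- mean(v[nb])
      ts$imputed[i, p] <- TRUE
    }
  }
  ts
}

#' Discard-log summary of a tsignal_set
#'
#' @param ts A `tsignal_set`.
#' @return Data frame of `cluster_id` and `reason` for discarded clusters.
#' @export
discard_log <- function(ts) {
  bad <- !is.na(ts$discarded)
  data.frame(cluster_id = ts$cluster_id[bad], reason = ts$discarded[bad],
             stringsAsFactors = FALSE)
}

#' Long-format export of a tsignal_set
#'
#' @param ts A `tsignal_set`.
#' @return Data frame `cluster_id, cycle, tsignal, imputed` for retained
#'   clusters.
#' @export
tsignal_long <- function(ts) {
  keep <- which(is.na(ts$discarded))
  T_ <- ncol(ts$tsignal)
  data.frame(
    cluster_id = rep(ts$cluster_id[keep], each = T_),
    cycle = rep(seq_len(T_), times = length(keep)),
    tsignal = as.vector(t(ts$tsignal[keep, , drop = FALSE])),
    imputed = as.vector(t(ts$imputed[keep, , drop = FALSE])),
    stringsAsFactors = FALSE)
}
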