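## 5EU metabolic-labeling half-life estimation.
##
## Labeled RNA of a gene with decay constant k approaches its steady-state
## level along y = C + log2(1 - exp(-k (x - t0))), where x is the labeling
## time (h), y the log2 standard-normalized labeled level, C the log2
## plateau (C = log2(S / k) for synthesis rate S), and t0 a condition-wide
## time offset. The steady-state measurement enters the fit as a
## pseudo-observation at x = 9999 h.

STEADY_STATE_TIME <- 9999

# model value in log2 space; x <= t0 (or a non-positive saturation term)
# yields a large negative value acting as the documented penalty residual
decay_model_y <- function(x, C, k, t0, floor_log2 = -50) {
  C + log2(pmax(1 - exp(-k * (x - t0)), 2^floor_log2))
}

#' Normalize a labeling time course to the spike-in standard
#'
#' Divides each library's counts by the 5EU-containing standard's count in
#' that library, forms the steady-state level as the mean of the two
#' normalized input measurements, and assembles per-gene observation series
#' (y = log2 normalized level) including the steady-state pseudo-observation
#' at `x = 9999` h. Zero labeled counts give undefined y and are dropped
#' with a log entry.
#'
#' @param labeled Count matrix (genes + standard) x timepoints.
#' @param input Count matrix (genes + standard) x 2 steady-state inputs.
#' @param times Labeling times (h) matching `labeled`'s columns.
#' @param standard_id Row name of the standard.
#' @return List: `series` (data frame `gene_id, x, y`), `steady` (data
#'   frame `gene_id, input_1, input_2, y_steady`), `dropped` (data frame
#'   `gene_id, x` of zero-count observations).
#' @export
normalize_timecourse <- function(labeled, input, times,
                                 standard_id = "std_gfp") {
  stopifnot(standard_id %in% rownames(labeled),
            standard_id %in% rownames(input),
            ncol(labeled) == length(times), ncol(input) == 2L)
  std_l <- labeled[standard_id, ]
  std_i <- input[standard_id, ]
  if (any(std_l <= 0) || any(std_i <= 0))
    stop("standard count must be positive at every timepoint")
  genes <- setdiff(rownames(labeled), standard_id)
  norm_l <- sweep(labeled[genes, , drop = FALSE], 2, std_l, "/")
  norm_i <- sweep(input[genes, , drop = FALSE], 2, std_i, "/")
  steady_level <- rowMeans(norm_i)
  long <- data.frame(gene_id = rep(genes, times = length(times)),
                     x = rep(times, each = length(genes)),
                     level = as.vector(norm_l), stringsAsFactors = FALSE)
  dropped <- long[long$level <= 0, c("gene_id", "x")]
  long <- long[long$level > 0, , drop = FALSE]
  series <- rbind(
    data.frame(gene_id = long$gene_id, x = long$x, y = log2(long$level),
               stringsAsFactors = FALSE),
    data.frame(gene_id = genes[steady_level > 0],
               x = STEADY_STATE_TIME,
               y = log2(steady_level[steady_level > 0]),
               stringsAsFactors = FALSE))
  steady <- data.frame(gene_id = genes, input_1 = norm_i[, 1],
                       input_2 = norm_i[, 2],
                       y_steady = ifelse(steady_level > 0,
                                         log2(steady_level), NA_real_),
                       stringsAsFactors = FALSE, row.names = NULL)
  list(series = series, steady = steady, dropped = dropped)
}

#' Steady-state consistency filter
#'
#' Excludes genes whose two steady-state input measurements differ by more
#' than `max_fold` (strictly; a ratio of exactly `max_fold` is retained).
#' Genes with a zero input at either point are excluded with reason
#' `"zero-input"`.
#'
#' @param norm Output of [normalize_timecourse()].
#' @param max_fold Fold-change threshold (default 2).
#' @return `norm` with filtered `series`/`steady`, plus `excluded` (data
#'   frame `gene_id, reason`).
#' @export
steady_state_filter <- function(norm, max_fold = 2) {
  s <- norm$steady
  hi <- pmax(s$input_1, s$input_2); lo <- pmin(s$input_1, s$input_2)
  zero <- lo <= 0
  fold_bad <- !zero & (hi / lo > max_fold)
  excluded <- rbind(
    data.frame(gene_id = s$gene_id[zero],
               reason = rep("zero-input", sum(zero)),
               stringsAsFactors = FALSE),
    data.frame(gene_id = s$gene_id[fold_bad],
               reason = rep("fold-change", sum(fold_bad)),
               stringsAsFactors = FALSE))
  keep <- s$gene_id[!(zero | fold_bad)]
  norm$steady <- s[s$gene_id %in% keep, , drop = FALSE]
  norm$series <- norm$series[norm$series$gene_id %in% keep, , drop = FALSE]
  norm$excluded <- excluded
  norm
}

#' Fit the labeling-kinetics model for one gene
#'
#' Bounded Levenberg-Marquardt least squares of
#' `y = C + log2(1 - exp(-k (x - t0)))` at a fixed `t0`, with `C`
#' initialized at `max(y)`, `k` at 0.23, and both bounded to (0, Inf).
#'
#' @param x,y Observations (including the steady-state pseudo-observation).
#' @param t0 Time offset (h).
#' @param k_init Initial decay constant.
#' @return List `C, k, converged, sse, n_obs`.
#' @export
fit_decay_gene <- function(x, y, t0, k_init = 0.23) {
  if (length(x) < 2L)
    return(list(C = max(y), k = NA_real_, converged = FALSE,
                sse = NA_real_, n_obs = length(x)))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ decay_model_y(x, C, k, t0),
      data = data.frame(x = x, y = y),
      start = list(C = max(y), k = k_init),
      lower = c(1e-9, 1e-9), upper = c(Inf, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10,
                                           ptol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(C = NA_real_, k = NA_real_, converged = FALSE,
                sse = NA_real_, n_obs = length(x)))
  co <- stats::coef(fit)
  conv <- fit$convInfo$isConv %||% TRUE
  # a k pinned to the lower bound means the decay rate is unidentifiable
  if (co[["k"]] <= 1e-8) conv <- FALSE
  list(C = co[["C"]], k = co[["k"]], converged = isTRUE(conv),
       sse = sum(stats::resid(fit)^2), n_obs = length(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a labeling condition: shared t0 grid search plus per-gene fits
#'
#' Varies `t0` over a grid (0.05 to 0.70 h in steps of 0.05 by default),
#' fits every gene at each candidate, selects the `t0` minimizing the mean
#' squared residual of y pooled over all genes' observations (equal weight
#' per observation), and refits at the winner. Half-lives are
#' `t1/2 = ln 2 / k`; the synthesis-rate scale is `S = k 2^C`. Genes whose
#' optimizer fails to converge are flagged and excluded from summaries.
#'
#' @param norm Output of [normalize_timecourse()] (usually after
#'   [steady_state_filter()]).
#' @param t0_grid Candidate time offsets (h).
#' @return List: `t0` (selected), `fits` (data frame `gene_id, C, k, t0,
#'   t_half, S, converged, sse, n_obs`), `grid` (data frame `t0, mse`).
#' @export
fit_condition <- function(norm, t0_grid = seq(0.05, 0.70, by = 0.05)) {
  series <- norm$series
  sp <- split(series[c("x", "y")], series$gene_id)
  grid_mse <- vapply(t0_grid, function(t0) {
    res <- lapply(sp, function(d) fit_decay_gene(d$x, d$y, t0))
    sse <- vapply(res, function(r) r$sse, numeric(1))
    nob <- vapply(res, function(r) r$n_obs, numeric(1))
    ok <- is.finite(sse)
    sum(sse[ok]) / sum(nob[ok])
  }, numeric(1))
  t0_star <- t0_grid[which.min(grid_mse)]
  res <- lapply(sp, function(d) fit_decay_gene(d$x, d$y, t0_star))
  fits <- data.frame(
    gene_id = names(sp),
    C = vapply(res, function(r) r$C, numeric(1)),
    k = vapply(res, function(r) r$k, numeric(1)),
    t0 = t0_star,
    t_half = log(2) / vapply(res, function(r) r$k, numeric(1)),
    S = vapply(res, function(r) r$k * 2^r$C, numeric(1)),
    converged = vapply(res, function(r) r$converged, logical(1)),
    sse = vapply(res, function(r) r$sse, numeric(1)),
    n_obs = vapply(res, function(r) r$n_obs, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(t0 = t0_star, fits = fits,
       grid = data.frame(t0 = t0_grid, mse = grid_mse))
}
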