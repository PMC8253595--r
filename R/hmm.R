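## Forward-only five-state Gaussian (mixture) HMM for T-signal segmentation.
##
## States: 0 initiation, 1 strong poly(A) tail, 2 weak poly(A) tail,
## 3 weak non-tail, 4 strong non-tail. Every read starts in state 0 and
## transitions may only move forward (non-decreasing state index), matching
## the physical layout of read 2: one initiation cycle, the poly(A) stretch,
## then the 3'-UTR. The model operates on log2-transformed T-signal.

#' Construct a forward-only Gaussian-mixture HMM
#'
#' @param transition 5x5 row-stochastic matrix; entries below the diagonal
#'   must be zero (forward-only structure).
#' @param means,vars,weights 5xK matrices of per-state Gaussian component
#'   parameters (K = 1 for a single-Gaussian model). `weights` rows must sum
#'   to 1; `vars` must be positive wherever the weight is positive.
#' @return An object of class `tail_hmm`.
#' @seealso [hmm_init()] for the published initializations.
#' @export
tail_hmm <- function(transition, means, vars, weights = NULL) {
  transition <- as.matrix(transition)
  means <- as.matrix(means)
  vars <- as.matrix(vars)
  if (is.null(weights)) weights <- matrix(1, nrow(means), 1L)
  weights <- as.matrix(weights)
  stopifnot(identical(dim(transition), c(5L, 5L)),
            nrow(means) == 5L,
            identical(dim(means), dim(vars)),
            identical(dim(means), dim(weights)))
  if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-9))
    stop("transition matrix must be row-stochastic")
  if (any(transition[lower.tri(transition)] > 0))
    stop("backward transitions are not allowed")
  if (any(weights < 0) || any(abs(rowSums(weights) - 1) > 1e-9))
    stop("component weights must be nonnegative and sum to 1 per state")
  if (any(vars[weights > 0] <= 0))
    stop("variances must be positive")
  structure(list(transition = transition, means = means, vars = vars,
                 weights = weights),
            class = "tail_hmm")
}

#' Published model initializations
#'
#' Returns the initial transition matrix and emission parameters used for
#' T-signal segmentation. The transition matrix is shared by both protocols.
#' `palseq` (aliases `palseq_v3`, `palseq_v4`) uses one Gaussian per state;
#' `tailseq` uses a two-component mixture per state in which the two
#' populations share means/variances across states but trade mixing weight.
#' The printed tailseq weight for state 0 reads 1.00 in both populations;
#' weights are taken as (`state0_weight`, 1 - `state0_weight`), default all
#' mass on population one, completing the complementary pattern of states
#' 1-4.
#'
#' @param protocol `"tailseq"` or `"palseq"` (or a `palseq_v*` alias).
#' @param state0_weight Population-one mixing weight for state 0 of the
#'   tailseq model.
#' @return A [tail_hmm()] object.
#' @export
hmm_init <- function(protocol = c("tailseq", "palseq", "palseq_v3", "palseq_v4"),
                     state0_weight = 1) {
  protocol <- match.arg(protocol)
  transition <- matrix(c(
    0.04, 0.93, 0.02, 0.01, 0.00,
    0.00, 0.94, 0.03, 0.02, 0.01,
    0.00, 0.00, 0.50, 0.40, 0.10,
    0.00, 0.00, 0.00, 0.60, 0.40,
    0.00, 0.00, 0.00, 0.00, 1.00), 5L, 5L, byrow = TRUE)
  if (protocol == "tailseq") {
    w1 <- c(state0_weight, 0.95, 0.75, 0.50, 0.25)
    means <- cbind(c(100.00, 1.50, 1.50, 1.50, 1.50),
                   c(0.00, -1.00, -1.00, -1.00, -1.00))
    vars <- cbind(c(1.00, 1.50, 1.50, 1.50, 1.50),
                  c(1.00, 1.50, 1.50, 1.50, 1.50))
    weights <- cbind(w1, 1 - w1)
  } else {
    means <- cbind(c(100.0, 2.0, 1.0, -1.0, -2.0))
    vars <- cbind(c(1.0, 0.5, 0.5, 0.5, 0.5))
    weights <- cbind(rep(1, 5))
  }
  tail_hmm(transition, means, vars, weights)
}

#' Pick an unsupervised training set
#'
#' Samples 1\% of the retained clusters, clamped to the interval
#' \[5000, 50000\] (and never more than are available), uniformly without
#' replacement.
#'
#' @param x Either a vector of cluster identifiers or a single count.
#' @param seed Integer seed.
#' @return If `x` is a vector, a subset of it; if a count, a vector of
#'   indices into `1:x`.
#' @export
select_training_set <- function(x, seed) {
  n <- if (length(x) == 1L && is.numeric(x)) as.numeric(x) else length(x)
  if (n < 1) stop("empty input")
  size <- training_set_size(n)
  idx <- with_seed(seed, sample.int(n, size, replace = FALSE))
  if (length(x) == 1L && is.numeric(x)) idx else x[idx]
}

#' @rdname select_training_set
#' @param n Number of retained clusters.
#' @export
training_set_size <- function(n) {
  as.integer(min(n, max(5000, min(50000, round(0.01 * n)))))
}

# per-state mixture log-density for one cycle's values (vector) -> n x 5
emission_loglik <- function(model, x) {
  n <- length(x)
  K <- ncol(model$means)
  out <- matrix(-Inf, n, 5L)
  for (s in 1:5) {
    comp <- matrix(-Inf, n, K)
    for (k in seq_len(K)) {
      w <- model$weights[s, k]
      if (w > 0)
        comp[, k] <- log(w) +
          dnorm(x, model$means[s, k], sqrt(model$vars[s, k]), log = TRUE)
    }
    out[, s] <- if (K == 1L) comp[, 1L] else row_logsumexp(comp)
  }
  out
}

# split rows of a matrix (or list of traces) into equal-length blocks
as_trace_matrix <- function(x) {
  if (is.matrix(x)) return(list(list(X = x, rows = seq_len(nrow(x)))))
  stopifnot(is.list(x))
  lens <- vapply(x, length, 1L)
  lapply(split(seq_along(x), lens), function(rows) {
    list(X = do.call(rbind, x[rows]), rows = rows)
  })
}

#' Viterbi decoding under the forward-only model
#'
#' Decodes the most likely non-decreasing state path for each trace, in log
#' space. Ties are broken toward the lower-numbered state.
#'
#' @param model A [tail_hmm()] object.
#' @param x Matrix of log2 T-signal values (traces in rows) or a list of
#'   numeric traces of possibly different lengths.
#' @return A list with `states` (integer matrix or list, states coded 0-4)
#'   and `loglik` (per-trace path log-likelihood, nats).
#' @export
hmm_viterbi <- function(model, x) {
  blocks <- as_trace_matrix(x)
  n_all <- if (is.matrix(x)) nrow(x) else length(x)
  states <- vector("list", n_all)
  loglik <- numeric(n_all)
  for (b in blocks) {
    res <- viterbi_block(model, b$X)
    for (i in seq_along(b$rows)) states[[b$rows[i]]] <- res$states[i, ]
    loglik[b$rows] <- res$loglik
  }
  if (is.matrix(x)) states <- do.call(rbind, states)
  list(states = states, loglik = loglik)
}

viterbi_block <- function(model, X) {
  n <- nrow(X); T_ <- ncol(X)
  lt <- suppressWarnings(log(model$transition))
  allowed <- lapply(1:5, function(j) 1:j)  # forward-only structure
  delta <- matrix(-Inf, n, 5L)
  delta[, 1L] <- emission_loglik(model, X[, 1L])[, 1L]  # start state 0 w.p. 1
  psi <- array(1L, dim = c(n, T_, 5L))
  if (T_ > 1L) for (t in 2:T_) {
    B <- emission_loglik(model, X[, t])
    newdelta <- matrix(-Inf, n, 5L)
    for (j in 1:5) {
      best <- rep(-Inf, n); arg <- rep(1L, n)
      for (i in allowed[[j]]) {
        sc <- delta[, i] + lt[i, j]
        upd <- sc > best        # strict: ties keep the earlier (lower) state
        best[upd] <- sc[upd]; arg[upd] <- i
      }
      newdelta[, j] <- best + B[, j]
      psi[, t, j] <- arg
    }
    delta <- newdelta
  }
  end <- max.col(delta, ties.method = "first")
  loglik <- delta[cbind(seq_len(n), end)]
  states <- matrix(0L, n, T_)
  states[, T_] <- end
  if (T_ > 1L) for (t in (T_ - 1L):1L)
    states[, t] <- psi[cbind(seq_len(n), t + 1L, states[, t + 1L])]
  list(states = states - 1L, loglik = loglik)
}

#' Baum-Welch training
#'
#' Unsupervised EM training of transitions, component means, variances, and
#' mixture weights. The start distribution (all mass on state 0) is fixed and
#' structural zeros of the transition matrix (backward moves) remain exactly
#' zero. Computation is in log space; the total log-likelihood is
#' non-decreasing across iterations up to numerical tolerance.
#'
#' @param model A [tail_hmm()] object.
#' @param x Matrix of log2 T-signal traces (rows) or list of traces.
#' @param max_iter Maximum EM iterations; `0` returns the model unchanged.
#' @param tol Relative total log-likelihood change below which EM stops.
#' @param var_floor Variance floor applied after each M step.
#' @return List with `model`, `loglik` (one total per iteration), `iterations`
#'   and `flags` (per-state starvation flags).
#' @export
hmm_train <- function(model, x, max_iter = 50L, tol = 1e-6, var_floor = 1e-4) {
  blocks <- as_trace_matrix(x)
  logliks <- numeric(0)
  flags <- rep(FALSE, 5L)
  if (max_iter < 1L)
    return(list(model = model, loglik = logliks, iterations = 0L, flags = flags))
  K <- ncol(model$means)
  amask <- model$transition > 0
  for (iter in seq_len(max_iter)) {
    # accumulators
    trans_num <- matrix(0, 5L, 5L)
    sw <- matrix(0, 5L, K)   # component responsibility mass
    sx <- matrix(0, 5L, K)
    sxx <- matrix(0, 5L, K)
    total_ll <- 0
    for (b in blocks) {
      st <- fb_block(model, b$X)
      total_ll <- total_ll + st$loglik
      trans_num <- trans_num + st$trans_num
      sw <- sw + st$sw; sx <- sx + st$sx; sxx <- sxx + st$sxx
    }
    logliks <- c(logliks, total_ll)
    # M step
    newtrans <- model$transition
    for (i in 1:5) {
      rs <- sum(trans_num[i, ])
      if (rs > 0) newtrans[i, ] <- trans_num[i, ] / rs
    }
    newtrans[!amask] <- 0
    newtrans <- newtrans / rowSums(newtrans)
    means <- model$means; vars <- model$vars; weights <- model$weights
    for (s in 1:5) {
      tot <- sum(sw[s, ])
      if (tot < 1e-8) { flags[s] <- TRUE; vars[s, ] <- pmax(vars[s, ], var_floor); next }
      for (k in seq_len(K)) {
        if (model$weights[s, k] <= 0) next   # structurally absent component
        if (sw[s, k] < 1e-8) { flags[s] <- TRUE; next }
        mu <- sx[s, k] / sw[s, k]
        v <- sxx[s, k] / sw[s, k] - mu^2
        means[s, k] <- mu
        vars[s, k] <- max(v, var_floor)
      }
      if (K > 1L) {
        w <- sw[s, ] * (model$weights[s, ] > 0)
        weights[s, ] <- w / sum(w)
      }
    }
    model <- tail_hmm(newtrans, means, vars, weights)
    if (iter > 1L) {
      prev <- logliks[iter - 1L]
      if (abs(total_ll - prev) <= tol * abs(prev)) break
    }
  }
  list(model = model, loglik = logliks, iterations = length(logliks),
       flags = flags)
}

# forward-backward sufficient statistics for one equal-length block
fb_block <- function(model, X) {
  n <- nrow(X); T_ <- ncol(X)
  K <- ncol(model$means)
  lt <- suppressWarnings(log(model$transition))
  allowed_from <- lapply(1:5, function(j) 1:j)   # forward-only structure
  allowed_to <- lapply(1:5, function(i) i:5)
  logB <- vector("list", T_)
  for (t in seq_len(T_)) logB[[t]] <- emission_loglik(model, X[, t])
  # forward
  la <- vector("list", T_)
  a1 <- matrix(-Inf, n, 5L); a1[, 1L] <- logB[[1L]][, 1L]
  la[[1L]] <- a1
  if (T_ > 1L) for (t in 2:T_) {
    at <- matrix(-Inf, n, 5L)
    prev <- la[[t - 1L]]
    for (j in 1:5) {
      cand <- vapply(allowed_from[[j]], function(i) prev[, i] + lt[i, j],
                     numeric(n))
      cand <- matrix(cand, nrow = n)
      at[, j] <- row_logsumexp(cand) + logB[[t]][, j]
    }
    la[[t]] <- at
  }
  ll_i <- row_logsumexp(la[[T_]])
  # backward
  lb_next <- matrix(0, n, 5L)
  trans_num <- matrix(0, 5L, 5L)
  sw <- matrix(0, 5L, K); sx <- matrix(0, 5L, K); sxx <- matrix(0, 5L, K)
  # walk backward, accumulating xi and gamma as we go
  for (t in T_:1L) {
    if (t < T_) {
      lb <- matrix(-Inf, n, 5L)
      for (i in 1:5) {
        cand <- vapply(allowed_to[[i]], function(j)
          lt[i, j] + logB[[t + 1L]][, j] + lb_next[, j], numeric(n))
        cand <- matrix(cand, nrow = n)
        lb[, i] <- row_logsumexp(cand)
      }
      # xi accumulation for transitions t -> t+1
      for (i in 1:5) for (j in allowed_to[[i]]) {
        if (model$transition[i, j] == 0) next
        lxi <- la[[t]][, i] + lt[i, j] + logB[[t + 1L]][, j] +
          lb_next[, j] - ll_i
        trans_num[i, j] <- trans_num[i, j] + sum(exp(lxi))
      }
    } else lb <- lb_next  # zeros
    lgam <- la[[t]] + lb - ll_i
    gam <- exp(lgam)
    xt <- X[, t]
    for (s in 1:5) {
      gs <- gam[, s]
      if (K == 1L) {
        sw[s, 1L] <- sw[s, 1L] + sum(gs)
        sx[s, 1L] <- sx[s, 1L] + sum(gs * xt)
        sxx[s, 1L] <- sxx[s, 1L] + sum(gs * xt^2)
      } else {
        # component posteriors within state s
        compld <- vapply(seq_len(K), function(k) {
          w <- model$weights[s, k]
          if (w > 0) log(w) + dnorm(xt, model$means[s, k],
                                    sqrt(model$vars[s, k]), log = TRUE)
          else rep(-Inf, n)
        }, numeric(n))
        compld <- matrix(compld, nrow = n)
        norm <- row_logsumexp(compld)
        for (k in seq_len(K)) {
          gk <- gs * exp(compld[, k] - norm)
          gk[!is.finite(gk)] <- 0
          sw[s, k] <- sw[s, k] + sum(gk)
          sx[s, k] <- sx[s, k] + sum(gk * xt)
          sxx[s, k] <- sxx[s, k] + sum(gk * xt^2)
        }
      }
    }
    lb_next <- lb
  }
  list(loglik = sum(ll_i), trans_num = trans_num, sw = sw, sx = sx, sxx = sxx)
}

#' Decode traces and call poly(A)-tail lengths
#'
#' Viterbi-decodes each retained trace and calls the tail length as the
#' number of cycles assigned to states 1 and 2 (strong and weak poly(A)-tail
#' states). T-signal values are log2-transformed before decoding.
#'
#' @param model A [tail_hmm()] object.
#' @param ts A `tsignal_set` from [impute_tsignal()], or a numeric matrix /
#'   list of raw (ratio-scale) T-signal traces.
#' @return A list with `calls` (data frame: `cluster_id`, `tail_length`,
#'   `log_likelihood`) and `states` (decoded paths for retained traces).
#' @export
call_tails <- function(model, ts) {
  if (inherits(ts, "tsignal_set")) {
    keep <- is.na(ts$discarded)
    x <- ts$tsignal[keep, , drop = FALSE]
    ids <- ts$cluster_id[keep]
  } else {
    x <- ts
    ids <- if (is.matrix(x)) rownames(x) else names(x)
    if (is.null(ids)) ids <- as.character(seq_len(if (is.matrix(x)) nrow(x) else length(x)))
  }
  if (is.matrix(x)) {
    if (any(x <= 0)) stop("T-signal must be strictly positive after imputation")
    lx <- log2(x)
  } else {
    lx <- lapply(x, function(v) { stopifnot(all(v > 0)); log2(v) })
  }
  dec <- hmm_viterbi(model, lx)
  tails <- if (is.matrix(dec$states)) rowSums(dec$states == 1L | dec$states == 2L)
           else vapply(dec$states, function(s) sum(s == 1L | s == 2L), 1)
  list(calls = data.frame(cluster_id = ids, tail_length = as.integer(tails),
                          log_likelihood = dec$loglik,
                          stringsAsFactors = FALSE),
       states = dec$states)
}
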