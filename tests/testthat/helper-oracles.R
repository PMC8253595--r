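# Shared fixtures and independent oracles for the test suite.

# Independent mixture log-density (recomputed from first principles,
# not via the package's emission code path).
oracle_state_loglik <- function(model, x, state) {
  K <- ncol(model$means)
  dens <- 0
  for (k in seq_len(K)) {
    w <- model$weights[state + 1L, k]
    if (w > 0)
      dens <- dens + w * dnorm(x, model$means[state + 1L, k],
                               sqrt(model$vars[state + 1L, k]))
  }
  log(dens)
}

# Exhaustive Viterbi oracle: enumerates every non-decreasing 5-state path
# starting in state 0 (dwell compositions d0 >= 1, d1..d4 >= 0) and scores
# it with its own density code. Returns the argmax path and its log-prob.
oracle_viterbi <- function(model, x) {
  T_ <- length(x)
  lt <- suppressWarnings(log(model$transition))
  ll <- sapply(0:4, function(s) oracle_state_loglik(model, x, s))
  ll <- matrix(ll, nrow = T_)
  best <- NULL; best_ll <- -Inf
  for (d0 in 1:T_) for (d1 in 0:(T_ - d0)) for (d2 in 0:(T_ - d0 - d1))
    for (d3 in 0:(T_ - d0 - d1 - d2)) {
      d4 <- T_ - d0 - d1 - d2 - d3
      path <- rep(0:4, c(d0, d1, d2, d3, d4))
      tp <- sum(lt[cbind(path[-T_] + 1L, path[-1] + 1L)])
      if (!is.finite(tp)) next
      score <- tp + sum(ll[cbind(seq_len(T_), path + 1L)])
      if (score > best_ll) { best_ll <- score; best <- path }
    }
  list(path = best, loglik = best_ll)
}

# Brute-force zero-imputation oracle: mean of the (up to) k nearest nonzero
# cycles, nearest distance first, ties to the earlier cycle.
oracle_impute_value <- function(v, pos, k = 10L) {
  nz <- which(v != 0)
  ord <- order(abs(nz - pos), nz)
  mean(v[nz[ord][seq_len(min(k, length(nz)))]])
}

# small truth table for generator-driven tests
tiny_truth <- function(n_genes = 50L, seed = 1L, ...) {
  simulate_truth(sim_config(seed = seed, n_genes = n_genes, ...))
}

# tag table with externally fixed tail lengths (bypasses the tail sampler)
fixed_tail_tags <- function(tails, feature_id = "geneX") {
  data.frame(tag_id = sprintf("tag%05d", seq_along(tails)),
             feature_id = feature_id, is_standard = FALSE,
             tail_length = as.integer(tails), terminal_U = FALSE,
             sample_id = "s1", stringsAsFactors = FALSE)
}

# simulate clusters for given tails and return retained calls joined to truth
call_tails_for <- function(tails, model, seed, dropout_frac = 0.01) {
  truth <- tiny_truth(5L, seed = 1L)
  tags <- fixed_tail_tags(tails)
  cl <- simulate_clusters(tags, truth, model,
                          cycles = max(tails) + 10L, seed = seed,
                          dropout_frac = dropout_frac)
  ts <- impute_tsignal(compute_tsignal(cl$intensities, cl$read1_means,
                                       cl$cluster_id))
  called <- call_tails(model, ts)
  keep <- is.na(ts$discarded)
  data.frame(true = tails[keep], called = called$calls$tail_length)
}

# multivariate normal sampler from a correlation matrix (chol transform)
rmvn <- function(n, R) {
  z <- matrix(rnorm(n * ncol(R)), n)
  z %*% chol(R)
}
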