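## Synthetic-data generators with known ground truth.
##
## These generators produce every input the pipeline consumes: per-gene
## truth (median tail length, TE, decay constant), poly(A)-tag tables,
## per-cluster 4-channel intensity traces whose T-signal is generated from
## the tail-calling HMM's own emission model, PAL-TRAP input/eluate pairs,
## and 5EU labeling-kinetics count time courses. All are pure functions of
## (config, seed).

#' Simulation configuration
#'
#' Collects the tunable knobs of the synthetic-data generators. Defaults
#' describe a coupled regime: per-gene median tails centered at 75 nt
#' (sd 25), tail/TE rank correlation 0.62, PAL-TRAP capture log-odds 0.02
#' per nt of tail, 5\% terminal-uridylation rate, and eight spike-in
#' tail-length standards spanning the calling range at 4\% of tags total.
#'
#' @param seed Integer root seed.
#' @param n_genes Number of genes.
#' @param tail_dist Per-gene tail distribution: list with `family`
#'   (`"normal"`), `mean` and `sd` of the per-gene median tail (nt), and
#'   `tag_sd`, the within-gene spread of per-tag tails (nt).
#' @param coupling_rho Target Spearman correlation between per-gene median
#'   tail and TE, in \[-1, 1\].
#' @param paltrap_beta Per-nt log-odds of eluate capture.
#' @param urid_rate Probability of terminal uridylation; either a scalar or
#'   a data frame `min_tail, max_tail, rate` of tail-length bands.
#' @param standard_lengths Spike-in standard tail lengths (nt).
#' @param standard_frac Fraction of tags drawn from the standards.
#' @param k_range Range of per-gene decay constants (1/h), sampled
#'   log-uniformly.
#' @param n_mito Number of genes flagged as mitochondrial.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 500L,
                       tail_dist = list(family = "normal", mean = 75,
                                        sd = 25, tag_sd = 20),
                       coupling_rho = 0.62,
                       paltrap_beta = 0.02,
                       urid_rate = 0.05,
                       standard_lengths = c(10L, 30L, 50L, 80L, 110L,
                                            150L, 200L, 250L),
                       standard_frac = 0.04,
                       k_range = c(0.05, 2),
                       n_mito = 13L) {
  stopifnot(coupling_rho >= -1, coupling_rho <= 1,
            standard_frac >= 0, standard_frac <= 1,
            all(standard_lengths >= 0), all(standard_lengths <= 250),
            tail_dist$mean >= 0, tail_dist$mean <= 250)
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 tail_dist = tail_dist, coupling_rho = coupling_rho,
                 paltrap_beta = paltrap_beta, urid_rate = urid_rate,
                 standard_lengths = as.integer(standard_lengths),
                 standard_frac = standard_frac, k_range = k_range,
                 n_mito = as.integer(n_mito)),
            class = "sim_config")
}

#' Simulate per-gene ground truth
#'
#' Draws per-gene median tail lengths and TEs from a Gaussian copula whose
#' latent correlation is chosen so that the ranks attain the configured
#' Spearman correlation (`rho_latent = 2 sin(pi rho_s / 6)`), plus per-gene
#' abundances, decay constants `k` (log-uniform over `k_range`), plateau
#' levels `C = log2(abundance)`, synthesis scale `S = k 2^C`, CDS lengths,
#' mitochondrial flags, and a fixed random 3'-UTR sequence per gene.
#'
#' @param config A [sim_config()].
#' @return List of class `truth_table` with `genes` (data frame),
#'   `standards` (data frame of spike-in standards) and `config`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_genes
    rho_l <- 2 * sin(pi * config$coupling_rho / 6)
    z1 <- rnorm(n)
    z2 <- rho_l * z1 + sqrt(1 - rho_l^2) * rnorm(n)
    td <- config$tail_dist
    median_tail <- pmin(pmax(td$mean + td$sd * z1, 5), 245)
    te <- exp(0.8 * z2)
    # abundances on the normalized-count scale (relative to the spike-in
    # standard); kept well above 1 so the log2 plateau C is positive, the
    # regime the bounded fit (C in (0, Inf)) addresses
    abundance <- rlnorm(n, 3, 1)
    k <- exp(runif(n, log(config$k_range[1]), log(config$k_range[2])))
    cds_len <- 3L * sample(100:1000, n, replace = TRUE)
    utr <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G"), 300, replace = TRUE,
                   prob = c(0.25, 0.4, 0.35)), collapse = ""), "")
    genes <- data.frame(
      gene_id = sprintf("gene%04d", seq_len(n)),
      median_tail = median_tail, te = te, abundance = abundance,
      k = k, C = log2(abundance), S = k * abundance,
      cds_len = cds_len,
      mito = seq_len(n) <= config$n_mito,
      utr = utr, stringsAsFactors = FALSE)
    standards <- data.frame(
      standard_id = sprintf("std%03d", config$standard_lengths),
      tail_length = config$standard_lengths, stringsAsFactors = FALSE)
    structure(list(genes = genes, standards = standards, config = config),
              class = "truth_table")
  })
}

urid_prob <- function(urid_rate, tails) {
  if (is.data.frame(urid_rate)) {
    p <- numeric(length(tails))
    for (r in seq_len(nrow(urid_rate))) {
      hit <- tails >= urid_rate$min_tail[r] & tails <= urid_rate$max_tail[r]
      p[hit] <- urid_rate$rate[r]
    }
    p
  } else rep(urid_rate, length(tails))
}

#' Simulate a poly(A)-tag table
#'
#' Draws tags from genes proportionally to abundance (plus spike-in
#' standards at `standard_frac`), per-tag tail lengths normal around the
#' gene's median tail (sd `tail_dist$tag_sd`), truncated to \[0, 250\] and
#' rounded; standards carry their exact defined tail length. Terminal
#' uridylation is Bernoulli with the configured (possibly banded) rate.
#'
#' @param truth A `truth_table` from [simulate_truth()].
#' @param n_tags Number of tags.
#' @param seed Integer seed.
#' @param sample_id Sample label stored in the table.
#' @param standard_frac Overrides the configured standard fraction if not
#'   `NULL` (set to 0 to omit standards).
#' @return Data frame `tag_id, feature_id, is_standard, tail_length,
#'   terminal_U, sample_id`.
#' @export
simulate_tags <- function(truth, n_tags, seed, sample_id = "s1",
                          standard_frac = NULL) {
  stopifnot(inherits(truth, "truth_table"), n_tags > 0)
  cfg <- truth$config
  sf <- if (is.null(standard_frac)) cfg$standard_frac else standard_frac
  with_seed(seed, {
    is_std <- runif(n_tags) < sf
    n_std <- sum(is_std)
    feature <- character(n_tags)
    tails <- integer(n_tags)
    if (n_std > 0) {
      si <- sample.int(nrow(truth$standards), n_std, replace = TRUE)
      feature[is_std] <- truth$standards$standard_id[si]
      tails[is_std] <- truth$standards$tail_length[si]
    }
    n_gene <- n_tags - n_std
    if (n_gene > 0) {
      gi <- sample.int(nrow(truth$genes), n_gene, replace = TRUE,
                       prob = truth$genes$abundance)
      feature[!is_std] <- truth$genes$gene_id[gi]
      raw <- rnorm(n_gene, truth$genes$median_tail[gi], cfg$tail_dist$tag_sd)
      tails[!is_std] <- as.integer(round(pmin(pmax(raw, 0), 250)))
    }
    term_u <- runif(n_tags) < urid_prob(cfg$urid_rate, tails)
    data.frame(tag_id = sprintf("tag%07d", seq_len(n_tags)),
               feature_id = feature, is_standard = is_std,
               tail_length = tails, terminal_U = term_u,
               sample_id = sample_id, stringsAsFactors = FALSE)
  })
}

# geometric dwell sampled from a transition-row continue probability
rdwell <- function(p_continue) 1L + rgeom(1L, 1 - p_continue)

# build one forward-only state path: one initiation cycle, L tail cycles
# split between states 1 and 2 (state-2 dwell at the tail's end, geometric
# per the transition matrix), then states 3 and 4
sim_state_path <- function(L, cycles, transition) {
  path <- integer(cycles)  # state 0
  pos <- 2L
  if (L > 0L) {
    m2 <- min(L, rdwell(transition[3, 3]))
    m1 <- L - m2
    if (m1 > 0L) { path[pos:(pos + m1 - 1L)] <- 1L; pos <- pos + m1 }
    path[pos:(pos + m2 - 1L)] <- 2L; pos <- pos + m2
  }
  if (pos <= cycles) {
    m3 <- min(cycles - pos + 1L, rdwell(transition[4, 4]))
    path[pos:(pos + m3 - 1L)] <- 3L; pos <- pos + m3
  }
  if (pos <= cycles) path[pos:cycles] <- 4L
  path
}

#' Simulate sequencing clusters for a tag table
#'
#' Generates, for each tag, a read-2 state path (one initiation cycle, the
#' tag's tail length in poly(A) states, then non-tail states, with dwell
#' times geometric per the model's transition matrix), draws per-cycle
#' emission values from the model's state-conditional Gaussian (mixture)
#' emissions, and manufactures 4-channel intensities whose T-signal equals
#' `2^emission`: the A/C/G channels get a common per-cycle baseline and the
#' T channel `2^s` times their sum, all scaled by per-cluster, per-channel
#' gains (the read-1 normalizer). A configurable fraction of cycles has the
#' T channel zeroed to exercise imputation. Read-2 base calls are `T` within
#' the tail, preceded by `A` when the tag is terminally uridylated, followed
#' by the gene's 3'-UTR bases.
#'
#' @param tags Tag table from [simulate_tags()].
#' @param truth A `truth_table` (for 3'-UTR sequences).
#' @param model A [tail_hmm()] emission spec.
#' @param cycles Read-2 length; must be at least `max(tail) + 10`.
#' @param seed Integer seed.
#' @param dropout_frac Fraction of cycles with a zeroed T channel.
#' @param gain_sd Lognormal sd of per-cluster channel gains.
#' @return List of class `cluster_set`: `cluster_id`, `intensities`
#'   (`n x cycles x 4`), `read1_means` (`n x 4`), `read2` (base calls),
#'   `states` (true paths), `tags` (the input table plus `cluster_id`).
#' @export
simulate_clusters <- function(tags, truth, model, cycles, seed,
                              dropout_frac = 0.01, gain_sd = 0.2) {
  stopifnot(inherits(model, "tail_hmm"))
  L <- tags$tail_length
  if (cycles < max(L) + 10L)
    stop("cycles must be at least max simulated tail + 10 (",
         max(L) + 10L, ")")
  n <- nrow(tags)
  with_seed(seed, {
    states <- t(vapply(L, sim_state_path, integer(cycles),
                       cycles = cycles, transition = model$transition))
    # state-conditional emission draws (log2 T-signal scale)
    s_val <- matrix(0, n, cycles)
    K <- ncol(model$means)
    for (st in 0:4) {
      idx <- which(states == st)
      if (!length(idx)) next
      comp <- if (K == 1L) rep(1L, length(idx))
              else sample.int(K, length(idx), replace = TRUE,
                              prob = model$weights[st + 1L, ])
      s_val[idx] <- rnorm(length(idx), model$means[st + 1L, comp],
                          sqrt(model$vars[st + 1L, comp]))
    }
    gains <- matrix(rlnorm(n * 4L, 0, gain_sd), n, 4L,
                    dimnames = list(NULL, CHANNELS))
    base <- matrix(runif(n * cycles, 0.5, 1.5), n, cycles)
    intens <- array(0, dim = c(n, cycles, 4L),
                    dimnames = list(NULL, NULL, CHANNELS))
    for (ch in 1:3) intens[, , ch] <- gains[, ch] * base
    intens[, , 4L] <- gains[, 4L] * (3 * base) * 2^s_val
    drop <- matrix(runif(n * cycles) < dropout_frac, n, cycles)
    tch <- intens[, , 4L]; tch[drop] <- 0; intens[, , 4L] <- tch
    utr_of <- setNames(truth$genes$utr, truth$genes$gene_id)
    read2 <- vapply(seq_len(n), function(i) {
      u <- if (tags$terminal_U[i]) "A" else ""
      utr <- utr_of[tags$feature_id[i]]
      if (is.na(utr)) utr <- paste(rep("C", cycles), collapse = "")  # standards
      s <- paste0(u, strrep("T", L[i]), utr)
      substr(s, 1L, cycles)
    }, "")
    cluster_id <- sprintf("cl%06d", seq_len(n))
    tags$cluster_id <- cluster_id
    structure(list(cluster_id = cluster_id, intensities = intens,
                   read1_means = gains, read2 = read2, states = states,
                   tags = tags),
              class = "cluster_set")
  })
}

#' Simulate a 5EU labeling time course
#'
#' Expected labeled level of gene g at labeling time x is
#' `depth * 2^C_g * (1 - exp(-k_g (x - t0)))`; observed counts are Poisson
#' around the expectation (optionally with a lognormal overdispersion
#' multiplier). A constant-abundance labeled standard row (`std_gfp`) and
#' two steady-state input columns (Poisson around `depth * 2^C_g`) are
#' included. Expectations at `x <= t0` are clamped to `expectation_floor`
#' and flagged.
#'
#' @param truth A `truth_table`.
#' @param times Labeling times (hours), all `> t0`.
#' @param t0 Time offset (hours).
#' @param depth Mean count scale.
#' @param seed Integer seed.
#' @param noise If `FALSE`, return exact expectations (no counting noise).
#' @param overdispersion Lognormal sd of an optional extra noise multiplier.
#' @param expectation_floor Floor applied to expectations at `x <= t0`.
#' @return List: `labeled` (matrix genes+standard x times), `input` (matrix
#'   genes+standard x 2), `times`, `flagged` (genes x times logical for
#'   clamped expectations).
#' @export
simulate_timecourse <- function(truth, times = c(1, 2, 4, 8), t0 = 0.3,
                                depth = 500, seed = 1L, noise = TRUE,
                                overdispersion = 0, expectation_floor = 0) {
  stopifnot(inherits(truth, "truth_table"), depth > 0)
  g <- truth$genes
  with_seed(seed, {
    frac <- outer(g$k, times - t0, function(k, dt) 1 - exp(-k * dt))
    flagged <- matrix(rep(times <= t0, each = nrow(g)), nrow(g))
    frac[flagged] <- expectation_floor
    mu <- depth * (2^g$C) * frac
    mu <- rbind(mu, std_gfp = rep(depth, length(times)))
    mu_in <- matrix(depth * 2^g$C, nrow(g), 2L)
    mu_in <- rbind(mu_in, std_gfp = rep(depth, 2L))
    rownames(mu) <- rownames(mu_in) <- c(g$gene_id, "std_gfp")
    colnames(mu) <- paste0("t", times)
    colnames(mu_in) <- c("input_1h", "input_8h")
    if (noise) {
      od <- function(m) if (overdispersion > 0)
        m * rlnorm(length(m), -overdispersion^2 / 2, overdispersion) else m
      lab <- matrix(rpois(length(mu), od(mu)), nrow(mu),
                    dimnames = dimnames(mu))
      inp <- matrix(rpois(length(mu_in), od(mu_in)), nrow(mu_in),
                    dimnames = dimnames(mu_in))
    } else { lab <- mu; inp <- mu_in }
    list(labeled = lab, input = inp, times = times, flagged = flagged)
  })
}

#' Simulate a PAL-TRAP input/eluate pair
#'
#' Input tags are drawn with [simulate_tags()] (without standards unless
#' requested); eluate tags are a subsample of the input, captured with
#' probability logistic in `beta * tail_length`, with the intercept set so
#' that the expected capture fraction at the mean input tail equals
#' `capture_frac`. `beta = 0` makes capture independent of tail length.
#'
#' @param truth A `truth_table`.
#' @param n_input_tags Number of input tags.
#' @param beta Per-nt log-odds of capture.
#' @param seed Integer seed.
#' @param capture_frac Expected capture fraction at the mean tail length.
#' @param standard_frac Standard fraction for the input table (default 0).
#' @return List with `input` and `eluate` tag tables.
#' @export
simulate_paltrap <- function(truth, n_input_tags, beta, seed,
                             capture_frac = 0.25, standard_frac = 0) {
  stopifnot(n_input_tags > 0)
  input <- simulate_tags(truth, n_input_tags, seed = derive_seed(seed, "pt-in"),
                         sample_id = "input", standard_frac = standard_frac)
  with_seed(derive_seed(seed, "pt-el"), {
    a <- qlogis(capture_frac) - beta * mean(input$tail_length)
    p <- plogis(a + beta * input$tail_length)
    eluate <- input[runif(nrow(input)) < p, , drop = FALSE]
    eluate$sample_id <- "eluate"
    list(input = input, eluate = eluate)
  })
}

#' Simulate RNA-seq and ribosome-footprint counts
#'
#' RNA counts are Poisson around `depth * abundance * window_kb`; footprint
#' counts around `depth * abundance * te * window_kb`, where `window_kb` is
#' the CDS counting window (CDS minus the first 15 and last 5 codons) in kb.
#'
#' @param truth A `truth_table`.
#' @param depth Mean count scale.
#' @param seed Integer seed.
#' @return Data frame `gene_id, rna, fp, cds_len, mito`.
#' @export
simulate_expression_counts <- function(truth, depth = 100, seed = 1L) {
  g <- truth$genes
  with_seed(seed, {
    win_kb <- pmax(g$cds_len / 3 - 20, 1) * 3 / 1000
    rna_mu <- depth * g$abundance * win_kb
    fp_mu <- depth * g$abundance * g$te * win_kb
    data.frame(gene_id = g$gene_id,
               rna = rpois(nrow(g), rna_mu),
               fp = rpois(nrow(g), fp_mu),
               cds_len = g$cds_len, mito = g$mito,
               stringsAsFactors = FALSE)
  })
}
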