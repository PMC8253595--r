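# Synthetic-data generators: determinism, ground-truth consistency,
# generative-model moments

test_that("generators are pure functions of (config, seed)", {
  truth <- tiny_truth(30, seed = 2)
  truth2 <- tiny_truth(30, seed = 2)
  expect_identical(truth, truth2)
  t1 <- simulate_tags(truth, 500, seed = 5)
  t2 <- simulate_tags(truth, 500, seed = 5)
  expect_identical(t1, t2)
  m <- hmm_init("palseq")
  c1 <- simulate_clusters(t1, truth, m, cycles = 300, seed = 6)
  c2 <- simulate_clusters(t1, truth, m, cycles = 300, seed = 6)
  expect_identical(c1$intensities, c2$intensities)
  tc1 <- simulate_timecourse(truth, seed = 7)
  tc2 <- simulate_timecourse(truth, seed = 7)
  expect_identical(tc1, tc2)
  p1 <- simulate_paltrap(truth, 2000, beta = 0.02, seed = 8)
  p2 <- simulate_paltrap(truth, 2000, beta = 0.02, seed = 8)
  expect_identical(p1$eluate, p2$eluate)
})

test_that("zero-length tails never enter the poly(A) states", {
  truth <- tiny_truth(5)
  tags <- fixed_tail_tags(rep(0L, 50))
  cl <- simulate_clusters(tags, truth, hmm_init("palseq"), cycles = 30,
                          seed = 3)
  expect_false(any(cl$states %in% c(1L, 2L)))
})

test_that("read length must cover the longest tail plus 10 cycles", {
  truth <- tiny_truth(5)
  tags <- fixed_tail_tags(c(10L, 100L))
  expect_error(simulate_clusters(tags, truth, hmm_init("palseq"),
                                 cycles = 105, seed = 1), "max simulated tail")
})

test_that("per-state T-signal moments match the emission spec", {
  m <- hmm_init("palseq")
  truth <- tiny_truth(5)
  set.seed(14)
  tags <- fixed_tail_tags(sample(0:60, 4000, replace = TRUE))
  cl <- simulate_clusters(tags, truth, m, cycles = 70, seed = 9,
                          dropout_frac = 0)
  x <- log2(compute_tsignal(cl$intensities, cl$read1_means)$tsignal)
  for (s in 0:4) {
    vals <- x[cl$states == s]
    se <- sqrt(m$vars[s + 1, 1] / length(vals))
    expect_lt(abs(mean(vals) - m$means[s + 1, 1]), 3 * se + 1e-3)
  }
})

test_that("state paths span exactly the true tail length", {
  truth <- tiny_truth(5)
  tags <- fixed_tail_tags(c(0L, 1L, 17L, 60L))
  cl <- simulate_clusters(tags, truth, hmm_init("tailseq"), cycles = 70,
                          seed = 2)
  expect_equal(rowSums(cl$states == 1L | cl$states == 2L),
               c(0, 1, 17, 60))
  expect_true(all(cl$states[, 1] == 0L))
  expect_true(all(apply(cl$states, 1, function(s) all(diff(s) >= 0))))
})

test_that("standard tag counts are multinomial at the configured fraction", {
  truth <- tiny_truth(100, seed = 3)
  for (seed in c(11, 12, 13)) {
    tags <- simulate_tags(truth, 20000, seed = seed)
    std <- tags[tags$is_standard, ]
    # share of standards ~ Binomial(n, 0.04)
    expect_lt(abs(nrow(std) / nrow(tags) - 0.04),
              3 * sqrt(0.04 * 0.96 / nrow(tags)))
    # uniform across the eight standards
    counts <- table(factor(std$feature_id,
                           levels = truth$standards$standard_id))
    expect_gt(chisq.test(counts)$p.value, 0.01)
    # standards carry their exact defined lengths
    expect_true(all(std$tail_length ==
      truth$standards$tail_length[match(std$feature_id,
                                        truth$standards$standard_id)]))
  }
})

test_that("the copula generator attains the target rank coupling", {
  truth <- tiny_truth(2000, seed = 4, coupling_rho = 0.3)
  rs <- cor(truth$genes$median_tail, truth$genes$te, method = "spearman")
  expect_lt(abs(rs - 0.3), 0.05)
})

test_that("timecourse expectations follow the saturation model", {
  truth <- tiny_truth(20, seed = 5)
  # noise off, x very large: level = depth * 2^C exactly
  tc <- simulate_timecourse(truth, times = c(1, 1e6), t0 = 0, depth = 100,
                            seed = 1, noise = FALSE)
  expect_equal(unname(tc$labeled[truth$genes$gene_id, 2]),
               100 * 2^truth$genes$C, tolerance = 1e-12)
  # k = ln 2, t0 = 0, x = 1: exactly half saturation
  truth$genes$k[] <- log(2)
  tc2 <- simulate_timecourse(truth, times = 1, t0 = 0, depth = 100,
                             seed = 1, noise = FALSE)
  expect_equal(unname(tc2$labeled[truth$genes$gene_id, 1]),
               100 * 2^truth$genes$C / 2, tolerance = 1e-12)
  # x <= t0 clamps to the floor and flags
  tc3 <- simulate_timecourse(truth, times = c(0.1, 1), t0 = 0.3,
                             depth = 100, seed = 1, noise = FALSE)
  expect_true(all(tc3$flagged[, 1]))
  expect_true(all(tc3$labeled[truth$genes$gene_id, 1] == 0))
})

test_that("Poisson counting noise is unbiased at depth 500", {
  truth <- tiny_truth(500, seed = 6)
  tc_exp <- simulate_timecourse(truth, depth = 500, seed = 1, noise = FALSE)
  tc_obs <- simulate_timecourse(truth, depth = 500, seed = 2, noise = TRUE)
  ratio <- tc_obs$labeled / pmax(tc_exp$labeled, 1e-9)
  expect_lt(abs(mean(ratio[tc_exp$labeled > 50]) - 1), 0.02)
})

test_that("PAL-TRAP capture is tail-neutral at beta 0 and tilted above", {
  truth <- tiny_truth(100, seed = 7)
  null <- simulate_paltrap(truth, 50000, beta = 0, seed = 3)
  expect_lt(abs(median(null$eluate$tail_length) -
                median(null$input$tail_length)), 2)
  pos <- simulate_paltrap(truth, 50000, beta = 0.05, seed = 3)
  expect_gte(median(pos$eluate$tail_length), median(pos$input$tail_length))
  expect_gt(mean(pos$eluate$tail_length), mean(pos$input$tail_length))
})
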