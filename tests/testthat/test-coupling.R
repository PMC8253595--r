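# TE computation, coupling statistics, dependent-correlation z-test,
# PAL-TRAP summaries

make_counts <- function(n = 50, seed = 1) {
  set.seed(seed)
  list(rna = setNames(rpois(n, 200), sprintf("g%03d", 1:n)),
       fp = setNames(rpois(n, 150), sprintf("g%03d", 1:n)),
       cds = 3L * sample(100:500, n, replace = TRUE),
       mito = seq_len(n) <= 5)
}

test_that("identical RNA and footprint tables give centered TE of zero", {
  cc <- make_counts()
  te <- compute_te(cc$rna, cc$rna, cc$cds, cc$mito, mode = "median-centered")
  expect_equal(te$log2_te, rep(0, nrow(te)))
})

test_that("the 30-read RNA expression cutoff is enforced", {
  rna <- setNames(c(29, 30, 500), c("a", "b", "c"))
  fp <- setNames(c(100, 100, 100), c("a", "b", "c"))
  te <- compute_te(rna, fp, rep(300L, 3), rep(FALSE, 3), mode = "all-genes")
  expect_identical(te$gene_id, c("b", "c"))
})

test_that("the counting window excludes 20 codons and floors at one codon", {
  rna <- setNames(c(100, 100), c("a", "b"))
  fp <- setNames(c(100, 100), c("a", "b"))
  te <- compute_te(rna, fp, c(300L, 63L), c(FALSE, FALSE), mode = "all-genes")
  # 300 nt = 100 codons -> 80-codon window; 63 nt = 21 codons -> floor 1
  expect_equal(te$rna_rpk[1] / te$rna_rpk[2], 3 / 240)
  expect_warning(compute_te(rna, fp, c(300L, 64L), c(FALSE, FALSE)),
                 "divisible")
})

test_that("mito-only normalization makes non-mito TE respond to fp scaling", {
  cc <- make_counts(seed = 2)
  te1 <- compute_te(cc$rna, cc$fp, cc$cds, cc$mito, mode = "mito-only")
  fp2 <- cc$fp
  fp2[!cc$mito] <- 2 * fp2[!cc$mito]
  te2 <- compute_te(cc$rna, fp2, cc$cds, cc$mito, mode = "mito-only")
  nm <- te1$gene_id[!cc$mito[match(te1$gene_id, names(cc$rna))]]
  expect_equal(te2$log2_te[te2$gene_id %in% nm],
               te1$log2_te[te1$gene_id %in% nm] + 1, tolerance = 1e-12)
  # mito genes are the reference set: their TE is unchanged
  expect_equal(te2$log2_te[!te2$gene_id %in% nm],
               te1$log2_te[!te1$gene_id %in% nm], tolerance = 1e-12)
  expect_error(compute_te(cc$rna, cc$fp, cc$cds, rep(FALSE, 50),
                          mode = "mito-only"), "mitochondrial")
})

test_that("TE is invariant to library depth under each mode", {
  cc <- make_counts(seed = 3)
  for (mode in c("all-genes", "mito-only", "median-centered")) {
    te1 <- compute_te(cc$rna, cc$fp, cc$cds, cc$mito, mode = mode)
    te2 <- compute_te(cc$rna * 4, cc$fp * 7, cc$cds, cc$mito, mode = mode)
    shift <- if (mode == "median-centered") 0 else 0  # modes are ratio-based
    expect_equal(te2$log2_te, te1$log2_te + shift, tolerance = 1e-12)
  }
})

test_that("Spearman coupling is monotone-invariant and joins on cutoffs", {
  mt <- data.frame(feature_id = sprintf("g%03d", 1:40),
                   n_tags = c(rep(150L, 30), rep(99L, 10)),
                   median_tail = c(seq(20, 136, by = 4), rep(50, 10)))
  te <- data.frame(gene_id = sprintf("g%03d", 1:40),
                   log2_te = c(exp(seq(20, 136, by = 4) / 40), rep(1, 10)))
  cc <- coupling_correlation(mt, te)
  expect_equal(cc$rs, 1)         # monotone function of tail
  expect_identical(cc$n, 30L)    # 99-tag genes excluded
  # degenerate vector: undefined, reported missing
  te$log2_te <- 1
  expect_true(is.na(coupling_correlation(mt, te)$rs))
  expect_error(coupling_correlation(mt[1:2, ], te[1:2, ]), "fewer than 3")
})

test_that("independent simulated ranks show no spurious coupling", {
  set.seed(31)
  mt <- data.frame(feature_id = sprintf("g%04d", 1:2000), n_tags = 1000L,
                   median_tail = rnorm(2000, 75, 20))
  te <- data.frame(gene_id = sprintf("g%04d", 1:2000),
                   log2_te = rnorm(2000))
  expect_lt(abs(coupling_correlation(mt, te)$rs), 0.05)
})

test_that("dependent-correlation z is zero at equality and reduces to the
           independent Fisher test with zero cross-correlations", {
  res <- compare_dependent_correlations(0.5, 0.5,
                                        c(r13 = 0.3, r14 = 0.2,
                                          r23 = 0.1, r24 = 0.4), n = 100)
  expect_equal(res$z, 0)
  expect_equal(res$p, 1)
  r1 <- 0.62; r2 <- 0.36; n <- 500
  res0 <- compare_dependent_correlations(r1, r2, rep(0, 4), n)
  z_indep <- (atanh(r1) - atanh(r2)) / sqrt(2 / (n - 3))
  expect_equal(res0$z, z_indep, tolerance = 1e-12)
  expect_equal(res0$c_bar, 0)
  expect_error(compare_dependent_correlations(1, 0.5, rep(0, 4), 100),
               "within")
  expect_error(compare_dependent_correlations(0.5, 0.4, rep(0, 4), 5))
})

test_that("positive cross-correlation structure increases test sensitivity", {
  # same correlation gap, dependent structure -> larger |z| than independent
  cross <- c(r13 = 0.7, r14 = 0.35, r23 = 0.35, r24 = 0.7)
  dep <- compare_dependent_correlations(0.6, 0.4, cross, 200)
  ind <- compare_dependent_correlations(0.6, 0.4, rep(0, 4), 200)
  expect_gt(abs(dep$z), abs(ind$z))
  expect_true(dep$c_bar > 0)
})

test_that("PAL-TRAP isoform summaries enforce the dual 100-tag cutoff", {
  set.seed(17)
  input <- data.frame(feature_id = rep(c("i1", "i2", "i3"), c(150, 100, 120)),
                      tail_length = c(rpois(150, 40), rpois(100, 60),
                                      rpois(120, 50)))
  eluate <- rbind(input[input$feature_id != "i2", ],
                  input[input$feature_id == "i2", ][1:99, ])
  st <- paltrap_stats(input, eluate)
  # i2 has only 99 eluate tags: excluded
  expect_identical(sort(st$isoforms$feature_id), c("i1", "i3"))
  # eluate == input for retained isoforms: all diffs zero
  expect_true(all(st$isoforms$diff == 0))
  expect_equal(st$frac_longer, 0)
  expect_equal(st$ecdf_input(40), st$ecdf_input(40))
})

test_that("a tail-tilted eluate enriches long-tailed isoform medians", {
  truth <- tiny_truth(60, seed = 21)
  pt <- simulate_paltrap(truth, 60000, beta = 0.05, seed = 5)
  st <- paltrap_stats(pt$input, pt$eluate, min_tags = 100)
  expect_gt(nrow(st$isoforms), 20)
  expect_gt(st$frac_longer, 0.5)
  expect_gte(st$median_eluate_pooled, st$median_input_pooled)
  # pooled CDFs reflect stochastic dominance
  qs <- seq(20, 120, by = 10)
  expect_true(all(st$ecdf_eluate(qs) <= st$ecdf_input(qs) + 0.02))
})
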