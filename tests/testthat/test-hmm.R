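# Forward-only Gaussian HMM: initialization, training, decoding, calling

test_that("published initializations are reproduced", {
  for (p in c("tailseq", "palseq")) {
    m <- hmm_init(p)
    expect_equal(m$transition[1, ], c(0.04, 0.93, 0.02, 0.01, 0.00))
    expect_equal(rowSums(m$transition), rep(1, 5))
    expect_true(all(m$transition[lower.tri(m$transition)] == 0))
    expect_equal(rowSums(m$weights), rep(1, 5))
  }
  pal <- hmm_init("palseq")
  expect_equal(pal$means[2, 1], 2.0)
  expect_equal(pal$vars[2, 1], 0.5)
  expect_equal(pal$means[1, 1], 100.0)
  ts <- hmm_init("tailseq")
  expect_equal(ts$weights[, 1], c(1, 0.95, 0.75, 0.50, 0.25))
  expect_equal(ts$means[2, ], c(1.5, -1.0))
  expect_identical(hmm_init("palseq_v3")$means, pal$means)
  expect_error(hmm_init("nanopore"))
})

test_that("model validation rejects broken specs", {
  m <- hmm_init("palseq")
  bad <- m$transition; bad[2, 1] <- 0.1; bad[2, 2] <- 0.84
  expect_error(tail_hmm(bad, m$means, m$vars, m$weights), "backward")
  bad2 <- m$transition; bad2[1, 1] <- 0.5
  expect_error(tail_hmm(bad2, m$means, m$vars, m$weights), "stochastic")
  expect_error(tail_hmm(m$transition, m$means, -m$vars, m$weights),
               "variance")
})

test_that("training-set selection is clamped, seeded and without replacement", {
  expect_identical(training_set_size(10000000), 50000L)
  expect_identical(training_set_size(100000), 5000L)
  expect_identical(training_set_size(2000000), 20000L)
  expect_identical(training_set_size(1000), 1000L)  # fewer than the floor
  ids <- sprintf("cl%05d", 1:20000)
  s1 <- select_training_set(ids, seed = 3)
  s2 <- select_training_set(ids, seed = 3)
  expect_identical(s1, s2)
  expect_length(s1, 5000L)
  expect_false(any(duplicated(s1)))
  expect_true(all(s1 %in% ids))
  expect_error(select_training_set(0, seed = 1), "empty")
})

test_that("Viterbi matches exact state-path enumeration on short traces", {
  set.seed(101)
  for (p in c("palseq", "tailseq")) {
    m <- hmm_init(p)
    for (rep in 1:15) {
      T_ <- sample(6:12, 1)
      L <- sample(0:(T_ - 3), 1)
      x <- c(rnorm(1, 100, 1),
             rnorm(L, 2, 0.7),
             rnorm(T_ - 1 - L, -1.5, 0.7))
      dec <- hmm_viterbi(m, matrix(x, 1))
      oracle <- oracle_viterbi(m, x)
      expect_identical(dec$states[1, ], oracle$path)
      expect_equal(dec$loglik[1], oracle$loglik, tolerance = 1e-9)
    }
  }
})

test_that("decoded paths never move backward", {
  set.seed(5)
  m <- hmm_init("tailseq")
  x <- matrix(rnorm(50 * 40, 0, 2), 50, 40)
  x[, 1] <- rnorm(50, 100, 1)
  dec <- hmm_viterbi(m, x)
  expect_true(all(apply(dec$states, 1, function(s) all(diff(s) >= 0))))
})

test_that("tail length is the number of cycles in states 1 and 2", {
  m <- hmm_init("palseq")
  # emission-mean trace along the path (0,1,1,2,3,4,...) decodes exactly
  x <- 2^c(100, 2, 2, 1, -1, -2, -2, -2)
  res <- call_tails(m, matrix(x, 1))
  expect_identical(res$states[1, 1:6], c(0L, 1L, 1L, 2L, 3L, 4L))
  expect_identical(res$calls$tail_length, 3L)
})

test_that("zero-iteration training is a no-op and EM is monotone", {
  m <- hmm_init("palseq")
  set.seed(9)
  tags <- fixed_tail_tags(sample(0:40, 300, replace = TRUE))
  cl <- simulate_clusters(tags, tiny_truth(5), m, cycles = 50, seed = 4,
                          dropout_frac = 0)
  x <- log2(compute_tsignal(cl$intensities, cl$read1_means)$tsignal)
  tr0 <- hmm_train(m, x, max_iter = 0)
  expect_identical(tr0$model, m)
  expect_identical(tr0$iterations, 0L)
  tr <- hmm_train(m, x, max_iter = 12, tol = 0)
  expect_gte(length(tr$loglik), 12L)
  expect_true(all(diff(tr$loglik) >= -1e-8 * abs(head(tr$loglik, -1))))
  # structural zeros survive training
  expect_true(all(tr$model$transition[lower.tri(tr$model$transition)] == 0))
  expect_equal(rowSums(tr$model$transition), rep(1, 5))
})

test_that("training recovers the generating emission parameters", {
  m <- hmm_init("palseq")
  set.seed(21)
  tags <- fixed_tail_tags(sample(0:40, 5000, replace = TRUE))
  cl <- simulate_clusters(tags, tiny_truth(5), m, cycles = 50, seed = 8,
                          dropout_frac = 0)
  x <- log2(compute_tsignal(cl$intensities, cl$read1_means)$tsignal)
  tr <- hmm_train(m, x, max_iter = 10)
  expect_lt(abs(tr$model$means[2, 1] - 2.0), 0.05)
  # the weak-tail state borders state 3 and may drift a little further
  expect_lt(abs(tr$model$means[3, 1] - 1.0), 0.2)
})

test_that("a single depressed mid-tail cycle shifts the call by at most 2 nt", {
  set.seed(33)
  for (p in c("palseq", "tailseq")) {
    m <- hmm_init(p)
    L <- 30L; T_ <- 45L
    x <- c(100, rnorm(L, 2, 0.5), rnorm(T_ - 1 - L, -1.5, 0.5))
    x_dep <- x; x_dep[15] <- 0.0   # mid-tail cycle pulled toward non-tail
    t_ref <- call_tails(m, matrix(2^x, 1))$calls$tail_length
    t_dep <- call_tails(m, matrix(2^x_dep, 1))$calls$tail_length
    expect_lte(abs(t_dep - t_ref), 2L)
  }
})

test_that("ragged trace lists decode identically to their matrix blocks", {
  m <- hmm_init("palseq")
  set.seed(12)
  traces <- lapply(c(20, 20, 30), function(T_) {
    L <- sample(0:10, 1)
    c(rnorm(1, 100, 1), rnorm(L, 2, 0.7), rnorm(T_ - 1 - L, -1.5, 0.7))
  })
  dec <- hmm_viterbi(m, traces)
  d20 <- hmm_viterbi(m, rbind(traces[[1]], traces[[2]]))
  expect_identical(dec$states[[1]], d20$states[1, ])
  expect_identical(dec$states[[2]], d20$states[2, ])
  expect_equal(dec$loglik[1:2], d20$loglik)
})
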