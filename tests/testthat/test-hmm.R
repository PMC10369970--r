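test_that("initialization yields valid stochastic models, seeded", {
  m <- init_hmm(5, 3, seed = 1)
  expect_equal(sum(m$pi), 1, tolerance = 1e-12)
  expect_equal(unname(rowSums(m$A)), rep(1, 5), tolerance = 1e-12)
  expect_true(all(m$E > 0.05 & m$E < 0.95))
  expect_identical(init_hmm(5, 3, seed = 1)$E, m$E)
  expect_false(identical(init_hmm(5, 3, seed = 2)$E, m$E))
})

test_that("forward-backward matches brute-force path enumeration", {
  # fixed toy: K=2, M=1, T=3 (8 paths)
  m <- hmm_model(pi = c(0.6, 0.4),
                 A = matrix(c(0.7, 0.3, 0.2, 0.8), 2, byrow = TRUE),
                 E = matrix(c(0.9, 0.1), 2, 1))
  obs <- matrix(c(1, 0, 1), 3, 1)
  fb <- forward_backward(m, obs)
  expect_equal(fb$log_likelihood, enumerate_loglik(m, obs), tolerance = 1e-9)
  expect_equal(fb$posteriors, enumerate_posteriors(m, obs), tolerance = 1e-9)

  # random instances, K=3, M=2, T up to 8
  withr::with_seed(61, {
    for (i in 1:5) {
      K <- 3; M <- 2; T_len <- sample(2:8, 1)
      mr <- init_hmm(K, M, seed = i + 100)
      o <- matrix(rbinom(T_len * M, 1, 0.4), T_len, M)
      fbr <- forward_backward(mr, o)
      expect_equal(fbr$log_likelihood, enumerate_loglik(mr, o),
                   tolerance = 1e-9)
      expect_equal(rowSums(fbr$posteriors), rep(1, T_len), tolerance = 1e-10)
    }
  })
})

test_that("uninformative emissions leave posteriors at the prior", {
  m <- hmm_model(pi = c(0.5, 0.5), A = matrix(0.5, 2, 2),
                 E = matrix(0.3, 2, 2))
  fb <- forward_backward(m, matrix(rbinom(10, 1, 0.5), 5, 2))
  expect_equal(fb$posteriors, matrix(0.5, 5, 2), tolerance = 1e-12)
})

test_that("full-batch Baum-Welch log-likelihood is non-decreasing", {
  withr::with_seed(62, {
    seqs <- lapply(1:3, function(i) matrix(rbinom(400 * 3, 1, 0.3), 400, 3))
  })
  m <- baum_welch(init_hmm(4, 3, seed = 5), seqs, max_iter = 50)
  ll <- attr(m, "loglik")
  expect_length(ll, 50)
  expect_true(all(diff(ll) >= -1e-8))
  expect_equal(unname(rowSums(m$A)), rep(1, 4), tolerance = 1e-9)
  expect_true(all(m$E >= 1e-6 & m$E <= 1 - 1e-6))
})

test_that("subsampled Baum-Welch runs to max_iter", {
  withr::with_seed(63, {
    seqs <- lapply(1:6, function(i) matrix(rbinom(100 * 2, 1, 0.3), 100, 2))
  })
  m <- baum_welch(init_hmm(3, 2, seed = 5), seqs, max_iter = 10,
                  batch_size = 2, seed = 4)
  expect_length(attr(m, "loglik"), 10)
  expect_s3_class(m, "hmm_model")
})

test_that("Baum-Welch recovers planted parameters from simulated data", {
  E_true <- matrix(c(0.9, 0.8, 0.05, 0.05,
                     0.05, 0.1, 0.9, 0.1,
                     0.02, 0.02, 0.02, 0.02), 3, 4, byrow = TRUE)
  A_true <- matrix(c(0.90, 0.05, 0.05,
                     0.10, 0.85, 0.05,
                     0.02, 0.03, 0.95), 3, 3, byrow = TRUE)
  truth <- hmm_model(pi = c(0.3, 0.3, 0.4), A = A_true, E = E_true)
  sim <- simulate_hmm(truth, 20000, seed = 8)
  fit <- baum_welch(init_hmm(3, 4, seed = 20), list(sim$observations),
                    max_iter = 100)
  perm <- match_states(fit$E, E_true)
  expect_lt(max(abs(fit$E[perm, ] - E_true)), 0.05)
  expect_lt(max(abs(fit$A[perm, perm] - A_true)), 0.05)
})

test_that("posterior decoding matches enumeration and recovers clean paths", {
  # orthogonal one-hot emissions identify the generating path exactly
  m <- hmm_model(pi = c(0.5, 0.5),
                 A = matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE),
                 E = matrix(c(1 - 1e-6, 1e-6, 1e-6, 1 - 1e-6), 2, 2,
                            byrow = TRUE))
  sim <- simulate_hmm(m, 500, seed = 9)
  expect_equal(decode(m, sim$observations), sim$path)

  mr <- init_hmm(3, 2, seed = 30)
  withr::with_seed(64, o <- matrix(rbinom(12, 1, 0.5), 6, 2))
  post <- enumerate_posteriors(mr, o)
  expect_equal(decode(mr, o), max.col(post, ties.method = "first"))
  expect_true(all(decode(mr, o) %in% 1:3))
})

test_that("state reordering sorts by mean emission and preserves likelihood", {
  m <- hmm_model(pi = c(0.3, 0.7),
                 A = matrix(c(0.6, 0.4, 0.1, 0.9), 2, byrow = TRUE),
                 E = matrix(c(0.1, 0.9), 2, 1))
  om <- order_states(m)
  expect_equal(om$E[, 1], c(0.9, 0.1))
  expect_equal(om$pi, c(0.7, 0.3))
  withr::with_seed(65, o <- matrix(rbinom(20, 1, 0.5), 20, 1))
  expect_equal(forward_backward(om, o)$log_likelihood,
               forward_backward(m, o)$log_likelihood, tolerance = 1e-12)
  # ties keep original relative order (stable sort)
  mt <- hmm_model(pi = c(0.5, 0.5), A = matrix(0.5, 2, 2),
                  E = matrix(c(0.4, 0.4), 2, 1))
  expect_equal(order_states(mt)$pi, mt$pi)
})

test_that("states group by their expert emission patterns", {
  E <- rbind(c(0.95, 0.05, 0.03),   # single expert
             c(0.0005, 0.0005, 0.0009),  # no expert
             c(0.5, 0.3, 0.01),     # multi expert
             c(0.95, 0.15, 0.01),   # >= 0.10 on a second expert -> unclassified
             c(0.3, 0.05, 0.05))    # one mid emission -> unclassified
  m <- hmm_model(pi = rep(0.2, 5), A = matrix(0.2, 5, 5), E = E)
  g <- classify_states(m)
  expect_equal(g$group, c("single_expert", "no_expert", "multi_expert",
                          "unclassified", "unclassified"))
})

test_that("binarization marks the top fraction, ties included", {
  asm <- genome_assembly("chr1", 25000)  # 1000 bins
  withr::with_seed(66, v <- sample(seq(0, 1, length.out = 1000)))
  tr <- toy_track(asm, values = list(chr1 = v), name = "e1")
  bc <- binarize_tracks(list(e1 = tr), top_fraction = 0.02)
  expect_equal(sum(bc$calls$chr1), 20)  # ceil(0.02 * 1000), tie-free
  # membership equals a full-sort oracle
  top <- order(v, decreasing = TRUE)[1:20]
  expect_setequal(which(bc$calls$chr1[, 1] == 1), top)

  tied <- tr
  tied$values$chr1[1:50] <- 0.99
  tied$values$chr1[51:1000] <- 0.1
  bct <- binarize_tracks(list(e1 = tied), top_fraction = 0.02)
  expect_equal(sum(bct$calls$chr1), 50)  # all boundary ties included
  expect_warning(binarize_tracks(list(e1 = toy_track(asm, fill = 1))),
                 "constant")
})

test_that("simulated observations reproduce the generating transitions", {
  m <- hmm_model(pi = c(0.5, 0.5),
                 A = matrix(c(0.8, 0.2, 0.3, 0.7), 2, byrow = TRUE),
                 E = matrix(c(0.9, 0.1), 2, 1))
  sim <- simulate_hmm(m, 100000, seed = 10)
  emp <- prop.table(table(head(sim$path, -1), tail(sim$path, -1)), 1)
  expect_lt(max(abs(emp - m$A)), 0.01)
  expect_identical(simulate_hmm(m, 100, seed = 3)$observations,
                   simulate_hmm(m, 100, seed = 3)$observations)
  # deterministic one-hot emissions identify the path from observations
  md <- hmm_model(pi = c(0.5, 0.5), A = matrix(0.5, 2, 2),
                  E = matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE))
  simd <- simulate_hmm(md, 200, seed = 4)
  expect_equal(simd$observations[, 1], as.integer(simd$path == 1))
})

test_that("segmentation covers every bin exactly once", {
  asm <- tiny_assembly(c(chr1 = 2500, chr2 = 1250))
  tr1 <- random_track(asm, 71, name = "e1")
  tr2 <- random_track(asm, 72, name = "e2")
  bc <- binarize_tracks(list(e1 = tr1, e2 = tr2), top_fraction = 0.1)
  m <- baum_welch(init_hmm(3, 2, seed = 6), bc$calls, max_iter = 10)
  seg <- segment_genome(m, bc)
  expect_equal(lengths(seg$states), vapply(bc$calls, nrow, 1L))
  expect_true(all(unlist(seg$states) %in% 1:3))
})
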