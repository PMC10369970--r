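test_that("signal windows sample 81 offsets with zero edge-padding", {
  asm <- genome_assembly("chr1", 100000)
  const <- toy_track(asm, fill = 3.5)
  W <- extract_signal_window(const, "chr1", 50000)
  expect_equal(ncol(W), 81)
  expect_equal(as.vector(W), rep(3.5, 81))

  # ramp track: value = bin index; brute-force per-offset lookup oracle
  ramp <- toy_track(asm, values = list(chr1 = seq_len(asm$n_bins[1]) - 1))
  pos <- c(12L, 50000L, 99995L)  # includes both chromosome edges
  W2 <- extract_signal_window(ramp, rep("chr1", 3), pos)
  offsets <- seq(-1000, 1000, by = 25)
  for (i in seq_along(pos)) {
    expected <- vapply(offsets, function(o) {
      p <- pos[i] + o
      if (p < 0 || p >= 100000) 0 else floor(p / 25)
    }, numeric(1))
    expect_equal(unname(W2[i, ]), expected)
  }
})

test_that("mark PCA matches an eigendecomposition oracle and fixes signs", {
  withr::with_seed(21, {
    X <- matrix(rnorm(50 * 81), 50, 81) %*% diag(c(rep(3, 5), rep(1, 76)))
  })
  pca <- fit_mark_pca(X)
  expect_true(all(abs(crossprod(pca$loadings) - diag(3)) < 1e-8))

  # oracle: eigenvectors of the covariance matrix
  ev <- eigen(stats::cov(X), symmetric = TRUE)
  for (j in 1:3) {
    v <- ev$vectors[, j]
    if (v[which.max(abs(v))] < 0) v <- -v
    expect_equal(unname(pca$loadings[, j]), unname(v), tolerance = 1e-6)
    expect_equal(pca$explained_fraction[j],
                 ev$values[j] / sum(ev$values), tolerance = 1e-8)
  }
})

test_that("rank-deficient inputs zero-pad the missing components", {
  base <- sin(seq_len(81))
  X <- outer(c(1, 2, 3, 4, 7), base)  # rank 1
  pca <- fit_mark_pca(X)
  expect_true(pca$rank_deficient)
  expect_equal(pca$explained_fraction[1], 1)
  expect_equal(pca$loadings[, 2], rep(0, 81))
  # 3-component reconstruction of rank-<=3 data is exact
  proj <- apply_mark_pca(pca, X)
  recon <- sweep(proj %*% t(pca$loadings), 2, pca$mean, `+`)
  expect_lt(max(abs(recon - X)), 1e-8)
  expect_error(fit_mark_pca(X[1:3, ]), "at least 4")
})

test_that("PCA projection is centered and matches brute-force dot products", {
  withr::with_seed(22, X <- matrix(rnorm(30 * 81), 30, 81))
  pca <- fit_mark_pca(X)
  expect_equal(as.vector(apply_mark_pca(pca, pca$mean)), c(0, 0, 0))
  got <- apply_mark_pca(pca, X[7, ])
  oracle <- vapply(1:3, function(j) sum((X[7, ] - pca$mean) * pca$loadings[, j]),
                   numeric(1))
  expect_equal(as.vector(got), oracle)
})

test_that("peak indicator uses half-open intervals and matches a linear scan", {
  peaks <- tibble::tibble(chrom = "chr1", start = c(10L, 100L, 50L),
                          end = c(20L, 200L, 120L))
  expect_equal(peak_indicator(peaks, "chr1", 15), 1L)
  expect_equal(peak_indicator(peaks, "chr1", 20), 0L)
  withr::with_seed(23, q <- sample.int(300, 1000, replace = TRUE) - 1L)
  got <- peak_indicator(peaks, rep("chr1", 1000), q)
  oracle <- vapply(q, function(p)
    as.integer(any(peaks$start <= p & p < peaks$end)), integer(1))
  expect_equal(got, oracle)
})

test_that("state one-hot encodes exactly one state per position", {
  asm <- genome_assembly("chr1", 1000)
  ann <- state_annotation(list(chr1 = rep(1:4, each = 10)), asm, K = 25)
  oh <- state_onehot(ann, "chr1", 300)  # bin 12 -> state 2
  expect_equal(ncol(oh), 25)
  expect_equal(sum(oh), 1)
  expect_equal(unname(which(oh[1, ] == 1)), 2L)
  withr::with_seed(24, q <- sample.int(1000, 50) - 1L)
  oh2 <- state_onehot(ann, rep("chr1", 50), q)
  expect_true(all(rowSums(oh2) == 1))
  expect_equal(max.col(oh2), rep(1:4, each = 10)[floor(q / 25) + 1])
})

test_that("assembled feature matrices have 5M + K columns in frozen order", {
  sw <- small_world()
  r <- sw$rendered$ct1
  labs <- world_labels(sw$world, "ct1")[1:20, ]
  pcas <- lapply(r$tracks, function(tr)
    fit_mark_pca(extract_signal_window(tr, labs$chrom, labs$pos)))
  X <- assemble_features(labs, r$tracks, r$peaks, r$ann, pcas)
  expect_equal(ncol(X), 5 * 12 + 25)  # 85
  expect_equal(colnames(X)[1:3], c("mark1_PC1", "mark1_PC2", "mark1_PC3"))
  expect_equal(colnames(X)[37], "mark1_signal")
  expect_equal(colnames(X)[49], "mark1_peak")
  expect_equal(colnames(X)[61], "state_1")
  # center-signal feature equals the track value at the reference bin
  expect_equal(X[, "mark1_signal"],
               chromscore:::track_value_at(r$tracks$mark1, labs$chrom, labs$pos))

  # single-mark, two-state toy: 3 + 1 + 1 + 2 = 7 columns
  asm <- genome_assembly("chr1", 100000)
  tr <- random_track(asm, 1, name = "m")
  ann2 <- state_annotation(list(chr1 = rep(1:2, length.out = asm$n_bins[1])),
                           asm, K = 2)
  pk <- tibble::tibble(chrom = character(), start = integer(), end = integer())
  regs <- tibble::tibble(chrom = "chr1", pos = c(30000L, 60000L, 62000L, 90000L, 91000L))
  pca1 <- list(m = fit_mark_pca(extract_signal_window(tr, regs$chrom, regs$pos)))
  X2 <- assemble_features(regs, list(m = tr), list(m = pk), ann2, pca1)
  expect_equal(ncol(X2), 7)
})

test_that("standardization uses training parameters only", {
  withr::with_seed(25, {
    train <- matrix(rnorm(40 * 3, mean = 5, sd = 2), 40, 3)
    test <- matrix(rnorm(10 * 3, mean = 9, sd = 4), 10, 3)
  })
  colnames(train) <- colnames(test) <- c("a", "b", "c")
  s <- fit_standardizer(train)
  zt <- apply_standardizer(s, train)
  expect_equal(unname(colMeans(zt)), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(zt, 2, sd)), c(1, 1, 1), tolerance = 1e-12)
  # already-standard data passes through (fit on itself)
  s2 <- fit_standardizer(zt)
  expect_equal(apply_standardizer(s2, zt), zt, tolerance = 1e-10)
  # held-out rows use train parameters, not their own moments
  ztest <- apply_standardizer(s, test)
  self <- scale(test)
  expect_gt(max(abs(ztest - self)), 0.1)
  expect_equal(ztest, sweep(sweep(test, 2, s$mean), 2, s$sd, `/`))

  const <- cbind(train, d = rep(2, 40))
  s3 <- fit_standardizer(const)
  expect_true(s3$zero_variance[["d"]])
  expect_equal(unname(apply_standardizer(s3, const)[, "d"]), rep(0, 40))
})
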