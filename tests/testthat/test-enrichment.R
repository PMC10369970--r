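test_that("overlap fold enrichment matches the closed form and the mixture identity", {
  asm <- genome_assembly("chr1", 25 * 1000)  # 1000 bins
  # state 1 covers 10% of bins; annotation covers 10%; half of state 1 overlaps
  st <- rep(2L, 1000); st[1:100] <- 1L
  ann <- state_annotation(list(chr1 = st), asm, K = 2)
  annot <- tibble::tibble(chrom = "chr1",
                          start = c(0L, 2500L),
                          end = c(1250L, 3750L))  # bins 1-50 and 101-150
  enr <- overlap_fold_enrichment(ann, annot)
  bg <- 100 / 1000
  expect_equal(enr$fold[1], (50 / 100) / bg)  # 5.0
  expect_equal(sum(enr$genome_frac * enr$fold), 1, tolerance = 1e-9)

  whole <- tibble::tibble(chrom = "chr1", start = 0L, end = 25000L)
  expect_equal(overlap_fold_enrichment(ann, whole)$fold, c(1, 1))
  none <- tibble::tibble(chrom = character(), start = integer(), end = integer())
  expect_true(all(is.na(overlap_fold_enrichment(ann, none)$fold)))
})

test_that("fold enrichment equals brute-force per-bin counting on random data", {
  asm <- tiny_assembly(c(chr1 = 2000, chr2 = 1000))
  withr::with_seed(81, {
    states <- lapply(setNames(asm$n_bins, asm$chrom), function(n)
      sample.int(3, n, replace = TRUE))
    iv <- tibble::tibble(
      chrom = sample(asm$chrom, 15, replace = TRUE),
      start = sample.int(900, 15)
    )
    iv$end <- iv$start + sample.int(80, 15)
  })
  ann <- state_annotation(states, asm, K = 3)
  enr <- overlap_fold_enrichment(ann, iv)
  # oracle: flag each bin by scanning every interval
  flag <- lapply(setNames(asm$n_bins, asm$chrom), function(n) logical(n))
  for (i in seq_len(nrow(iv))) {
    for (b in seq_len(asm$n_bins[asm$chrom == iv$chrom[i]])) {
      lo <- (b - 1) * 25; hi <- b * 25
      if (iv$start[i] < hi && iv$end[i] > lo) flag[[iv$chrom[i]]][b] <- TRUE
    }
  }
  st <- unlist(states); fl <- unlist(flag)
  for (k in 1:3) {
    oracle <- mean(fl[st == k]) / mean(fl)
    expect_equal(enr$fold[k], oracle, tolerance = 1e-12)
  }
  expect_equal(sum(enr$genome_frac * enr$fold), 1, tolerance = 1e-9)
})

test_that("TSS profiles flip minus-strand genes and match direct lookup", {
  asm <- genome_assembly("chr1", 1e6)
  st <- rep(2L, asm$n_bins[1])
  tss_pos <- 500000L
  st[(tss_pos / 25 + 1):((tss_pos + 1000) / 25)] <- 1L  # state 1 on [TSS, TSS+1kb)
  ann <- state_annotation(list(chr1 = st), asm, K = 2)
  plus <- tibble::tibble(chrom = "chr1", pos = tss_pos, strand = "+")
  prof_p <- tss_profile(ann, plus, window_bp = 4000, step_bp = 200)
  off_with_1 <- sort(prof_p$offset[prof_p$state == 1 & prof_p$freq > 0])
  expect_true(all(off_with_1 >= 0 & off_with_1 < 1000))

  minus <- dplyr::mutate(plus, strand = "-")
  prof_m <- tss_profile(ann, minus, window_bp = 4000, step_bp = 200)
  off_m <- sort(prof_m$offset[prof_m$state == 1 & prof_m$freq > 0])
  expect_equal(off_m, sort(-off_with_1))  # mirror image

  expect_error(tss_profile(ann, dplyr::mutate(plus, strand = ".")), "strand")

  # track profile equals brute-force per-gene lookup average
  tr <- random_track(asm, 82)
  genes <- tibble::tibble(chrom = "chr1", pos = c(300000L, 600000L),
                          strand = c("+", "-"))
  prof_t <- tss_profile(tr, genes, window_bp = 2000, step_bp = 200)
  offsets <- seq(-1000, 1000, 200)
  oracle <- vapply(offsets, function(o) {
    p <- genes$pos + ifelse(genes$strand == "-", -o, o)
    mean(chromscore:::track_value_at(tr, genes$chrom, p))
  }, numeric(1))
  expect_equal(prof_t$mean_score, oracle)
})

test_that("expression correlation recovers exact and null relationships", {
  asm <- genome_assembly("chr1", 1e6)
  n_g <- 30
  withr::with_seed(83, {
    tss <- tibble::tibble(chrom = "chr1",
                          pos = sort(sample.int(9e5, n_g) + 50000L),
                          strand = sample(c("+", "-"), n_g, replace = TRUE),
                          gene = paste0("g", 1:n_g))
    rpkm <- runif(n_g, 0, 50)
  })
  # plant the track at each TSS bin as an exact linear function of log expr
  vals <- numeric(asm$n_bins[1])
  vals[floor(tss$pos / 25) + 1] <- 0.1 + 0.02 * log2(rpkm + 1)
  tr <- toy_track(asm, values = list(chr1 = vals), name = "sc", cell_type = "ctA")
  expr <- tibble::tibble(gene = tss$gene, ctA = rpkm)
  cc <- expression_correlation(list(ctA = tr), tss, expr, window_bp = 2000)
  expect_equal(cc$r[cc$offset == 0], 1, tolerance = 1e-9)

  # closed-form oracle at a nonzero offset
  off <- 500
  p <- tss$pos + ifelse(tss$strand == "-", -off, off)
  v <- chromscore:::track_value_at(tr, tss$chrom, p)
  oracle <- if (sd(v) == 0) NA_real_ else cor(v, log2(rpkm + 1))
  got <- cc$r[cc$offset == off]
  if (is.na(oracle)) expect_true(is.na(got)) else expect_equal(got, oracle)

  # permuted expression: correlation near zero at the TSS
  withr::with_seed(84, expr_perm <- dplyr::mutate(expr, ctA = sample(ctA)))
  cp <- expression_correlation(list(ctA = tr), tss, expr_perm, window_bp = 2000)
  expect_lt(abs(cp$r[cp$offset == 0]), 2 / sqrt(n_g - 3))
  expect_error(expression_correlation(list(ctA = tr), tss[1:2, ], expr),
               "at least 3")
})

test_that("repeat quantile enrichment concentrates planted repeats in top scores", {
  asm <- genome_assembly("chr1", 5e5)
  n <- asm$n_bins[1]
  v <- seq(0, 1, length.out = n)
  tr <- toy_track(asm, values = list(chr1 = v), name = "sc")
  # repeats exactly where scores are in the top decile
  top_start <- floor(0.9 * n) * 25L
  reps <- list(LINE = tibble::tibble(chrom = "chr1", start = top_start,
                                     end = 500000L))
  enr <- repeat_quantile_enrichment(tr, reps, n_quantiles = 20,
                                    n_sample = 20000, seed = 85)
  expect_gt(mean(enr$fold[enr$quantile >= 19]), 5)
  expect_equal(mean(enr$fold[enr$quantile <= 10]), 0)
  # uniform placement: folds near 1 everywhere
  all_reps <- list(ALL = tibble::tibble(chrom = "chr1", start = 0L,
                                        end = 500000L))
  enr_u <- repeat_quantile_enrichment(tr, all_reps, n_quantiles = 20,
                                      n_sample = 20000, seed = 85)
  expect_equal(enr_u$fold, rep(1, 20))
})

test_that("track correlation matrices match brute-force Pearson", {
  asm <- genome_assembly("chr1", 250000)
  t1 <- random_track(asm, 86, name = "a")
  t2 <- random_track(asm, 87, name = "b")
  t3 <- t1
  t3$name <- "c"
  t3$values$chr1 <- 1 - t1$values$chr1  # exact negation
  r <- track_correlation_matrix(list(a = t1, b = t2, c = t3),
                                n_sample = 5000, seed = 88)
  expect_equal(diag(r), c(a = 1, b = 1, c = 1))
  expect_equal(r["a", "c"], -1)
  expect_equal(r, t(r))
  # brute-force oracle at the same sampled loci
  loci <- sample_neutral_background(asm, 5000, 1, seed = 88)
  x <- chromscore:::track_value_at(t1, loci$chrom, loci$pos)
  y <- chromscore:::track_value_at(t2, loci$chrom, loci$pos)
  expect_equal(r["a", "b"], cor(x, y), tolerance = 1e-12)
  const <- toy_track(asm, fill = 0.5, name = "k")
  rc <- track_correlation_matrix(list(a = t1, k = const), n_sample = 2000,
                                 seed = 89)
  expect_true(is.na(rc["a", "k"]))
})

test_that("per-state score distributions recover planted state means", {
  asm <- genome_assembly("chr1", 250000)
  st <- rep(1:2, length.out = asm$n_bins[1])
  vals <- ifelse(st == 1, 0.8, 0.2)
  tr <- toy_track(asm, values = list(chr1 = vals), name = "sc")
  ann <- state_annotation(list(chr1 = st), asm, K = 2)
  d <- score_distribution_by_state(tr, ann, n_sample = 5000, seed = 90)
  expect_equal(d$mean[d$state == 1], 0.8)
  expect_equal(d$mean[d$state == 2], 0.2)
  dc <- score_distribution_by_state(toy_track(asm, fill = 0.5), ann,
                                    n_sample = 2000, seed = 91)
  expect_true(all(dc$mean == 0.5))
})

test_that("variable-locus selection applies the cross-cell-type range rule", {
  asm <- genome_assembly("chr1", 250000)
  t1 <- random_track(asm, 92, name = "ct1")
  expect_warning(out0 <- select_variable_loci(list(a = t1, b = t1)),
                 "no loci")
  expect_equal(nrow(out0), 0)

  t2 <- t1
  t2$values$chr1 <- pmin(t1$values$chr1 + 0.3, 1)
  sel <- select_variable_loci(list(a = t1, b = t2), min_difference = 0.25,
                              n_loci = 100, seed = 93)
  expect_equal(nrow(sel), 100)
  # qualification equals the brute-force max-minus-min rule
  rng <- abs(t2$values$chr1 - t1$values$chr1)
  qual_bins <- which(rng >= 0.25)
  expect_true(all((floor(sel$pos / 25) + 1) %in% qual_bins))
  sel_all <- select_variable_loci(list(a = t1, b = t2), n_loci = 1e7,
                                  seed = 93)
  expect_equal(nrow(sel_all), length(qual_bins))
})
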