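test_that("class weights give a 0.25 weighted activating share for any counts", {
  cw <- make_class_weights(100, 300)
  expect_equal(cw$w_activating, 300)
  expect_equal(cw$w_neutral, 300)
  expect_equal(cw$weighted_activating_share, 0.25)
  expect_equal(make_class_weights(1, 1)$weighted_activating_share, 0.25)
  withr::with_seed(31, {
    for (i in 1:50) {
      n <- sample.int(10000, 2)
      expect_equal(make_class_weights(n[1], n[2])$weighted_activating_share,
                   0.25)
    }
  })
  expect_error(make_class_weights(0, 10), "positive")
})

test_that("the weighted ridge solver minimizes the stated objective", {
  withr::with_seed(32, {
    X <- matrix(rnorm(80 * 4), 80, 4)
    y <- rbinom(80, 1, plogis(X[, 1] - X[, 2]))
    w <- ifelse(y == 1, 2.5, 0.7)
  })
  fit <- chromscore:::fit_logistic_ridge(X, y, w, C = 1)
  expect_true(fit$converged)
  # independent oracle: general-purpose optimizer on the same objective
  obj <- function(b) {
    eta <- b[1] + X %*% b[-1]
    -sum(w * (y * eta - log(1 + exp(eta)))) + sum(b[-1]^2) / 2
  }
  orc <- optim(rep(0, 5), obj, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  expect_equal(unname(fit$coef), orc$par, tolerance = 1e-4)
  expect_lte(obj(fit$coef), orc$value + 1e-6)
})

test_that("ensembles are seed-reproducible and separate planted classes", {
  withr::with_seed(33, {
    X <- matrix(rnorm(200 * 5), 200, 5)
    y <- ifelse(X[, 1] > 0, "activating", "neutral")
  })
  colnames(X) <- paste0("f", 1:5)
  e1 <- train_expert(X, y, n_models = 10, seed = 9)
  e2 <- train_expert(X, y, n_models = 10, seed = 9)
  expect_identical(e1$coefs, e2$coefs)
  e3 <- train_expert(X, y, n_models = 10, seed = 10)
  expect_false(identical(e1$coefs, e3$coefs))
  expect_gte(auroc(predict_expert(e1, X), y), 0.99)
})

test_that("ensemble scores are the mean of member probabilities", {
  withr::with_seed(34, {
    X <- matrix(rnorm(100 * 3), 100, 3)
    y <- rep(c("activating", "neutral"), 50)
  })
  colnames(X) <- paste0("f", 1:3)
  ens <- train_expert(X, y, n_models = 7, seed = 2)
  got <- predict_expert(ens, X)
  oracle <- rowMeans(vapply(seq_len(7), function(m)
    plogis(ens$coefs[1, m] + X %*% ens$coefs[-1, m])[, 1], numeric(100)))
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_true(all(got >= 0 & got <= 1))
  Xbad <- X; colnames(Xbad) <- c("f1", "f2", "zz")
  expect_error(predict_expert(ens, Xbad), "do not match")
})

test_that("AUROC matches an all-pairs oracle and an external implementation", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(rep(0.5, 10), rep(c(1, 0), 5)), 0.5)
  withr::with_seed(35, {
    s <- round(runif(50), 1)  # ties on purpose
    y <- rbinom(50, 1, 0.4)
  })
  pos <- s[y == 1]; neg <- s[y == 0]
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(auroc(s, y), mean(pairs))
  skip_if_not_installed("pROC")
  expect_equal(auroc(s, y),
               as.numeric(pROC::auc(y, s, direction = "<", quiet = TRUE)))
})

test_that("within-dataset evaluation is stratified, seeded and leak-free", {
  # near-noiseless world so the planted signal is cleanly separable
  w <- make_world(n_chroms = 1, chrom_length = 4e5, n_elements = 50,
                  noise_sd = 0.02, seed = 77)
  r <- render_tracks(w, "ct1")
  labs <- world_labels(w, "ct1", seed = 78)
  ev <- evaluate_within_dataset(labs, r$tracks, r$peaks, r$ann,
                                n_partitions = 4, n_models = 5, seed = 6)
  ev2 <- evaluate_within_dataset(labs, r$tracks, r$peaks, r$ann,
                                 n_partitions = 4, n_models = 5, seed = 6)
  expect_identical(ev$auroc, ev2$auroc)
  expect_true(all(ev$auroc >= 0.95))  # planted low-noise signal

  # stratification contract on the splitter itself
  y <- rep(c("activating", "neutral"), c(40, 120))
  withr::with_seed(36, is_test <- chromscore:::stratified_split(y, 0.2))
  expect_equal(sum(is_test[y == "activating"]), 8)
  expect_equal(sum(is_test), 32)
})

test_that("spatial partitions assign whole 5 kb chunks at rate p_test", {
  asm <- genome_assembly("chr1", 5e7)
  part <- spatial_partition(asm, seed = 12)
  expect_equal(nrow(part), 10000)
  frac <- mean(part$partition == "test")
  expect_lt(abs(frac - 0.25), 3 * sqrt(0.25 * 0.75 / 10000))  # binomial CI
  # two loci in one chunk always share an assignment
  p <- partition_of(part, c("chr1", "chr1"), c(12345, 14999))
  expect_equal(p[1], p[2])
  expect_identical(spatial_partition(asm, seed = 12)$partition,
                   part$partition)
})

test_that("cell-type holdout recovers a shared chromatin-activity rule", {
  sw <- small_world()
  w <- sw$world
  datasets <- lapply(w$cell_types, function(ct)
    list(labels = world_labels(w, ct), dataset_id = paste0("d_", ct),
         cell_type = ct))
  tracks <- lapply(sw$rendered, `[[`, "tracks")
  peaks <- lapply(sw$rendered, `[[`, "peaks")
  anns <- lapply(sw$rendered, `[[`, "ann")
  ev <- evaluate_cell_type_holdout(datasets, tracks, peaks, anns,
                                   held_out_cell_type = "ct2",
                                   n_repetitions = 3, n_models = 5, seed = 13)
  expect_true(all(ev$scheme == "cell_type_holdout"))
  expect_true(all(ev$dataset_id == "d_ct2"))
  expect_true(all(ev$auroc > 0.9))
  expect_error(
    evaluate_cell_type_holdout(datasets[2], tracks, peaks, anns,
                               held_out_cell_type = "ct2"),
    "no training datasets"
  )
})

test_that("the chromatin-state baseline scores by training label fractions", {
  asm <- genome_assembly("chr1", 1000)
  ann <- state_annotation(list(chr1 = rep(1:2, each = 20)), asm, K = 3)
  labs <- labeled_regions(rep("chr1", 10), c(seq(0, 450, by = 50)),
                          c(rep("activating", 2), rep("neutral", 8)))
  b <- fit_state_baseline(labs, ann)
  expect_equal(b$score[1], 0.2)   # 2/10 positives, all in state 1
  expect_equal(b$score[3], 0.2)   # unseen state -> global fraction
  expect_equal(predict_state_baseline(b, ann, "chr1", 10), 0.2)
  # a label fully determined by state gives a perfect baseline
  labs2 <- labeled_regions(rep("chr1", 40), seq(0, 975, by = 25),
                           ifelse(rep(1:2, each = 20) == 1, "activating",
                                  "neutral"))
  b2 <- fit_state_baseline(labs2, ann)
  sc <- predict_state_baseline(b2, ann, labs2$chrom, labs2$pos)
  expect_equal(auroc(sc, labs2$label), 1)
})
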