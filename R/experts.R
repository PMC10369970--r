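#' Class weights for activating/neutral training
#'
#' The label-weight rule `w(activating) = n_neutral`,
#' `w(neutral) = 3 * n_activating` gives every dataset the same effective
#' activating share of the total weighted mass:
#' `w_a * n_a / (w_a * n_a + w_n * n_n) = 1/4` for any positive counts, i.e.
#' an effective 0.25 activating/neutral label ratio regardless of the raw
#' class imbalance.
#'
#' @param n_activating,n_neutral Positive label counts.
#' @return List with `w_activating`, `w_neutral` and the implied
#'   `weighted_activating_share`.
#' @examples
#' make_class_weights(100, 300)$weighted_activating_share  # 0.25
#' @export
make_class_weights <- function(n_activating, n_neutral) {
  if (n_activating <= 0 || n_neutral <= 0) {
    stop("both label counts must be positive")
  }
  n_activating <- as.numeric(n_activating)
  n_neutral <- as.numeric(n_neutral)
  w_a <- n_neutral
  w_n <- 3 * n_activating
  list(w_activating = w_a, w_neutral = w_n,
       weighted_activating_share =
         (w_a * n_activating) / (w_a * n_activating + w_n * n_neutral))
}

# Weighted L2-penalized logistic regression by Newton/IRLS.
# Objective: -sum_i w_i [y_i log p_i + (1-y_i) log(1-p_i)] + ||beta||^2 / (2C)
# with the intercept unpenalized. Deterministic; tol on the max coefficient
# change; damped steps if the objective increases.
fit_logistic_ridge <- function(X, y, weights, C = 1, tol = 1e-6,
                               max_iter = 1000L) {
  n <- nrow(X); p <- ncol(X)
  Xi <- cbind(`(Intercept)` = 1, X)
  pen <- c(0, rep(1 / C, p))
  beta <- numeric(p + 1)
  obj <- function(b) {
    eta <- drop(Xi %*% b)
    -sum(weights * (y * eta - log1p(exp(eta)))) + sum(pen * b^2) / 2
  }
  f_old <- obj(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(Xi %*% beta)
    mu <- stats::plogis(eta)
    g <- drop(crossprod(Xi, weights * (y - mu))) - pen * beta
    w_irls <- weights * mu * (1 - mu)
    H <- crossprod(Xi * sqrt(w_irls)) + diag(pen, p + 1)
    step <- tryCatch(solve(H, g), error = function(e)
      solve(H + diag(1e-8, p + 1), g))
    # halve the step until the objective does not increase
    lambda <- 1
    repeat {
      beta_new <- beta + lambda * step
      f_new <- obj(beta_new)
      if (is.finite(f_new) && f_new <= f_old + 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-8) { beta_new <- beta; f_new <- f_old; break }
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new; f_old <- f_new
    if (delta < tol) { converged <- TRUE; break }
  }
  list(coef = beta, converged = converged)
}

label01 <- function(label) {
  if (is.logical(label)) return(as.integer(label))
  if (is.numeric(label)) return(as.integer(label != 0))
  as.integer(label == "activating")
}

#' Train a bagging ensemble of weighted logistic regressions
#'
#' Fits `n_models` L2-penalized logistic members, each on a bootstrap
#' resample (with replacement, same size as the training set), with
#' per-sample class weights from [make_class_weights()] computed on the full
#' training set. Members that fail to converge are refit once on a fresh
#' resample and flagged.
#'
#' @param features Standardized numeric feature matrix with column names.
#' @param labels Vector of `"activating"`/`"neutral"` (or logical/0-1)
#'   labels, one per row.
#' @param n_models Ensemble size (default 100).
#' @param C L2 regularization strength (inverse penalty; default 1).
#' @param seed Integer seed; training is reproducible given the seed.
#' @param dataset_id,cell_type Metadata stamped onto the ensemble.
#' @param transforms Optional list with the `pcas` and `standardizer` used to
#'   build `features`, stored for genome-wide application.
#' @return An `expert_ensemble`: coefficient matrix `coefs`
#'   (`(1 + p) x n_models`), `feature_names`, `weights`, `transforms`,
#'   `converged` flags, metadata.
#' @export
train_expert <- function(features, labels, n_models = 100L, C = 1,
                         seed = 1L, dataset_id = NA_character_,
                         cell_type = NA_character_, transforms = NULL) {
  y <- label01(labels)
  n_a <- sum(y == 1); n_n <- sum(y == 0)
  if (n_a < 2 || n_n < 2) stop("need at least 2 examples of each class")
  cw <- make_class_weights(n_a, n_n)
  w <- ifelse(y == 1, cw$w_activating, cw$w_neutral)
  n <- nrow(features)
  coefs <- matrix(NA_real_, ncol(features) + 1, n_models)
  converged <- logical(n_models)
  withr::with_seed(seed, {
    for (m in seq_len(n_models)) {
      idx <- sample.int(n, n, replace = TRUE)
      fit <- fit_logistic_ridge(features[idx, , drop = FALSE], y[idx],
                                w[idx], C = C)
      if (!fit$converged) {  # one retry on a fresh resample
        idx <- sample.int(n, n, replace = TRUE)
        fit <- fit_logistic_ridge(features[idx, , drop = FALSE], y[idx],
                                  w[idx], C = C)
      }
      coefs[, m] <- fit$coef
      converged[m] <- fit$converged
    }
  })
  rownames(coefs) <- c("(Intercept)", colnames(features))
  structure(list(coefs = coefs, feature_names = colnames(features),
                 n_models = n_models, C = C, seed = seed,
                 weights = cw, converged = converged,
                 dataset_id = dataset_id, cell_type = cell_type,
                 transforms = transforms),
            class = "expert_ensemble")
}

#' @export
print.expert_ensemble <- function(x, ...) {
  cat(sprintf("<expert_ensemble> '%s' (%s): %d members, %d features, C=%g\n",
              x$dataset_id, x$cell_type, x$n_models,
              length(x$feature_names), x$C))
  invisible(x)
}

#' Predict activating probabilities with an expert ensemble
#'
#' The ensemble score is the mean of the members' predicted probabilities.
#'
#' @param ensemble An [train_expert()] ensemble.
#' @param features Standardized feature matrix whose columns match the
#'   ensemble's training features.
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
predict_expert <- function(ensemble, features) {
  if (!identical(colnames(features), ensemble$feature_names)) {
    stop("feature columns do not match the ensemble's training features")
  }
  eta <- cbind(1, features) %*% ensemble$coefs
  rowMeans(stats::plogis(eta))
}

#' Fit the full expert pipeline on labeled regions
#'
#' Convenience wrapper tying the feature pipeline to training: fits each
#' mark's window PCA and the feature standardizer on the given (training)
#' regions, assembles and standardizes the feature matrix, and trains the
#' bagging ensemble. The fitted transforms are stored in the ensemble so it
#' can be applied to new positions or genome-wide.
#'
#' @param labels Labeled-region tibble (`chrom`, `pos`, `label`, ...).
#' @param tracks,peaks,ann Cell-type-matched inputs as in
#'   [assemble_features()].
#' @inheritParams train_expert
#' @inheritParams assemble_features
#' @return An `expert_ensemble` with transforms attached.
#' @export
fit_expert <- function(labels, tracks, peaks, ann, n_models = 100L, C = 1,
                       seed = 1L, window_bp = 2000, step_bp = 25) {
  pcas <- lapply(tracks, function(tr) {
    fit_mark_pca(extract_signal_window(tr, labels$chrom, labels$pos,
                                       window_bp = window_bp,
                                       step_bp = step_bp))
  })
  feats <- assemble_features(labels, tracks, peaks, ann, pcas,
                             window_bp = window_bp, step_bp = step_bp)
  std <- fit_standardizer(feats)
  train_expert(apply_standardizer(std, feats), labels$label,
               n_models = n_models, C = C, seed = seed,
               dataset_id = labels$dataset_id[1],
               cell_type = labels$cell_type[1],
               transforms = list(pcas = pcas, standardizer = std,
                                 window_bp = window_bp, step_bp = step_bp))
}

#' Score arbitrary positions with a fitted expert
#'
#' Applies the ensemble's stored PCA and standardization transforms to
#' features extracted at the given positions (possibly in a different cell
#' type's tracks) and returns ensemble scores.
#'
#' @param ensemble A [fit_expert()] ensemble (with transforms).
#' @param regions Tibble with `chrom`, `pos`.
#' @param tracks,peaks,ann Inputs for the cell type being scored.
#' @return Numeric scores in `[0, 1]`.
#' @export
predict_expert_at <- function(ensemble, regions, tracks, peaks, ann) {
  tr <- ensemble$transforms
  if (is.null(tr)) stop("ensemble has no stored transforms; use fit_expert()")
  feats <- assemble_features(regions, tracks, peaks, ann, tr$pcas,
                             window_bp = tr$window_bp, step_bp = tr$step_bp)
  predict_expert(ensemble, apply_standardizer(tr$standardizer, feats))
}

#' Area under the ROC curve
#'
#' Mann-Whitney U formulation with midrank tie handling.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (`"activating"`/`"neutral"`, logical or 0/1).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  y <- label01(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)  # midranks on ties
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

stratified_split <- function(y, test_fraction, max_redraws = 100L) {
  # returns logical is_test; redraws if a partition ends up single-class
  for (k in seq_len(max_redraws)) {
    is_test <- logical(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      n_test <- round(length(idx) * test_fraction)
      is_test[sample(idx, n_test)] <- TRUE
    }
    if (length(unique(y[is_test])) == 2 && length(unique(y[!is_test])) == 2) {
      return(is_test)
    }
    message("single-class partition; redrawing (", k, ")")
  }
  stop("could not draw a two-class train/test partition")
}

#' Within-dataset cross-validated evaluation of an expert
#'
#' Draws `n_partitions` random stratified train/test splits (4:1 by
#' default), refits the whole pipeline (PCA, standardizer, ensemble) on each
#' training partition only, and reports the held-out AUROC per partition.
#'
#' @inheritParams fit_expert
#' @param n_partitions Number of random partitions (default 20).
#' @param test_fraction Held-out fraction per partition (default 0.2).
#' @param n_models,C,seed Ensemble configuration.
#' @return Tibble of class `expert_evaluation` with columns `dataset_id`,
#'   `scheme`, `repetition`, `auroc`.
#' @export
evaluate_within_dataset <- function(labels, tracks, peaks, ann,
                                    n_partitions = 20L, test_fraction = 0.2,
                                    n_models = 100L, C = 1, seed = 1L,
                                    window_bp = 2000, step_bp = 25) {
  y <- labels$label
  if (length(unique(y)) < 2) stop("dataset must contain both classes")
  aucs <- numeric(n_partitions)
  withr::with_seed(seed, {
    member_seeds <- sample.int(.Machine$integer.max - 1L, n_partitions)
    for (r in seq_len(n_partitions)) {
      is_test <- stratified_split(y, test_fraction)
      train_lab <- labels[!is_test, ]
      test_lab <- labels[is_test, ]
      ens <- fit_expert(train_lab, tracks, peaks, ann, n_models = n_models,
                        C = C, seed = member_seeds[r],
                        window_bp = window_bp, step_bp = step_bp)
      sc <- predict_expert_at(ens, test_lab, tracks, peaks, ann)
      aucs[r] <- auroc(sc, test_lab$label)
    }
  })
  out <- tibble::tibble(dataset_id = labels$dataset_id[1],
                        scheme = "within_dataset",
                        repetition = seq_len(n_partitions), auroc = aucs)
  class(out) <- c("expert_evaluation", class(out))
  out
}

#' Spatially partition the genome into train/test chunks
#'
#' Cuts every chromosome into `chunk_bp` chunks and assigns each chunk
#' independently to the test partition with probability `p_test`; all
#' positions in a chunk inherit its assignment, preventing leakage between
#' nearby train and test loci.
#'
#' @param assembly A [genome_assembly()].
#' @param chunk_bp Chunk width in bp (default 5000).
#' @param p_test Probability a chunk is assigned to testing (default 0.25).
#' @param seed Integer seed.
#' @return Tibble with `chrom`, `start`, `end`, `partition`
#'   (`"train"`/`"test"`), of class `spatial_partition`.
#' @export
spatial_partition <- function(assembly, chunk_bp = 5000, p_test = 0.25,
                              seed = 1L) {
  withr::with_seed(seed, {
    out <- purrr::map_dfr(seq_len(nrow(assembly)), function(i) {
      n_chunks <- ceiling(assembly$length[i] / chunk_bp)
      start <- (seq_len(n_chunks) - 1) * chunk_bp
      tibble::tibble(
        chrom = assembly$chrom[i],
        start = as.integer(start),
        end = as.integer(pmin(start + chunk_bp, assembly$length[i])),
        partition = ifelse(stats::runif(n_chunks) < p_test, "test", "train")
      )
    })
  })
  class(out) <- c("spatial_partition", class(out))
  attr(out, "chunk_bp") <- chunk_bp
  out
}

#' Look up the partition of genomic positions
#'
#' @param partition A [spatial_partition()].
#' @param chrom,pos Positions (0-based).
#' @return Character vector `"train"`/`"test"`.
#' @export
partition_of <- function(partition, chrom, pos) {
  chunk_bp <- attr(partition, "chunk_bp")
  key <- paste0(partition$chrom, ":", partition$start %/% chunk_bp)
  lut <- stats::setNames(partition$partition, key)
  out <- lut[paste0(chrom, ":", pos %/% chunk_bp)]
  if (anyNA(out)) stop("position outside the partitioned assembly")
  unname(out)
}

#' Cell-type-holdout evaluation of the combined expert score
#'
#' Trains one expert per dataset from every cell type except the held-out
#' one, then scores the held-out cell type's labeled loci with the mean of
#' the surviving experts (the combined ChromScore restricted to those
#' experts) and reports held-out AUROCs. Train/test loci are separated by a
#' random 5 kb spatial partition of the genome, redrawn each repetition;
#' training loci are restricted to train chunks and evaluation loci to test
#' chunks, so the held-out dataset never contributes training rows.
#'
#' @param datasets List of dataset descriptors, each a list with `labels`
#'   (labeled-region tibble), `dataset_id`, `cell_type`.
#' @param tracks_by_ct,peaks_by_ct,ann_by_ct Named lists (by cell type) of
#'   the per-cell-type inputs.
#' @param held_out_cell_type Cell type whose datasets are only evaluated.
#' @param n_repetitions Number of spatial-partition repetitions (default 20).
#' @param chunk_bp,p_test Spatial-partition geometry (defaults 5000, 0.25).
#' @inheritParams evaluate_within_dataset
#' @return Tibble of class `expert_evaluation` with one row per held-out
#'   dataset and repetition.
#' @export
evaluate_cell_type_holdout <- function(datasets, tracks_by_ct, peaks_by_ct,
                                       ann_by_ct, held_out_cell_type,
                                       n_repetitions = 20L, chunk_bp = 5000,
                                       p_test = 0.25, n_models = 100L, C = 1,
                                       seed = 1L, window_bp = 2000,
                                       step_bp = 25) {
  cts <- vapply(datasets, `[[`, "", "cell_type")
  train_sets <- datasets[cts != held_out_cell_type]
  test_sets <- datasets[cts == held_out_cell_type]
  if (length(train_sets) == 0) stop("no training datasets outside the held-out cell type")
  if (length(test_sets) == 0) stop("no dataset in the held-out cell type to evaluate")
  assembly <- tracks_by_ct[[1]][[1]]$assembly
  res <- list()
  withr::with_seed(seed, {
    rep_seeds <- sample.int(.Machine$integer.max - 1L, n_repetitions)
  })
  for (r in seq_len(n_repetitions)) {
    part <- spatial_partition(assembly, chunk_bp = chunk_bp, p_test = p_test,
                              seed = rep_seeds[r])
    experts <- list()
    for (d in train_sets) {
      lab <- d$labels
      lab <- lab[partition_of(part, lab$chrom, lab$pos) == "train", ]
      if (length(unique(lab$label)) < 2) next
      ct <- d$cell_type
      experts[[d$dataset_id]] <- fit_expert(
        lab, tracks_by_ct[[ct]], peaks_by_ct[[ct]], ann_by_ct[[ct]],
        n_models = n_models, C = C, seed = rep_seeds[r],
        window_bp = window_bp, step_bp = step_bp
      )
    }
    if (length(experts) == 0) stop("no surviving training experts in repetition ", r)
    for (d in test_sets) {
      lab <- d$labels
      lab <- lab[partition_of(part, lab$chrom, lab$pos) == "test", ]
      if (length(unique(lab$label)) < 2) next
      ct <- d$cell_type
      sc <- rowMeans(vapply(experts, function(e)
        predict_expert_at(e, lab, tracks_by_ct[[ct]], peaks_by_ct[[ct]],
                          ann_by_ct[[ct]]),
        numeric(nrow(lab))))
      res[[length(res) + 1]] <- tibble::tibble(
        dataset_id = d$dataset_id, scheme = "cell_type_holdout",
        repetition = r, auroc = auroc(sc, lab$label)
      )
    }
  }
  out <- dplyr::bind_rows(res)
  class(out) <- c("expert_evaluation", class(out))
  out
}

#' Chromatin-state baseline score
#'
#' Maps each chromatin state to the average fraction of activating labels it
#' carries in the training data; positions are then scored by their state's
#' fraction. States unseen in training fall back to the global activating
#' fraction.
#'
#' @param labels Training labeled-region tibble.
#' @param ann A [state_annotation()] for the matching cell type.
#' @return A `state_baseline`: per-state score vector plus the global
#'   fallback.
#' @export
fit_state_baseline <- function(labels, ann) {
  st <- state_at(ann, labels$chrom, labels$pos)
  y <- label01(labels$label)
  global <- mean(y)
  score <- vapply(seq_len(ann$K), function(k) {
    i <- st == k
    if (any(i)) mean(y[i]) else global
  }, numeric(1))
  structure(list(score = score, global = global, K = ann$K),
            class = "state_baseline")
}

#' @rdname fit_state_baseline
#' @param baseline A fitted `state_baseline`.
#' @param chrom,pos Positions to score.
#' @return Numeric scores (the training activating fraction of each
#'   position's state).
#' @export
predict_state_baseline <- function(baseline, ann, chrom, pos) {
  baseline$score[state_at(ann, chrom, pos)]
}
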