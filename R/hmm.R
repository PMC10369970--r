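#' Multivariate Bernoulli-emission hidden Markov models
#'
#' The genome-annotation model: `K` hidden states emit an `M`-vector of
#' independent Bernoulli observations per bin (one binary call per expert
#' track). The emission parameter `E[k, m]` is the probability that state
#' `k` shows a top-scoring call for expert `m`.
#'
#' @param pi Initial state distribution (length `K`, sums to 1).
#' @param A Transition matrix (`K x K`, rows sum to 1).
#' @param E Emission matrix (`K x M`, entries in `[0, 1]`).
#' @param track_names Optional expert/track names (length `M`).
#' @return An `hmm_model`.
#' @export
hmm_model <- function(pi, A, E, track_names = colnames(E)) {
  K <- length(pi)
  stopifnot(nrow(A) == K, ncol(A) == K, nrow(E) == K)
  if (abs(sum(pi) - 1) > 1e-8) stop("pi must sum to 1")
  if (any(abs(rowSums(A) - 1) > 1e-8)) stop("rows of A must sum to 1")
  if (any(E < 0 | E > 1)) stop("emission parameters must lie in [0, 1]")
  if (is.null(track_names)) track_names <- paste0("track_", seq_len(ncol(E)))
  colnames(E) <- track_names
  structure(list(K = K, M = ncol(E), pi = pi, A = A, E = E,
                 track_names = track_names),
            class = "hmm_model")
}

#' @export
print.hmm_model <- function(x, ...) {
  cat(sprintf("<hmm_model> K=%d states, M=%d Bernoulli tracks\n", x$K, x$M))
  invisible(x)
}

#' Randomly initialize a Bernoulli-emission HMM
#'
#' Draws a valid stochastic initial distribution and transition matrix, and
#' emissions uniformly in (0.05, 0.95); reproducible per seed.
#'
#' @param K Number of states (>= 2).
#' @param M Number of binary tracks (>= 1).
#' @param seed Integer seed.
#' @param track_names Optional track names.
#' @return An [hmm_model()].
#' @export
init_hmm <- function(K, M, seed = 1L, track_names = NULL) {
  stopifnot(K >= 2, M >= 1)
  withr::with_seed(seed, {
    pi <- stats::runif(K); pi <- pi / sum(pi)
    A <- matrix(stats::runif(K * K), K, K)
    # favor self-transitions so random initializations are segmentation-like
    diag(A) <- diag(A) + K
    A <- A / rowSums(A)
    E <- matrix(stats::runif(K * M, 0.05, 0.95), K, M)
  })
  hmm_model(pi, A, E, track_names = track_names)
}

# per-bin emission likelihoods for binary observations: B[t,k] =
# prod_m E[k,m]^o (1-E[k,m])^(1-o), computed in log space then exponentiated
emission_likelihoods <- function(model, seq) {
  E <- pmin(pmax(model$E, 1e-6), 1 - 1e-6)
  logB <- seq %*% t(log(E)) + (1 - seq) %*% t(log1p(-E))
  exp(logB)
}

#' Forward-backward posterior inference
#'
#' Scaled forward-backward recursions for one observation sequence. The
#' emission likelihood of observation `o` in state `k` is
#' `prod_m E[k,m]^o_m (1 - E[k,m])^(1 - o_m)`.
#'
#' @param model An [hmm_model()].
#' @param seq Binary observation matrix (`T x M`).
#' @return List with `posteriors` (`T x K`, rows sum to 1), `xi_sum`
#'   (`K x K` summed transition-pair expectations) and `log_likelihood`.
#' @export
forward_backward <- function(model, seq) {
  seq <- as.matrix(seq)
  storage.mode(seq) <- "double"
  if (ncol(seq) != model$M) stop("sequence has wrong number of tracks")
  fb <- .fb_scaled(model$pi, model$A, emission_likelihoods(model, seq))
  list(posteriors = fb$gamma, xi_sum = fb$xi_sum,
       log_likelihood = fb$loglik)
}

#' Baum-Welch training of the Bernoulli-emission HMM
#'
#' Concatenated training: all sequences (cell type x chromosome
#' combinations) share one parameter set; per iteration, expected counts are
#' accumulated over the sequences and the parameters re-estimated in closed
#' form. With `batch_size = NULL` (full batch) the total log-likelihood is
#' non-decreasing across iterations; with a finite `batch_size`, each
#' iteration uses that many randomly selected sequences (mirroring
#' subsampled training of genome segmentation models) and the monotonicity
#' guarantee is lost. Training runs for exactly `max_iter` iterations (no
#' likelihood-change stopping criterion). Emission parameters are clamped to
#' `[1e-6, 1 - 1e-6]`.
#'
#' @param model Starting [hmm_model()] (e.g. from [init_hmm()]).
#' @param sequences List of binary observation matrices (`T x M` each).
#' @param max_iter Number of EM iterations (default 200).
#' @param batch_size `NULL` for full batch, or the number of sequences
#'   randomly drawn per iteration (e.g. 128).
#' @param seed Seed for batch subsampling.
#' @return The fitted [hmm_model()] with an attached `loglik` attribute: the
#'   per-iteration total log-likelihood of the data used in that iteration.
#' @export
baum_welch <- function(model, sequences, max_iter = 200L, batch_size = NULL,
                       seed = 1L) {
  stopifnot(length(sequences) >= 1)
  sequences <- lapply(sequences, function(s) {
    s <- as.matrix(s); storage.mode(s) <- "double"; s
  })
  K <- model$K; M <- model$M
  ll_trace <- numeric(max_iter)
  withr::with_seed(seed, {
    for (it in seq_len(max_iter)) {
      batch <- if (is.null(batch_size) || batch_size >= length(sequences)) {
        sequences
      } else {
        sequences[sample.int(length(sequences), batch_size)]
      }
      pi_acc <- numeric(K)
      xi_acc <- matrix(0, K, K)
      e_num <- matrix(0, K, M)
      gamma_tot <- numeric(K)
      ll <- 0
      for (s in batch) {
        fb <- .fb_scaled(model$pi, model$A, emission_likelihoods(model, s))
        g <- fb$gamma
        pi_acc <- pi_acc + g[1, ]
        xi_acc <- xi_acc + fb$xi_sum
        e_num <- e_num + crossprod(g, s)
        gamma_tot <- gamma_tot + colSums(g)
        ll <- ll + fb$loglik
      }
      ll_trace[it] <- ll
      pi_new <- pi_acc / sum(pi_acc)
      A_new <- xi_acc / pmax(rowSums(xi_acc), .Machine$double.xmin)
      E_new <- e_num / pmax(gamma_tot, .Machine$double.xmin)
      E_new <- pmin(pmax(E_new, 1e-6), 1 - 1e-6)
      model <- hmm_model(pi_new, A_new, E_new, track_names = model$track_names)
    }
  })
  attr(model, "loglik") <- ll_trace
  model
}

#' Fit a Bernoulli-emission HMM with random restarts
#'
#' Runs [baum_welch()] from `n_restarts` independent random initializations
#' and keeps the fit with the highest final log-likelihood; EM on these
#' models is sensitive to initialization, and a small number of restarts
#' reliably avoids poor local optima.
#'
#' @param sequences List of binary observation matrices (`T x M`).
#' @param K Number of states.
#' @param n_restarts Number of random initializations (default 3).
#' @param track_names Optional track names.
#' @inheritParams baum_welch
#' @return The best fitted [hmm_model()] (per-iteration log-likelihoods of
#'   the winning run in the `loglik` attribute).
#' @export
fit_hmm <- function(sequences, K, n_restarts = 3L, max_iter = 200L,
                    batch_size = NULL, seed = 1L, track_names = NULL) {
  M <- ncol(sequences[[1]])
  withr::with_seed(seed, {
    init_seeds <- sample.int(.Machine$integer.max - 1L, n_restarts)
  })
  best <- NULL
  best_ll <- -Inf
  for (s in init_seeds) {
    fit <- baum_welch(init_hmm(K, M, seed = s, track_names = track_names),
                      sequences, max_iter = max_iter,
                      batch_size = batch_size, seed = s)
    ll <- utils::tail(attr(fit, "loglik"), 1)
    if (ll > best_ll) { best <- fit; best_ll <- ll }
  }
  best
}

#' Decode a sequence to per-bin states
#'
#' Assigns each bin the state with maximal posterior probability (ties break
#' to the lowest state index). This is per-bin posterior decoding, not
#' Viterbi: adjacent assignments need not form the single most probable
#' joint path.
#'
#' @param model An [hmm_model()].
#' @param seq Binary observation matrix (`T x M`).
#' @return Integer vector of state indices in `1..K`.
#' @export
decode <- function(model, seq) {
  post <- forward_backward(model, seq)$posteriors
  max.col(post, ties.method = "first")
}

#' Renumber HMM states by decreasing mean emission
#'
#' States are permuted so the mean emission parameter over tracks is
#' non-increasing in the state index (ties keep their original relative
#' order); `pi`, `A` and `E` are permuted consistently, leaving every
#' sequence likelihood unchanged.
#'
#' @param model An [hmm_model()].
#' @return The renumbered [hmm_model()].
#' @export
order_states <- function(model) {
  means <- rowMeans(model$E)
  ord <- order(-means)  # stable in R
  hmm_model(model$pi[ord], model$A[ord, ord, drop = FALSE],
            model$E[ord, , drop = FALSE], track_names = model$track_names)
}

#' Group HMM states by their expert emission pattern
#'
#' * `multi_expert`: at least two experts with emission `>= 0.20`;
#' * `single_expert`: exactly one expert with emission `>= 0.90` and all
#'   others `< 0.10`;
#' * `no_expert`: all emissions `< 0.001`;
#' * `unclassified`: none of the above.
#'
#' @param model An [hmm_model()].
#' @return Tibble with `state`, `group` and the per-state mean emission.
#' @export
classify_states <- function(model) {
  E <- model$E
  group <- vapply(seq_len(model$K), function(k) {
    e <- E[k, ]
    if (sum(e >= 0.20) >= 2) return("multi_expert")
    if (sum(e >= 0.90) == 1 && sum(e >= 0.10) == 1) return("single_expert")
    if (all(e < 0.001)) return("no_expert")
    "unclassified"
  }, "")
  tibble::tibble(state = seq_len(model$K), group = group,
                 mean_emission = rowMeans(E))
}

#' Binarize expert score tracks at a top-fraction threshold
#'
#' For each expert track the threshold is the score of the
#' `ceiling(top_fraction * N)`-th highest bin; bins scoring at or above it
#' are 1, the rest 0. On tie-free tracks exactly `ceiling(top_fraction * N)`
#' bins are marked; ties at the threshold are all included, so the marked
#' fraction can exceed `top_fraction`.
#'
#' @param tracks Named list of expert score [signal_track()]s.
#' @param top_fraction Fraction of bins to mark (default 0.02).
#' @return A `binary_calls` object: per-chromosome binary matrices (bins x
#'   experts) plus the per-expert thresholds.
#' @export
binarize_tracks <- function(tracks, top_fraction = 0.02) {
  stopifnot(top_fraction > 0, top_fraction < 1)
  if (is.null(names(tracks))) {
    names(tracks) <- vapply(tracks, `[[`, "", "name")
  }
  thresholds <- vapply(tracks, function(t) {
    v <- track_values(t)
    if (max(v) == min(v)) {
      warning("constant track '", t$name, "': no bins binarized")
      return(Inf)
    }
    k <- ceiling(top_fraction * length(v))
    sort(v, decreasing = TRUE)[k]
  }, numeric(1))
  chroms <- names(tracks[[1]]$values)
  calls <- lapply(chroms, function(ch) {
    m <- vapply(names(tracks), function(e)
      as.integer(tracks[[e]]$values[[ch]] >= thresholds[[e]]),
      integer(length(tracks[[1]]$values[[ch]])))
    if (is.null(dim(m))) m <- matrix(m, nrow = 1,
                                     dimnames = list(NULL, names(tracks)))
    m
  })
  names(calls) <- chroms
  structure(list(calls = calls, thresholds = thresholds,
                 experts = names(tracks), top_fraction = top_fraction,
                 assembly = tracks[[1]]$assembly,
                 cell_type = tracks[[1]]$cell_type),
            class = "binary_calls")
}

#' @export
print.binary_calls <- function(x, ...) {
  cat(sprintf("<binary_calls> %d expert(s) x %s bins (top %.1f%%)\n",
              length(x$experts),
              format(sum(vapply(x$calls, nrow, 1L)), big.mark = ","),
              100 * x$top_fraction))
  invisible(x)
}

#' Write binary calls in the binarized text layout
#'
#' One file per chromosome: a header line `cell<TAB>chrom`, a line of expert
#' names, then one 0/1 row per bin.
#'
#' @param calls A [binarize_tracks()] object.
#' @param dir Output directory; files are named
#'   `<cell>_<chrom>_binary.txt`.
#' @return The written paths, invisibly.
#' @export
write_binary_calls <- function(calls, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cell <- calls$cell_type %||% "cell"
  paths <- vapply(names(calls$calls), function(ch) {
    path <- file.path(dir, paste0(cell, "_", ch, "_binary.txt"))
    con <- file(path, "wt")
    writeLines(paste(cell, ch, sep = "\t"), con)
    writeLines(paste(calls$experts, collapse = "\t"), con)
    utils::write.table(calls$calls[[ch]], con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    close(con)
    path
  }, "")
  invisible(paths)
}

#' Segment binary calls into a state annotation
#'
#' Decodes every chromosome of a cell type's binary calls with the fitted
#' HMM and returns the resulting genome segmentation.
#'
#' @param model A fitted [hmm_model()].
#' @param calls A [binarize_tracks()] object on the model's tracks.
#' @return A [state_annotation()] with `K` = `model$K`.
#' @export
segment_genome <- function(model, calls) {
  states <- lapply(calls$calls, function(m) decode(model, m))
  state_annotation(states, calls$assembly, K = model$K)
}

#' Simulate from a Bernoulli-emission HMM
#'
#' Samples a hidden state path from `pi`/`A` and binary observations from
#' the per-state Bernoulli emissions; the hidden path is returned for
#' parameter-recovery checks.
#'
#' @param model An [hmm_model()].
#' @param T_len Sequence length in bins.
#' @param seed Integer seed.
#' @return List with `observations` (`T x M` binary matrix) and `path`
#'   (integer states).
#' @export
simulate_hmm <- function(model, T_len, seed = 1L) {
  withr::with_seed(seed, {
    path <- integer(T_len)
    path[1] <- sample.int(model$K, 1, prob = model$pi)
    for (t in seq_len(T_len - 1)) {
      path[t + 1] <- sample.int(model$K, 1, prob = model$A[path[t], ])
    }
    obs <- matrix(stats::rbinom(T_len * model$M, 1,
                                model$E[path, ]),
                  T_len, model$M, dimnames = list(NULL, model$track_names))
  })
  list(observations = obs, path = path)
}

#' Write an HMM model as TSV blocks
#'
#' @param model An [hmm_model()].
#' @param path Output path (sections `#pi`, `#A`, `#E`).
#' @return `path`, invisibly.
#' @export
write_hmm_model <- function(model, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("#pi", con)
  writeLines(paste(format(model$pi, digits = 15), collapse = "\t"), con)
  writeLines("#A", con)
  utils::write.table(format(model$A, digits = 15), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines("#E", con)
  writeLines(paste(model$track_names, collapse = "\t"), con)
  utils::write.table(format(model$E, digits = 15), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
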