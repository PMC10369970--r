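# Shared desk-scale fixtures, all generated in code.

tiny_assembly <- function(lengths = c(chr1 = 1000, chr2 = 500)) {
  genome_assembly(names(lengths), unname(lengths))
}

# a track with given per-chromosome values (recycled/padded with zeros)
toy_track <- function(assembly, values = NULL, name = "toy",
                      cell_type = "ctA", fill = 0) {
  nb <- setNames(assembly$n_bins, assembly$chrom)
  vals <- lapply(assembly$chrom, function(ch) {
    v <- rep(fill, nb[[ch]])
    if (!is.null(values[[ch]])) {
      v[seq_along(values[[ch]])] <- values[[ch]]
    }
    v
  })
  names(vals) <- assembly$chrom
  signal_track(vals, assembly, name = name, cell_type = cell_type)
}

random_track <- function(assembly, seed, name = "rnd", cell_type = "ctA") {
  nb <- setNames(assembly$n_bins, assembly$chrom)
  withr::with_seed(seed, {
    vals <- lapply(assembly$chrom, function(ch) runif(nb[[ch]]))
  })
  names(vals) <- assembly$chrom
  signal_track(vals, assembly, name = name, cell_type = cell_type)
}

# small planted world shared by feature/expert tests (built once per run)
small_world_env <- new.env()
small_world <- function() {
  if (is.null(small_world_env$w)) {
    small_world_env$w <- make_world(n_chroms = 1, chrom_length = 4e5,
                                    n_elements = 30, n_cell_types = 2,
                                    noise_sd = 0.05, seed = 42)
    small_world_env$r <- lapply(small_world_env$w$cell_types, function(ct)
      render_tracks(small_world_env$w, ct))
    names(small_world_env$r) <- small_world_env$w$cell_types
  }
  list(world = small_world_env$w, rendered = small_world_env$r)
}

world_labels <- function(world, ct, seed = 5) {
  assay <- render_assay(world, ct, "starr_peaks", seed = seed)
  act <- label_threshold_peaks(assay, 0, dataset_id = paste0("d_", ct),
                               cell_type = ct)
  neu <- sample_neutral_background(world$assembly, nrow(act), 3,
                                   seed = seed + 1,
                                   dataset_id = paste0("d_", ct),
                                   cell_type = ct)
  dplyr::bind_rows(act, neu)
}

# brute-force HMM log-likelihood by full path enumeration (tiny T, K)
enumerate_loglik <- function(model, obs) {
  T_len <- nrow(obs); K <- model$K
  E <- pmin(pmax(model$E, 1e-6), 1 - 1e-6)
  emit <- function(k, t) prod(E[k, ]^obs[t, ] * (1 - E[k, ])^(1 - obs[t, ]))
  paths <- expand.grid(rep(list(seq_len(K)), T_len))
  total <- 0
  for (i in seq_len(nrow(paths))) {
    p <- as.integer(paths[i, ])
    pr <- model$pi[p[1]] * emit(p[1], 1)
    if (T_len > 1) {
      for (t in 2:T_len) pr <- pr * model$A[p[t - 1], p[t]] * emit(p[t], t)
    }
    total <- total + pr
  }
  log(total)
}

# brute-force per-bin posteriors by path enumeration
enumerate_posteriors <- function(model, obs) {
  T_len <- nrow(obs); K <- model$K
  E <- pmin(pmax(model$E, 1e-6), 1 - 1e-6)
  emit <- function(k, t) prod(E[k, ]^obs[t, ] * (1 - E[k, ])^(1 - obs[t, ]))
  paths <- expand.grid(rep(list(seq_len(K)), T_len))
  w <- numeric(nrow(paths))
  for (i in seq_len(nrow(paths))) {
    p <- as.integer(paths[i, ])
    pr <- model$pi[p[1]] * emit(p[1], 1)
    if (T_len > 1) {
      for (t in 2:T_len) pr <- pr * model$A[p[t - 1], p[t]] * emit(p[t], t)
    }
    w[i] <- pr
  }
  post <- matrix(0, T_len, K)
  for (t in seq_len(T_len)) {
    for (k in seq_len(K)) post[t, k] <- sum(w[paths[, t] == k])
  }
  post / rowSums(post)
}

# match estimated states to true states by greedy emission distance
match_states <- function(E_hat, E_true) {
  K <- nrow(E_true)
  perm <- integer(K)
  used <- logical(K)
  for (k in seq_len(K)) {
    d <- apply(E_hat, 1, function(r) sum(abs(r - E_true[k, ])))
    d[used] <- Inf
    perm[k] <- which.min(d)
    used[perm[k]] <- TRUE
  }
  perm
}
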