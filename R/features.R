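#' Signal window features around reference nucleotides
#'
#' Samples a mark's binned signal at fixed offsets in a window centered on
#' each reference nucleotide: offsets `-window_bp/2, ..., 0, ..., +window_bp/2`
#' in steps of `step_bp` (81 positions for the default 2 kb window at 25 bp
#' steps). Each offset position is mapped to its bin; offsets falling off the
#' chromosome read as 0.
#'
#' @param track A [signal_track()].
#' @param chrom,pos Vectors of reference nucleotides (0-based).
#' @param window_bp Total window width in bp (default 2000).
#' @param step_bp Sampling step in bp (default 25).
#' @return Numeric matrix, one row per position, `window_bp / step_bp + 1`
#'   columns named by offset.
#' @export
extract_signal_window <- function(track, chrom, pos, window_bp = 2000,
                                  step_bp = 25) {
  offsets <- seq(-window_bp / 2, window_bp / 2, by = step_bp)
  bs <- bin_size_of(track$assembly)
  out <- matrix(0, nrow = length(pos), ncol = length(offsets),
                dimnames = list(NULL, paste0("off", offsets)))
  for (ch in unique(chrom)) {
    v <- track$values[[ch]]
    if (is.null(v)) stop("unknown chromosome: ", ch)
    i <- which(chrom == ch)
    # positions matrix: rows loci, cols offsets
    p <- outer(pos[i], offsets, `+`)
    b <- floor(p / bs) + 1
    ok <- p >= 0 & b <= length(v)
    vals <- matrix(0, nrow = length(i), ncol = length(offsets))
    vals[ok] <- v[b[ok]]
    out[i, ] <- vals
  }
  out
}

#' Per-mark PCA of window features
#'
#' Mean-centered (not scaled) PCA of a mark's window-feature matrix, keeping
#' the top `n_components` components. Loading signs are fixed by making each
#' component's largest-magnitude entry positive so fits are reproducible
#' across linear-algebra backends. If the data rank is below `n_components`
#' the remaining loadings are zero and flagged.
#'
#' @param window_matrix Numeric matrix (regions x window features), at least
#'   4 rows.
#' @param n_components Number of components to keep (default 3).
#' @return An object of class `mark_pca`: `mean` (feature means), `loadings`
#'   (features x `n_components`, orthonormal), `explained_fraction`,
#'   `rank_deficient` flag.
#' @export
fit_mark_pca <- function(window_matrix, n_components = 3L) {
  if (nrow(window_matrix) < 4) stop("need at least 4 rows to fit PCA")
  pc <- stats::prcomp(window_matrix, center = TRUE, scale. = FALSE)
  total_var <- sum(pc$sdev^2)
  k_avail <- sum(pc$sdev > 1e-12)
  k <- min(n_components, k_avail)
  loadings <- matrix(0, ncol(window_matrix), n_components)
  expl <- numeric(n_components)
  if (k > 0) {
    L <- pc$rotation[, seq_len(k), drop = FALSE]
    for (j in seq_len(k)) {
      top <- which.max(abs(L[, j]))
      if (L[top, j] < 0) L[, j] <- -L[, j]
    }
    loadings[, seq_len(k)] <- L
    expl[seq_len(k)] <- if (total_var > 0) pc$sdev[seq_len(k)]^2 / total_var else 0
  }
  structure(list(mean = pc$center, loadings = loadings,
                 explained_fraction = expl,
                 rank_deficient = k < n_components),
            class = "mark_pca")
}

#' Project window features onto a fitted mark PCA
#'
#' @param pca A [fit_mark_pca()] object.
#' @param windows Numeric matrix (or single vector) of window features with
#'   the same number of columns the PCA was fitted on.
#' @return Matrix of component scores (regions x components).
#' @export
apply_mark_pca <- function(pca, windows) {
  if (is.null(dim(windows))) windows <- matrix(windows, nrow = 1)
  sweep(windows, 2, pca$mean) %*% pca$loadings
}

#' Peak presence at reference nucleotides
#'
#' @param peaks Interval tibble (`chrom`, `start`, `end`).
#' @param chrom,pos Reference nucleotides (0-based).
#' @return Integer 0/1 vector: 1 iff some half-open interval contains the
#'   position.
#' @export
peak_indicator <- function(peaks, chrom, pos) {
  as.integer(point_in_intervals(peaks, chrom, pos))
}

#' One-hot chromatin-state encoding at reference nucleotides
#'
#' @param ann A [state_annotation()].
#' @param chrom,pos Reference nucleotides (0-based).
#' @return Integer matrix (positions x K) with exactly one 1 per row.
#' @export
state_onehot <- function(ann, chrom, pos) {
  st <- state_at(ann, chrom, pos)
  out <- matrix(0L, length(st), ann$K,
                dimnames = list(NULL, paste0("state_", seq_len(ann$K))))
  out[cbind(seq_along(st), st)] <- 1L
  out
}

#' Assemble the per-region feature matrix
#'
#' Builds the full classification feature matrix: for each mark its top
#' window-PCA components and the raw signal at the reference nucleotide,
#' then a peak indicator per mark, then the one-hot chromatin-state encoding
#' -- `5 * M + K` columns in a frozen order (85 for 12 marks and 25 states).
#' Column order: `mark1_PC1..PC3, mark2_PC1..., ..., mark1_signal, ...,
#' mark1_peak, ..., state_1..state_K`.
#'
#' @param regions Tibble with `chrom`, `pos` reference nucleotides.
#' @param tracks Named list of [signal_track()]s, one per mark.
#' @param peaks Named list of peak interval tibbles, same names as `tracks`.
#' @param ann A [state_annotation()].
#' @param pcas Named list of [fit_mark_pca()] objects, same names as
#'   `tracks`, fitted on the training partition.
#' @param window_bp,step_bp Window geometry passed to
#'   [extract_signal_window()].
#' @return Numeric matrix (regions x features) with frozen column names.
#' @export
assemble_features <- function(regions, tracks, peaks, ann, pcas,
                              window_bp = 2000, step_bp = 25) {
  marks <- names(tracks)
  if (is.null(marks)) stop("`tracks` must be a named list of marks")
  if (!identical(sort(marks), sort(names(peaks))) ||
      !identical(sort(marks), sort(names(pcas)))) {
    stop("tracks, peaks and pcas must cover the same marks")
  }
  n <- nrow(regions)
  n_pc <- ncol(pcas[[marks[1]]]$loadings)
  pc_block <- matrix(0, n, n_pc * length(marks))
  sig_block <- matrix(0, n, length(marks))
  peak_block <- matrix(0, n, length(marks))
  pc_names <- character(0)
  for (m in seq_along(marks)) {
    mk <- marks[m]
    W <- extract_signal_window(tracks[[mk]], regions$chrom, regions$pos,
                               window_bp = window_bp, step_bp = step_bp)
    pc_block[, (m - 1) * n_pc + seq_len(n_pc)] <- apply_mark_pca(pcas[[mk]], W)
    pc_names <- c(pc_names, paste0(mk, "_PC", seq_len(n_pc)))
    sig_block[, m] <- track_value_at(tracks[[mk]], regions$chrom, regions$pos)
    peak_block[, m] <- peak_indicator(peaks[[mk]], regions$chrom, regions$pos)
  }
  oh <- state_onehot(ann, regions$chrom, regions$pos)
  out <- cbind(pc_block, sig_block, peak_block, oh)
  colnames(out) <- c(pc_names, paste0(marks, "_signal"),
                     paste0(marks, "_peak"), colnames(oh))
  out
}

#' Fit / apply feature standardization
#'
#' `fit_standardizer()` learns per-column means and standard deviations on
#' the training rows; `apply_standardizer()` centers and scales any matrix
#' with those training parameters (never refit on test rows). Zero-variance
#' columns are flagged and map to all zeros.
#'
#' @param train Numeric feature matrix with column names.
#' @return A `standardizer` object (`mean`, `sd`, `zero_variance`,
#'   `feature_names`).
#' @export
fit_standardizer <- function(train) {
  if (nrow(train) == 0) stop("empty training matrix")
  mu <- colMeans(train)
  sdev <- apply(train, 2, stats::sd)
  zero <- !is.finite(sdev) | sdev < 1e-12
  sdev[zero] <- 1
  structure(list(mean = mu, sd = sdev, zero_variance = zero,
                 feature_names = colnames(train)),
            class = "standardizer")
}

#' @rdname fit_standardizer
#' @param s A fitted `standardizer`.
#' @param m Feature matrix to transform (columns must match the training
#'   feature names).
#' @export
apply_standardizer <- function(s, m) {
  if (!identical(colnames(m), s$feature_names)) {
    stop("feature columns do not match the standardizer's training features")
  }
  out <- sweep(sweep(m, 2, s$mean), 2, s$sd, `/`)
  if (any(s$zero_variance)) out[, s$zero_variance] <- 0
  out
}
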