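# bin-level overlap flags for an interval set: TRUE for every bin the
# intervals cover by >= 1 bp, per chromosome of the assembly
interval_bin_flags <- function(intervals, assembly) {
  bs <- bin_size_of(assembly)
  nb <- assembly_nbins(assembly)
  flags <- lapply(nb, function(n) logical(n))
  if (nrow(intervals) > 0) {
    check_chrom(assembly, intervals$chrom)
    for (i in seq_len(nrow(intervals))) {
      ch <- intervals$chrom[i]
      b <- (floor(intervals$start[i] / bs) + 1):
        min(floor((intervals$end[i] - 1) / bs) + 1, nb[[ch]])
      flags[[ch]][b] <- TRUE
    }
  }
  flags
}

#' Overlap fold enrichment of states with an annotation
#'
#' For every state of a segmentation, the fold enrichment of an annotation
#' (intervals) is the fraction of the state's bins that the annotation
#' overlaps, divided by the fraction of all genome bins it overlaps. A bin
#' counts as overlapped if the annotation covers at least 1 bp of it. The
#' per-state folds satisfy the mixture identity
#' `sum_k genome_frac(k) * fold(k) = 1`.
#'
#' @param ann A [state_annotation()].
#' @param annotation Interval tibble (`chrom`, `start`, `end`), on the same
#'   assembly.
#' @param annotation_name Label for the output rows.
#' @return Tibble of class `enrichment_table` with `state`, `state_name`,
#'   `annotation`, `genome_frac` (state coverage), `overlap_frac`
#'   (annotation coverage within the state) and `fold`. Folds are `NA` when
#'   the annotation covers zero bins.
#' @export
overlap_fold_enrichment <- function(ann, annotation,
                                    annotation_name = "annotation") {
  flags <- interval_bin_flags(annotation, ann$assembly)
  st <- unlist(ann$states, use.names = FALSE)
  fl <- unlist(flags[names(ann$states)], use.names = FALSE)
  n_total <- length(st)
  bg <- mean(fl)
  out <- purrr::map_dfr(seq_len(ann$K), function(k) {
    in_state <- st == k
    n_state <- sum(in_state)
    ov <- if (n_state > 0) mean(fl[in_state]) else NA_real_
    tibble::tibble(
      state = k, state_name = ann$state_names[k],
      annotation = annotation_name,
      genome_frac = n_state / n_total,
      overlap_frac = ov,
      fold = if (bg > 0 && n_state > 0) ov / bg else NA_real_
    )
  })
  class(out) <- c("enrichment_table", class(out))
  out
}

flip_offsets <- function(offsets, strand) {
  ifelse(strand == "-", -offsets, offsets)
}

#' Positional profile around transcription start sites
#'
#' Samples a segmentation (state frequencies) or a score track (mean score)
#' at fixed offsets in windows centered on TSSs. For minus-strand genes the
#' offsets are flipped so positive offsets always point into the gene body.
#' Offsets falling outside a chromosome are dropped for that gene.
#'
#' @param x A [state_annotation()] or [signal_track()].
#' @param tss Tibble with `chrom`, `pos` (0-based TSS) and `strand`
#'   (`"+"`/`"-"`).
#' @param window_bp Total window width (default 24000).
#' @param step_bp Sampling step (default 200).
#' @return For an annotation: tibble of class `tss_profile` with `offset`,
#'   `state`, `state_name`, `freq`. For a track: `offset`, `mean_score`,
#'   `n_genes`.
#' @export
tss_profile <- function(x, tss, window_bp = 24000, step_bp = 200) {
  if (!"strand" %in% names(tss) || anyNA(tss$strand) ||
      !all(tss$strand %in% c("+", "-"))) {
    stop("every TSS must carry a '+' or '-' strand")
  }
  offsets <- seq(-window_bp / 2, window_bp / 2, by = step_bp)
  # genomic position of each (gene, offset): flip offsets on minus strand
  n_g <- nrow(tss)
  gpos <- outer(tss$pos, offsets, `+`)
  neg <- tss$strand == "-"
  if (any(neg)) gpos[neg, ] <- outer(tss$pos[neg], -offsets, `+`)
  long <- tibble::tibble(
    gene = rep(seq_len(n_g), times = length(offsets)),
    chrom = rep(tss$chrom, times = length(offsets)),
    offset = rep(offsets, each = n_g),
    pos = as.vector(gpos)
  )
  if (inherits(x, "state_annotation")) {
    lens <- assembly_lengths(x$assembly)
    long <- long[long$pos >= 0 & long$pos < lens[long$chrom], ]
    long$state <- state_at(x, long$chrom, long$pos)
    out <- dplyr::count(long, .data$offset, .data$state, name = "n")
    out <- dplyr::mutate(
      dplyr::group_by(out, .data$offset),
      freq = .data$n / sum(.data$n)
    )
    out <- dplyr::ungroup(out)
    out$state_name <- x$state_names[out$state]
    out <- out[, c("offset", "state", "state_name", "freq")]
  } else if (inherits(x, "signal_track")) {
    lens <- assembly_lengths(x$assembly)
    long <- long[long$pos >= 0 & long$pos < lens[long$chrom], ]
    long$score <- track_value_at(x, long$chrom, long$pos)
    out <- dplyr::summarise(dplyr::group_by(long, .data$offset),
                            mean_score = mean(.data$score),
                            n_genes = dplyr::n(), .groups = "drop")
  } else {
    stop("x must be a state_annotation or a signal_track")
  }
  class(out) <- c("tss_profile", class(out))
  out
}

#' Per-offset correlation between scores near TSSs and gene expression
#'
#' For each offset in a window around the TSS, computes the Pearson
#' correlation across genes between the track value at that offset and
#' `log2(RPKM + 1)` expression, per cell type, then averages the
#' correlations over cell types. Minus-strand windows are mirrored.
#'
#' @param tracks Named list of [signal_track()]s, one per cell type (names
#'   must match expression columns).
#' @param tss Tibble with `chrom`, `pos`, `strand`, `gene`.
#' @param expr Expression tibble: `gene` column plus one RPKM column per
#'   cell type.
#' @param window_bp,step_bp Window geometry (defaults 24000, 25).
#' @return Tibble with `offset`, `r` (mean over cell types) and `n_cell_types`.
#' @export
expression_correlation <- function(tracks, tss, expr, window_bp = 24000,
                                   step_bp = 25) {
  cts <- names(tracks)
  if (is.null(cts) || !all(cts %in% names(expr))) {
    stop("track names must match expression columns (cell types)")
  }
  genes <- dplyr::inner_join(tss, expr, by = "gene")
  if (nrow(genes) < 3) stop("need at least 3 genes with expression")
  offsets <- seq(-window_bp / 2, window_bp / 2, by = step_bp)
  per_ct <- lapply(cts, function(ct) {
    track <- tracks[[ct]]
    lens <- assembly_lengths(track$assembly)
    logexp <- log2(genes[[ct]] + 1)
    vapply(offsets, function(off) {
      gpos <- genes$pos + flip_offsets(off, genes$strand)
      ok <- gpos >= 0 & gpos < lens[genes$chrom]
      if (sum(ok) < 3) return(NA_real_)
      v <- track_value_at(track, genes$chrom[ok], gpos[ok])
      if (stats::sd(v) == 0 || stats::sd(logexp[ok]) == 0) return(NA_real_)
      stats::cor(v, logexp[ok])
    }, numeric(1))
  })
  r_mat <- do.call(cbind, per_ct)
  tibble::tibble(offset = offsets,
                 r = rowMeans(r_mat, na.rm = TRUE),
                 n_cell_types = rowSums(!is.na(r_mat)))
}

#' Repeat-element enrichment across score quantiles
#'
#' Samples genomic positions, groups them into equal-mass score quantiles,
#' and computes for each repeat class the fold enrichment of repeat overlap
#' in each quantile relative to the genome background (the overlap fraction
#' over all sampled positions).
#'
#' @param track A score [signal_track()].
#' @param repeats Named list of interval tibbles, one per repeat class.
#' @param n_quantiles Number of score quantiles (default 200, i.e. 0.5% of
#'   positions each).
#' @param n_sample Number of sampled positions.
#' @param excluded Optional excluded-region intervals.
#' @param seed Integer seed.
#' @return Tibble with `quantile` (1 = lowest scores), `repeat_class`,
#'   `fold`; `NA` folds for classes with zero background overlap.
#' @export
repeat_quantile_enrichment <- function(track, repeats, n_quantiles = 200L,
                                       n_sample = 100000L, excluded = NULL,
                                       seed = 1L) {
  if (n_sample < n_quantiles) stop("n_sample must be at least n_quantiles")
  loci <- sample_neutral_background(track$assembly, n_sample, 1,
                                    excluded = excluded, seed = seed)
  sc <- track_value_at(track, loci$chrom, loci$pos)
  # equal-mass quantile groups by score rank (ties broken by order)
  q <- ceiling(rank(sc, ties.method = "first") * n_quantiles / length(sc))
  purrr::map_dfr(names(repeats), function(cl) {
    hit <- point_in_intervals(repeats[[cl]], loci$chrom, loci$pos)
    bg <- mean(hit)
    folds <- vapply(seq_len(n_quantiles), function(k) {
      i <- q == k
      if (bg == 0 || !any(i)) return(NA_real_)
      mean(hit[i]) / bg
    }, numeric(1))
    tibble::tibble(quantile = seq_len(n_quantiles), repeat_class = cl,
                   fold = folds)
  })
}

#' Pairwise Pearson correlations between tracks
#'
#' Correlations are computed over a single shared random sample of genomic
#' positions (excluding `excluded` regions), so all pairs see the same loci.
#'
#' @param tracks Named list of [signal_track()]s on one assembly.
#' @param n_sample Number of sampled positions (default 500000).
#' @param excluded Optional excluded-region intervals.
#' @param seed Integer seed.
#' @return Symmetric correlation matrix with unit diagonal; `NA` for pairs
#'   involving a constant track.
#' @export
track_correlation_matrix <- function(tracks, n_sample = 500000L,
                                     excluded = NULL, seed = 1L) {
  if (length(tracks) < 2) stop("need at least 2 tracks")
  if (is.null(names(tracks))) {
    names(tracks) <- vapply(tracks, `[[`, "", "name")
  }
  loci <- sample_neutral_background(tracks[[1]]$assembly, n_sample, 1,
                                    excluded = excluded, seed = seed)
  X <- vapply(tracks, function(t) track_value_at(t, loci$chrom, loci$pos),
              numeric(n_sample))
  r <- suppressWarnings(stats::cor(X))
  diag(r) <- 1
  r
}

#' Score distribution by chromatin state
#'
#' Samples loci, looks up each locus's chromatin state and score, and
#' summarizes the score distribution per state.
#'
#' @param track A score [signal_track()].
#' @param ann A [state_annotation()] on the same assembly.
#' @param n_sample Number of sampled loci.
#' @param excluded Optional excluded-region intervals.
#' @param seed Integer seed.
#' @return Tibble with `state`, `state_name`, `n`, `mean`, `q25`, `median`,
#'   `q75`; states with no sampled loci are absent.
#' @export
score_distribution_by_state <- function(track, ann, n_sample = 100000L,
                                        excluded = NULL, seed = 1L) {
  loci <- sample_neutral_background(track$assembly, n_sample, 1,
                                    excluded = excluded, seed = seed)
  df <- tibble::tibble(
    state = state_at(ann, loci$chrom, loci$pos),
    score = track_value_at(track, loci$chrom, loci$pos)
  )
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$state),
    n = dplyr::n(), mean = mean(.data$score),
    q25 = stats::quantile(.data$score, 0.25),
    median = stats::median(.data$score),
    q75 = stats::quantile(.data$score, 0.75), .groups = "drop"
  )
  out$state_name <- ann$state_names[out$state]
  dplyr::relocate(out, "state", "state_name")
}

#' Select loci with variable scores across cell types
#'
#' Finds bins whose score range across cell types (max minus min) is at
#' least `min_difference` and samples `n_loci` of them uniformly; returns
#' their bin-center positions.
#'
#' @param tracks Named list of [signal_track()]s, one per cell type.
#' @param min_difference Minimum cross-cell-type score range (default 0.25).
#' @param n_loci Number of loci to sample (all qualifying loci if fewer).
#' @param seed Integer seed.
#' @return Tibble with `chrom`, `pos` (bin centers); empty, with a warning,
#'   when no locus qualifies.
#' @export
select_variable_loci <- function(tracks, min_difference = 0.25,
                                 n_loci = 20000L, seed = 1L) {
  if (length(tracks) < 2) stop("need at least 2 cell types")
  assembly <- tracks[[1]]$assembly
  bs <- bin_size_of(assembly)
  qual <- purrr::map_dfr(names(tracks[[1]]$values), function(ch) {
    vs <- vapply(tracks, function(t) t$values[[ch]],
                 numeric(length(tracks[[1]]$values[[ch]])))
    rng <- apply(vs, 1, max) - apply(vs, 1, min)
    bins <- which(rng >= min_difference)
    tibble::tibble(chrom = ch, pos = bin_center(bins - 1L, bs))
  })
  if (nrow(qual) == 0) {
    warning("no loci with cross-cell-type difference >= ", min_difference)
    return(qual)
  }
  withr::with_seed(seed, {
    qual[sample.int(nrow(qual), min(n_loci, nrow(qual))), ]
  })
}
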