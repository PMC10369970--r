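#' Score the genome with a fitted expert
#'
#' Applies an expert to every bin of the assembly: features are extracted at
#' each bin's center nucleotide (the 13th base of a 25 bp bin) and scored
#' with the ensemble, using the PCA and standardization transforms stored at
#' training time. Work is chunked per chromosome to bound memory.
#'
#' @param ensemble A [fit_expert()] ensemble with transforms.
#' @param tracks,peaks,ann Inputs for the cell type being scored (same
#'   assembly as at training time is not required, but the same marks are).
#' @param chunk_bins Number of bins scored per block (default 50000).
#' @return A [signal_track()] of scores in `[0, 1]`, named after the
#'   ensemble's dataset id.
#' @export
score_genome <- function(ensemble, tracks, peaks, ann, chunk_bins = 50000L) {
  assembly <- tracks[[1]]$assembly
  bs <- bin_size_of(assembly)
  nb <- assembly_nbins(assembly)
  vals <- lapply(assembly$chrom, function(ch) {
    n <- nb[[ch]]
    out <- numeric(n)
    for (lo in seq(1L, n, by = chunk_bins)) {
      hi <- min(lo + chunk_bins - 1L, n)
      bins <- lo:hi
      regions <- tibble::tibble(chrom = ch,
                                pos = bin_center(bins - 1L, bs))
      out[bins] <- predict_expert_at(ensemble, regions, tracks, peaks, ann)
    }
    out
  })
  names(vals) <- assembly$chrom
  signal_track(vals, assembly, name = ensemble$dataset_id,
               cell_type = tracks[[1]]$cell_type)
}

#' Combine expert score tracks into ChromScore
#'
#' ChromScore is the per-bin arithmetic mean of the expert score tracks: a
#' single 0-1 regulatory-activity potential per 25 bp bin.
#'
#' @param expert_tracks List of score [signal_track()]s on the same assembly.
#' @return A [signal_track()] named `"chromscore"`.
#' @export
chromscore <- function(expert_tracks) {
  if (length(expert_tracks) == 0) stop("need at least one expert track")
  ref <- expert_tracks[[1]]
  vals <- lapply(names(ref$values), function(ch) {
    vs <- lapply(expert_tracks, function(t) {
      v <- t$values[[ch]]
      if (is.null(v) || length(v) != length(ref$values[[ch]])) {
        stop("expert tracks have mismatched lengths on ", ch)
      }
      v
    })
    Reduce(`+`, vs) / length(vs)
  })
  names(vals) <- names(ref$values)
  signal_track(vals, ref$assembly, name = "chromscore",
               cell_type = ref$cell_type)
}

#' Build a cross-expert quantile-normalization map
#'
#' Samples `n_sample` genomic positions (uniformly, excluding `excluded`
#' regions), reads every expert's score there, and builds the reference
#' distribution as the per-rank median across the experts' sorted samples.
#' Each expert then gets `n_bins` equal-mass quantile bins mapped to the
#' reference median score of the bin, so normalized scores from different
#' experts are directly comparable.
#'
#' @param expert_tracks Named list of expert score [signal_track()]s.
#' @param n_sample Number of sampled positions (must be `>= n_bins`).
#' @param n_bins Number of quantile bins (default 1000).
#' @param excluded Optional interval tibble of regions never sampled.
#' @param seed Integer seed.
#' @return A `normalization_map`: per-expert lower bin boundaries and the
#'   shared per-bin reference values (both monotone non-decreasing).
#' @export
build_normalization_map <- function(expert_tracks, n_sample = 100000L,
                                    n_bins = 1000L, excluded = NULL,
                                    seed = 1L) {
  if (n_sample < n_bins) stop("n_sample must be at least n_bins")
  if (is.null(names(expert_tracks))) {
    names(expert_tracks) <- vapply(expert_tracks, `[[`, "", "name")
  }
  assembly <- expert_tracks[[1]]$assembly
  loci <- sample_neutral_background(assembly, n_sample, 1,
                                    excluded = excluded, seed = seed)
  S <- vapply(expert_tracks, function(t)
    sort(track_value_at(t, loci$chrom, loci$pos)), numeric(n_sample))
  reference <- apply(S, 1, stats::median)  # per-rank median, non-decreasing
  # equal-mass bins over ranks; bin b covers ranks rank_lo[b] .. rank_hi[b]
  rank_lo <- floor((seq_len(n_bins) - 1) * n_sample / n_bins) + 1
  rank_hi <- c(rank_lo[-1] - 1, n_sample)
  ref_value <- vapply(seq_len(n_bins), function(b)
    stats::median(reference[rank_lo[b]:rank_hi[b]]), numeric(1))
  boundaries <- apply(S, 2, function(v) v[rank_lo])
  structure(list(boundaries = boundaries, ref_value = ref_value,
                 n_bins = n_bins, n_sample = n_sample,
                 experts = colnames(boundaries)),
            class = "normalization_map")
}

#' Quantile-normalize an expert score track
#'
#' Each value is assigned to its expert's quantile bin (values outside the
#' sampled range clamp to the edge bins) and replaced by the bin's reference
#' value; within-expert score ordering is preserved up to bin resolution.
#'
#' @param track An expert score [signal_track()].
#' @param map A [build_normalization_map()] for a set of experts including
#'   this one (matched by track name).
#' @return A normalized [signal_track()].
#' @export
normalize_track <- function(track, map) {
  if (!track$name %in% map$experts) {
    stop("no normalization mapping for expert '", track$name, "'")
  }
  b <- map$boundaries[, track$name]
  vals <- lapply(track$values, function(v) {
    bin <- findInterval(v, b)          # 0 below the sampled minimum
    bin <- pmin(pmax(bin, 1L), map$n_bins)
    map$ref_value[bin]
  })
  signal_track(vals, track$assembly, name = paste0(track$name, "_norm"),
               cell_type = track$cell_type)
}

#' Write a normalization map as TSV
#'
#' @param map A [build_normalization_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_normalization_map <- function(map, path) {
  df <- purrr::map_dfr(map$experts, function(e)
    tibble::tibble(expert = e, bin = seq_len(map$n_bins) - 1L,
                   lower_bound = map$boundaries[, e],
                   reference_value = map$ref_value))
  readr::write_tsv(df, path)
  invisible(path)
}
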