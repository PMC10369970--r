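#' Labeled regions
#'
#' All labelers return a tibble of labeled regions: one row per reference
#' nucleotide with a binary activating/neutral label. The reference
#' nucleotide is the single base considered most representative of the
#' region's regulatory activity (assay-specific: signal maximum, construct
#' center, peak center or element midpoint).
#'
#' @param chrom,pos,label,dataset_id,cell_type Column vectors.
#' @return Tibble with columns `chrom`, `pos` (0-based reference
#'   nucleotide), `label` (`"activating"`/`"neutral"`), `dataset_id`,
#'   `cell_type`.
#' @keywords internal
labeled_regions <- function(chrom, pos, label, dataset_id = NA_character_,
                            cell_type = NA_character_) {
  stopifnot(all(label %in% c("activating", "neutral")))
  tibble::tibble(chrom = as.character(chrom), pos = as.integer(pos),
                 label = label, dataset_id = dataset_id,
                 cell_type = cell_type)
}

interval_center <- function(start, end) {
  as.integer(start + floor((end - start) / 2))
}

#' Signed extremum score of a tiled MPRA region
#'
#' For a region with activity scores at 5 bp intervals, finds the interval
#' with the maximum absolute score (first occurrence on ties) and returns
#' the signed score there together with the 0-based interval index.
#'
#' @param scores Numeric vector of per-5 bp activity scores.
#' @return List with `s_absmax` (signed score at the absolute maximum) and
#'   `argmax_bin` (0-based index of that 5 bp interval).
#' @export
sharpr_region_score <- function(scores) {
  if (length(scores) == 0) stop("empty score vector")
  i <- which.max(abs(scores))  # first occurrence on ties
  list(s_absmax = scores[[i]], argmax_bin = i - 1L)
}

#' Label tiled MPRA regions by their signed extremum score
#'
#' Regions whose signed extremum exceeds `activating_threshold` are
#' activating; regions inside the closed `neutral_band` are neutral; regions
#' below the band (likely repressive) are dropped. The reference nucleotide
#' is the center base of the extremal 5 bp interval.
#'
#' @param regions Tibble with `chrom`, `start`, `end` and a `scores`
#'   list-column of per-5 bp score vectors (the `sharpr` record schema).
#' @param activating_threshold Scores strictly above this are activating
#'   (default 1).
#' @param neutral_band Closed interval of neutral scores (default `c(-1, 1)`).
#' @param dataset_id,cell_type Metadata stamped onto the output.
#' @return Labeled-region tibble (see [labeled_regions]); regions below the
#'   neutral band are absent from it.
#' @export
label_sharpr <- function(regions, activating_threshold = 1,
                         neutral_band = c(-1, 1),
                         dataset_id = NA_character_,
                         cell_type = NA_character_) {
  sc <- lapply(regions$scores, sharpr_region_score)
  s <- vapply(sc, `[[`, numeric(1), "s_absmax")
  amax <- vapply(sc, `[[`, integer(1), "argmax_bin")
  label <- ifelse(s > activating_threshold, "activating",
                  ifelse(s >= neutral_band[1] & s <= neutral_band[2],
                         "neutral", NA_character_))
  keep <- !is.na(label)
  # center base of the 5 bp interval at the extremum
  pos <- regions$start[keep] + 5L * amax[keep] + 2L
  labeled_regions(regions$chrom[keep], pos, label[keep],
                  dataset_id, cell_type)
}

#' Label constructs by activity p-value
#'
#' Constructs with `p_value` strictly below `alpha` are activating, the rest
#' neutral. The reference nucleotide is the construct center.
#'
#' @param records Tibble with `chrom`, `start`, `end`, `p_value` (the
#'   `pvalue` record schema).
#' @param alpha Significance threshold (default 0.05).
#' @inheritParams label_sharpr
#' @return Labeled-region tibble.
#' @export
label_by_pvalue <- function(records, alpha = 0.05,
                            dataset_id = NA_character_,
                            cell_type = NA_character_) {
  if (any(records$p_value < 0 | records$p_value > 1)) {
    stop("p_value outside [0, 1]")
  }
  labeled_regions(records$chrom,
                  interval_center(records$start, records$end),
                  ifelse(records$p_value < alpha, "activating", "neutral"),
                  dataset_id, cell_type)
}

#' Label the top fraction of peaks by score as activating
#'
#' Peaks are ranked by score (descending); the top `ceiling(fraction * N)`
#' become activating. Peaks tied with the score at the rank boundary are all
#' included. The reference nucleotide is the peak center.
#'
#' @param peaks Tibble with `chrom`, `start`, `end`, `score`.
#' @param fraction Fraction of peaks to label activating, in (0, 1].
#' @inheritParams label_sharpr
#' @return Labeled-region tibble of activating regions only (neutral
#'   background is drawn separately with [sample_neutral_background()]).
#' @export
label_top_fraction <- function(peaks, fraction = 0.10,
                               dataset_id = NA_character_,
                               cell_type = NA_character_) {
  stopifnot(fraction > 0, fraction <= 1)
  n <- nrow(peaks)
  if (n == 0) return(labeled_regions(character(), integer(), character()))
  k <- ceiling(fraction * n)
  cutoff <- sort(peaks$score, decreasing = TRUE)[k]
  sel <- peaks$score >= cutoff
  labeled_regions(peaks$chrom[sel],
                  interval_center(peaks$start[sel], peaks$end[sel]),
                  "activating", dataset_id, cell_type)
}

#' Label peaks above a fixed readout threshold as activating
#'
#' Peaks whose score is strictly above `threshold` (e.g. corrected
#' fold-enrichment above 4, or RNA/DNA ratio above 1) become activating; the
#' reference nucleotide is the peak center.
#'
#' @param peaks Tibble with `chrom`, `start`, `end` and the score column
#'   named by `score_col`.
#' @param threshold Strict lower cutoff for the activating call.
#' @param score_col Name of the score column (default `"score"`).
#' @inheritParams label_sharpr
#' @return Labeled-region tibble of activating regions only.
#' @export
label_threshold_peaks <- function(peaks, threshold, score_col = "score",
                                  dataset_id = NA_character_,
                                  cell_type = NA_character_) {
  stopifnot(is.finite(threshold))
  sel <- peaks[[score_col]] > threshold
  labeled_regions(peaks$chrom[sel],
                  interval_center(peaks$start[sel], peaks$end[sel]),
                  "activating", dataset_id, cell_type)
}

#' Sample neutral background positions from the genome
#'
#' Draws positions uniformly from the assembly (or from `within` when the
#' assay only tiled part of the genome), rejecting any that fall in
#' `excluded`. Used to pair each activating region with `per_activating`
#' neutral regions (default 3).
#'
#' @param assembly A [genome_assembly()].
#' @param n_activating Number of activating regions being matched.
#' @param per_activating Neutral regions per activating region (default 3).
#' @param excluded Interval tibble of regions never to sample from (e.g. an
#'   assembly's excluded-regions list). May be empty.
#' @param within Optional interval tibble restricting the sampling universe
#'   (e.g. HiDRA tiled regions); positions are drawn uniformly from its
#'   bases, then filtered against `excluded`.
#' @param seed Integer seed; sampling is reproducible given the seed.
#' @param max_tries Bounded number of rejection rounds before giving up.
#' @inheritParams label_sharpr
#' @return Labeled-region tibble of exactly `n_activating * per_activating`
#'   neutral positions.
#' @export
sample_neutral_background <- function(assembly, n_activating,
                                      per_activating = 3,
                                      excluded = NULL, within = NULL,
                                      seed = 1L, max_tries = 100L,
                                      dataset_id = NA_character_,
                                      cell_type = NA_character_) {
  stopifnot(per_activating >= 1)
  n_needed <- as.integer(n_activating * per_activating)
  if (n_needed == 0) return(labeled_regions(character(), integer(), character()))
  if (is.null(excluded)) {
    excluded <- tibble::tibble(chrom = character(), start = integer(),
                               end = integer())
  }
  draw <- function(n) {
    if (is.null(within)) {
      # uniform over genome bases: chromosome ~ length, then position
      probs <- assembly$length / sum(assembly$length)
      ch_i <- sample.int(nrow(assembly), n, replace = TRUE, prob = probs)
      tibble::tibble(
        chrom = assembly$chrom[ch_i],
        pos = as.integer(floor(stats::runif(n) * assembly$length[ch_i]))
      )
    } else {
      w <- as.numeric(within$end - within$start)
      iv_i <- sample.int(nrow(within), n, replace = TRUE, prob = w / sum(w))
      tibble::tibble(
        chrom = within$chrom[iv_i],
        pos = as.integer(within$start[iv_i] +
                           floor(stats::runif(n) * w[iv_i]))
      )
    }
  }
  withr::with_seed(seed, {
    out <- tibble::tibble(chrom = character(), pos = integer())
    for (try in seq_len(max_tries)) {
      cand <- draw(n_needed - nrow(out))
      keep <- !point_in_intervals(excluded, cand$chrom, cand$pos)
      out <- dplyr::bind_rows(out, cand[keep, ])
      if (nrow(out) >= n_needed) break
    }
    if (nrow(out) < n_needed) {
      stop("could not sample enough neutral positions; excluded regions ",
           "cover (nearly) the whole sampling universe")
    }
    labeled_regions(out$chrom, out$pos, "neutral", dataset_id, cell_type)
  })
}

#' Label CRISPRi elements from element-gene records
#'
#' An element is activating if at least one of its surviving element-gene
#' records is significant (`adjusted_p < alpha`). Record-level filters
#' follow the assay family:
#'
#' * `mode = "gasperini"`: keep records with `beta < 0` (expression decrease
#'   on perturbation) and `outlier_flag == FALSE`; elements whose records are
#'   all filtered are labeled neutral.
#' * `mode = "fulco"`: keep records with `power_ok == TRUE` (at least 80%
#'   power to detect a 25% effect) and a negative expression effect
#'   (`beta < 0`); elements left with zero surviving records are dropped.
#'
#' The reference nucleotide is the element midpoint.
#'
#' @param records Tibble in the `crispr` record schema.
#' @param alpha Significance threshold (default 0.05, strict).
#' @param mode `"gasperini"` or `"fulco"`.
#' @inheritParams label_sharpr
#' @return Labeled-region tibble, one row per element.
#' @export
label_crispr_elements <- function(records, alpha = 0.05,
                                  mode = c("gasperini", "fulco"),
                                  dataset_id = NA_character_,
                                  cell_type = NA_character_) {
  mode <- match.arg(mode)
  rec <- dplyr::mutate(records,
                       element = paste(.data$chrom, .data$start, .data$end,
                                       sep = ":"))
  if (mode == "gasperini") {
    surviving <- dplyr::filter(rec, .data$beta < 0, !.data$outlier_flag)
  } else {
    surviving <- dplyr::filter(rec, .data$power_ok, .data$beta < 0)
  }
  elements <- dplyr::distinct(rec, .data$element, .data$chrom, .data$start,
                              .data$end)
  hits <- dplyr::summarise(
    dplyr::group_by(surviving, .data$element),
    activating = any(.data$adjusted_p < alpha), .groups = "drop"
  )
  out <- dplyr::left_join(elements, hits, by = "element")
  if (mode == "fulco") {
    out <- dplyr::filter(out, !is.na(.data$activating))  # no surviving record -> dropped
  } else {
    out$activating[is.na(out$activating)] <- FALSE
  }
  labeled_regions(out$chrom, interval_center(out$start, out$end),
                  ifelse(out$activating, "activating", "neutral"),
                  dataset_id, cell_type)
}

#' Write labeled regions as BED4 plus a manifest
#'
#' @param labels Labeled-region tibble.
#' @param path Output BED path (`chrom`, `pos`, `pos + 1`, `label`).
#' @param manifest_path Optional TSV manifest path with per-dataset label
#'   counts.
#' @param header Optional comment lines.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path, manifest_path = NULL, header = NULL) {
  write_intervals(
    tibble::tibble(chrom = labels$chrom, start = labels$pos,
                   end = labels$pos + 1L, name = labels$label),
    path, header = header
  )
  if (!is.null(manifest_path)) {
    man <- dplyr::count(labels, .data$dataset_id, .data$cell_type,
                        .data$label)
    readr::write_tsv(man, manifest_path)
  }
  invisible(path)
}
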