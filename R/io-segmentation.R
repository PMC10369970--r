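#' Chromatin-state annotations at bin resolution
#'
#' A `state_annotation` assigns every genomic bin exactly one state index in
#' `1..K`. It houses both input chromatin-state segmentations (e.g. a
#' 25-state model) and the ChromScoreHMM output segmentations.
#'
#' @param states Named list of integer vectors (one per chromosome, values in
#'   `1..K`), names/lengths matching the assembly.
#' @param assembly A [genome_assembly()].
#' @param K Number of states.
#' @param state_names Optional character vector of length `K`; defaults to
#'   `"1_S1"`, ..., `"K_SK"` style `"<index>_<label>"` names.
#' @return A `state_annotation` object.
#' @export
state_annotation <- function(states, assembly, K,
                             state_names = paste0(seq_len(K), "_S", seq_len(K))) {
  K <- as.integer(K)
  if (length(state_names) != K) stop("state_names must have length K")
  nb <- assembly_nbins(assembly)
  check_chrom(assembly, names(states))
  sts <- lapply(assembly$chrom, function(ch) {
    v <- states[[ch]]
    if (is.null(v)) stop("no state vector for chromosome ", ch)
    v <- as.integer(v)
    if (length(v) != nb[[ch]]) {
      stop(sprintf("state vector for %s has %d bins, assembly expects %d",
                   ch, length(v), nb[[ch]]))
    }
    if (anyNA(v) || any(v < 1L | v > K)) {
      stop("state indices must lie in 1..", K, " (", ch, ")")
    }
    v
  })
  names(sts) <- assembly$chrom
  structure(list(states = sts, assembly = assembly, K = K,
                 state_names = state_names),
            class = "state_annotation")
}

#' @export
print.state_annotation <- function(x, ...) {
  cat(sprintf("<state_annotation> K=%d states over %s bins @ %d bp\n",
              x$K, format(sum(lengths(x$states)), big.mark = ","),
              bin_size_of(x$assembly)))
  invisible(x)
}

#' @export
as_tibble.state_annotation <- function(x, ...) {
  bs <- bin_size_of(x$assembly)
  lens <- assembly_lengths(x$assembly)
  purrr::map_dfr(names(x$states), function(ch) {
    v <- x$states[[ch]]
    start <- (seq_along(v) - 1L) * bs
    tibble::tibble(chrom = ch, start = start,
                   end = pmin(start + bs, lens[[ch]]),
                   state = v, state_name = x$state_names[v])
  })
}

state_at <- function(ann, chrom, pos) {
  bs <- bin_size_of(ann$assembly)
  out <- integer(length(pos))
  for (ch in unique(chrom)) {
    v <- ann$states[[ch]]
    if (is.null(v)) stop("unknown chromosome: ", ch)
    i <- which(chrom == ch)
    b <- floor(pos[i] / bs) + 1
    if (any(b < 1 | b > length(v))) stop("position outside chromosome ", ch)
    out[i] <- v[b]
  }
  out
}

#' Read a dense segmentation BED into a state annotation
#'
#' Expects a 4-column BED whose intervals tile each chromosome without gaps
#' or overlaps and align to the bin grid; the state index is parsed from the
#' leading integer of the name column (ChromHMM-style names such as
#' `"1_TssA"`).
#'
#' @param path Path to the segmentation BED.
#' @param assembly A [genome_assembly()].
#' @param K Number of states.
#' @return A [state_annotation()].
#' @export
read_segmentation <- function(path, assembly, K) {
  K <- as.integer(K)
  iv <- read_intervals(path)
  if (!"name" %in% names(iv)) stop("segmentation BED must have 4 columns")
  check_chrom(assembly, iv$chrom)
  bs <- bin_size_of(assembly)
  nb <- assembly_nbins(assembly)
  lens <- assembly_lengths(assembly)
  idx <- suppressWarnings(as.integer(sub("_.*$", "", iv$name)))
  if (anyNA(idx)) stop("state name without leading integer: ",
                       iv$name[which(is.na(idx))[1]])
  if (any(idx < 1L | idx > K)) {
    stop("state index outside 1..", K, ": ", iv$name[which(idx < 1L | idx > K)[1]])
  }
  # recover full state names where the file provides labels
  state_names <- paste0(seq_len(K), "_S", seq_len(K))
  seen <- !duplicated(idx)
  state_names[idx[seen]] <- iv$name[seen]
  sts <- lapply(assembly$chrom, function(ch) integer(nb[[ch]]))
  names(sts) <- assembly$chrom
  for (ch in unique(iv$chrom)) {
    sub <- iv[iv$chrom == ch, ]
    ord <- order(sub$start)
    s <- sub$start[ord]; e <- sub$end[ord]
    if (s[1] != 0) stop("segmentation does not start at 0 on ", ch)
    if (any(s[-1] != e[-length(e)])) {
      stop("gap or overlap in segmentation tiling on ", ch)
    }
    if (utils::tail(e, 1) != lens[[ch]]) {
      stop("segmentation does not cover chromosome ", ch)
    }
    if (any(s %% bs != 0) || any(e %% bs != 0 & e != lens[[ch]])) {
      stop("segmentation interval not aligned to the ", bs, " bp grid on ", ch)
    }
    st <- idx[iv$chrom == ch][ord]
    sts[[ch]] <- rep.int(st, ceiling(e / bs) - s / bs)
  }
  if (any(vapply(sts, function(v) any(v == 0L), TRUE))) {
    stop("segmentation missing for some chromosome in the assembly")
  }
  state_annotation(sts, assembly, K = K, state_names = state_names)
}

#' Write a state annotation as a dense 4-column BED
#'
#' Adjacent bins in the same state are merged into single rows;
#' `read_segmentation(write_segmentation(x))` reproduces `x` exactly.
#'
#' @param ann A [state_annotation()].
#' @param path Output path.
#' @param header Optional comment lines.
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(ann, path, header = NULL) {
  bs <- bin_size_of(ann$assembly)
  lens <- assembly_lengths(ann$assembly)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  for (ch in names(ann$states)) {
    v <- ann$states[[ch]]
    r <- rle(v)
    end_bin <- cumsum(r$lengths)
    start <- (end_bin - r$lengths) * bs
    end <- pmin(end_bin * bs, lens[[ch]])
    writeLines(sprintf("%s\t%d\t%d\t%s", ch, as.integer(start),
                       as.integer(end), ann$state_names[r$values]), con)
  }
  invisible(path)
}
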