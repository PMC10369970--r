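#' Binned signal tracks
#'
#' A `signal_track` holds one numeric value per genomic bin for every
#' chromosome of an assembly: chromatin-mark signal, an expert's predicted
#' activating probability, or the combined ChromScore. Values are stored as
#' one vector per chromosome, in assembly order.
#'
#' @param values Named list of numeric vectors, one per chromosome; names and
#'   lengths must match the assembly's chromosomes and bin counts. Missing
#'   chromosomes are zero-filled.
#' @param assembly A [genome_assembly()].
#' @param name Track name (mark name or expert id, e.g. `"H3K27ac"` or
#'   `"chromscore"`).
#' @param cell_type Cell type the track belongs to.
#' @return A `signal_track` object.
#' @export
signal_track <- function(values, assembly, name = "signal", cell_type = NA_character_) {
  nb <- assembly_nbins(assembly)
  if (is.null(names(values)) && length(values) == nrow(assembly)) {
    names(values) <- assembly$chrom
  }
  check_chrom(assembly, names(values))
  vals <- lapply(assembly$chrom, function(ch) {
    v <- values[[ch]]
    if (is.null(v)) return(numeric(nb[[ch]]))
    v <- as.numeric(v)
    if (length(v) != nb[[ch]]) {
      stop(sprintf("track vector for %s has %d bins, assembly expects %d",
                   ch, length(v), nb[[ch]]))
    }
    if (any(!is.finite(v))) stop("track values must be finite (", ch, ")")
    v
  })
  names(vals) <- assembly$chrom
  structure(
    list(values = vals, assembly = assembly, name = name, cell_type = cell_type),
    class = "signal_track"
  )
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("<signal_track> '%s' (%s): %d chromosome(s), %s bins @ %d bp\n",
              x$name, x$cell_type, length(x$values),
              format(sum(lengths(x$values)), big.mark = ","),
              bin_size_of(x$assembly)))
  invisible(x)
}

#' @export
as_tibble.signal_track <- function(x, ...) {
  bs <- bin_size_of(x$assembly)
  lens <- assembly_lengths(x$assembly)
  purrr::map_dfr(names(x$values), function(ch) {
    v <- x$values[[ch]]
    start <- (seq_along(v) - 1L) * bs
    tibble::tibble(chrom = ch, start = start,
                   end = pmin(start + bs, lens[[ch]]), value = v)
  })
}

track_values <- function(track) unlist(track$values, use.names = FALSE)

# value at the bin containing each (chrom, pos); positions off-chromosome read 0
track_value_at <- function(track, chrom, pos) {
  bs <- bin_size_of(track$assembly)
  out <- numeric(length(pos))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    v <- track$values[[ch]]
    if (is.null(v)) stop("unknown chromosome: ", ch)
    b <- floor(pos[i] / bs) + 1
    ok <- pos[i] >= 0 & b <= length(v)
    out[i[ok]] <- v[b[ok]]
  }
  out
}

skip_comment_lines <- function(lines) {
  lines[!grepl("^\\s*(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))]
}

#' Read a binned signal track (bedGraph or fixedStep wiggle)
#'
#' Accepts bedGraph whose intervals align to the assembly's bin grid, or
#' fixedStep wiggle with `step` and `span` equal to the bin size. Bins not
#' covered by the file read as 0. Wiggle 1-based starts are converted to the
#' 0-based grid on read; all coordinates are handled 0-based half-open
#' internally.
#'
#' @param path Path to a bedGraph or wiggle file. Comment/track lines are
#'   skipped.
#' @param assembly A [genome_assembly()].
#' @inheritParams signal_track
#' @return A [signal_track()].
#' @export
read_signal_track <- function(path, assembly, name = "signal",
                              cell_type = NA_character_) {
  bs <- bin_size_of(assembly)
  nb <- assembly_nbins(assembly)
  vals <- lapply(nb, function(n) numeric(n))

  lines <- readr::read_lines(path)
  lines <- skip_comment_lines(lines)
  if (length(lines) == 0) {
    return(signal_track(vals, assembly, name = name, cell_type = cell_type))
  }

  is_fixed <- grepl("^fixedStep", lines)
  if (any(is_fixed)) {
    # wiggle fixedStep: 1-based starts; step == span == bin size
    header_idx <- which(is_fixed)
    block_end <- c(header_idx[-1] - 1L, length(lines))
    for (k in seq_along(header_idx)) {
      h <- lines[header_idx[k]]
      get_field <- function(f) {
        m <- regmatches(h, regexec(paste0(f, "=([^ \t]+)"), h))[[1]]
        if (length(m) < 2) NA_character_ else m[2]
      }
      ch <- get_field("chrom")
      start1 <- as.numeric(get_field("start"))
      step <- as.numeric(get_field("step"))
      span <- as.numeric(get_field("span"))
      if (is.na(span)) span <- step
      if (is.na(ch) || is.na(start1) || is.na(step)) {
        stop("malformed fixedStep header: ", h)
      }
      if (step != bs || span != bs) {
        stop(sprintf("fixedStep step/span must equal bin size %d: %s", bs, h))
      }
      check_chrom(assembly, ch)
      start0 <- start1 - 1
      if (start0 %% bs != 0) {
        stop("fixedStep start not aligned to the bin grid: ", h)
      }
      body <- lines[seq(header_idx[k] + 1L, block_end[k])]
      body <- body[!grepl("^fixedStep", body)]
      v <- as.numeric(body)
      if (anyNA(v)) stop("non-numeric wiggle value in block starting: ", h)
      b0 <- start0 / bs
      idx <- b0 + seq_along(v)           # 1-based bin indices
      if (any(idx > nb[[ch]])) stop("wiggle block runs past end of ", ch)
      vals[[ch]][idx] <- v
    }
  } else {
    parts <- strsplit(lines, "[ \t]+")
    nf <- lengths(parts)
    if (any(nf < 4)) {
      stop("bedGraph line with fewer than 4 fields: line ",
           which(nf < 4)[1])
    }
    ch <- vapply(parts, `[[`, "", 1)
    start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2)))
    end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3)))
    val <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 4)))
    bad <- which(is.na(start) | is.na(end) | is.na(val))
    if (length(bad) > 0) stop("malformed bedGraph line: ", lines[bad[1]])
    check_chrom(assembly, ch)
    lens <- assembly_lengths(assembly)
    chrom_end_ok <- end == lens[ch]   # last interval may end at chrom length
    mis <- which(start %% bs != 0 | (end %% bs != 0 & !chrom_end_ok))
    if (length(mis) > 0) {
      stop("bedGraph interval not aligned to the ", bs,
           " bp grid: ", lines[mis[1]])
    }
    if (any(start >= end)) {
      stop("bedGraph interval with start >= end: ", lines[which(start >= end)[1]])
    }
    for (i in seq_along(ch)) {
      b <- (start[i] / bs + 1):ceiling(end[i] / bs)
      if (max(b) > nb[[ch[i]]]) stop("interval runs past end of ", ch[i])
      vals[[ch[i]]][b] <- val[i]
    }
  }
  signal_track(vals, assembly, name = name, cell_type = cell_type)
}

#' Write a signal or score track as bedGraph
#'
#' Runs of adjacent bins with equal values are merged into single bedGraph
#' intervals, so `read_signal_track(write_score_track(x))` reproduces `x`
#' exactly.
#'
#' @param track A [signal_track()].
#' @param path Output path.
#' @param header Optional character vector of comment lines (written with a
#'   leading `#`).
#' @return `path`, invisibly.
#' @export
write_score_track <- function(track, path, header = NULL) {
  bs <- bin_size_of(track$assembly)
  lens <- assembly_lengths(track$assembly)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    if (length(v) == 0) next
    r <- rle(v)
    end_bin <- cumsum(r$lengths)
    start_bin <- end_bin - r$lengths
    start <- start_bin * bs
    end <- pmin(end_bin * bs, lens[[ch]])
    # %.17g round-trips doubles exactly through the text format
    writeLines(sprintf("%s\t%d\t%d\t%.17g", ch, as.integer(start),
                       as.integer(end), r$values), con)
  }
  invisible(path)
}
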