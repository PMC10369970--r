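#' Read genomic intervals from a BED3+ file
#'
#' Intervals are 0-based half-open, preserved verbatim in file order.
#' Columns beyond the first three are captured as `name`, `score` and
#' `strand` when present (BED4/BED5/BED6). Extra columns are kept with their
#' file positions as `X7`, `X8`, ... (used e.g. for repeat class/family).
#'
#' @param path Path to a BED file. `#`/track/browser lines are skipped.
#' @return A tibble with columns `chrom`, `start`, `end` and any optional
#'   BED columns present.
#' @export
read_intervals <- function(path) {
  lines <- skip_comment_lines(readr::read_lines(path))
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer()))
  }
  parts <- strsplit(lines, "\t")
  nf <- min(lengths(parts))
  if (nf < 3) stop("BED line with fewer than 3 fields: line ",
                   which(lengths(parts) < 3)[1])
  col <- function(i) vapply(parts, function(p) if (length(p) >= i) p[[i]] else NA_character_, "")
  start_raw <- col(2); end_raw <- col(3)
  start <- suppressWarnings(as.numeric(start_raw))
  end <- suppressWarnings(as.numeric(end_raw))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) | end != floor(end))
  if (length(bad) > 0) stop("non-integer BED coordinates: ", lines[bad[1]])
  if (any(start >= end)) {
    stop("BED interval with start >= end: ", lines[which(start >= end)[1]])
  }
  out <- tibble::tibble(chrom = col(1), start = as.integer(start),
                        end = as.integer(end))
  maxf <- max(lengths(parts))
  if (maxf >= 4) out$name <- col(4)
  if (maxf >= 5) out$score <- suppressWarnings(as.numeric(col(5)))
  if (maxf >= 6) out$strand <- col(6)
  if (maxf >= 7) {
    for (i in 7:maxf) out[[paste0("X", i)]] <- col(i)
  }
  out
}

#' Write intervals as BED
#'
#' @param intervals Tibble with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @param path Output path.
#' @param header Optional comment lines (written with a leading `#`).
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path, header = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  cols <- c("chrom", "start", "end",
            intersect(c("name", "score", "strand"), names(intervals)))
  # BED columns are positional: stop at the first absent optional column
  keep <- c("chrom", "start", "end")
  for (opt in c("name", "score", "strand")) {
    if (opt %in% cols) keep <- c(keep, opt) else break
  }
  df <- as.data.frame(intervals[keep])
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# logical: does any interval contain each (chrom, pos)? half-open convention
point_in_intervals <- function(intervals, chrom, pos) {
  out <- logical(length(pos))
  if (nrow(intervals) == 0) return(out)
  by_chrom <- split(intervals[c("start", "end")], intervals$chrom)
  for (ch in intersect(names(by_chrom), unique(chrom))) {
    iv <- by_chrom[[ch]]
    ord <- order(iv$start)
    s <- iv$start[ord]; e <- iv$end[ord]
    i <- which(chrom == ch)
    # a point is covered iff some interval with start <= pos has end > pos;
    # with starts sorted, the running max of ends over the first j intervals
    # decides it exactly
    j <- findInterval(pos[i], s)
    ce <- cummax(e)
    out[i] <- j >= 1 & pos[i] < ce[pmax(j, 1)]
  }
  out
}
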