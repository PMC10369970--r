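#' Genome assemblies and the 25 bp bin grid
#'
#' A genome assembly is the ordered set of chromosome names and lengths that
#' every track, segmentation and interval set in the package is bound to.
#' All genome-wide quantities live on a fixed grid of `bin_size` bp bins
#' (25 bp by default); chromosome `i` has `ceiling(length / bin_size)` bins.
#'
#' @param chrom Character vector of chromosome names (unique).
#' @param length Positive integer vector of chromosome lengths in bp.
#' @param bin_size Width of the genomic bins in bp. Default 25.
#'
#' @return A tibble with columns `chrom`, `length` and `n_bins`, of class
#'   `genome_assembly`, carrying `bin_size` as an attribute.
#' @examples
#' asm <- genome_assembly(c("chr1", "chr2"), c(1000, 500))
#' asm
#' @export
genome_assembly <- function(chrom, length, bin_size = 25L) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) stop("duplicate chromosome names in assembly")
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("chromosome lengths must be positive")
  }
  if (length(chrom) != base::length(length)) {
    stop("`chrom` and `length` must have the same length")
  }
  out <- tibble::tibble(
    chrom = chrom,
    length = length,
    n_bins = ceiling(length / bin_size)
  )
  attr(out, "bin_size") <- as.integer(bin_size)
  class(out) <- c("genome_assembly", class(out))
  out
}

#' Read a chrom-sizes file into a genome assembly
#'
#' @param path Two-column whitespace-separated file: chromosome name, length.
#' @param bin_size Bin width in bp.
#' @return A [genome_assembly()].
#' @export
read_chrom_sizes <- function(path, bin_size = 25L) {
  df <- utils::read.table(path, header = FALSE, sep = "",
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"),
                          comment.char = "#")
  genome_assembly(df$chrom, df$length, bin_size = bin_size)
}

bin_size_of <- function(assembly) attr(assembly, "bin_size") %||% 25L

assembly_lengths <- function(assembly) {
  stats::setNames(assembly$length, assembly$chrom)
}

assembly_nbins <- function(assembly) {
  stats::setNames(assembly$n_bins, assembly$chrom)
}

check_chrom <- function(assembly, chrom) {
  bad <- setdiff(unique(chrom), assembly$chrom)
  if (length(bad) > 0) {
    stop("unknown chromosome(s): ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Bin arithmetic on the genomic grid
#'
#' `bin_of()` maps a 0-based genomic position to its 0-based bin index
#' (`floor(pos / bin_size)`); `bin_center()` maps a 0-based bin index to the
#' 0-based position of its center nucleotide, the 13th base of a 25 bp bin
#' (`bin * bin_size + floor(bin_size / 2)`).
#'
#' @param pos,bin Non-negative integer vectors (0-based).
#' @param bin_size Bin width in bp.
#' @return Integer vector.
#' @examples
#' bin_of(0:30)      # 0 0 ... 1 1
#' bin_center(0)     # 12 -- the 13th nucleotide of bin 0
#' @export
bin_of <- function(pos, bin_size = 25L) as.integer(floor(pos / bin_size))

#' @rdname bin_of
#' @export
bin_center <- function(bin, bin_size = 25L) {
  as.integer(bin) * as.integer(bin_size) + as.integer(floor(bin_size / 2))
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf("<genome_assembly> %d chromosome(s), %s bp, bin size %d bp\n",
              nrow(x), format(sum(x$length), big.mark = ","), bin_size_of(x)))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
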