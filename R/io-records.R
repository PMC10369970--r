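#' Schemas for functional-characterization record tables
#'
#' Each supported assay family ships its readouts in a TSV with a fixed set
#' of required columns; [read_record_table()] validates and types them.
#'
#' * `sharpr` — densely tiled MPRA regions with per-5 bp activity scores:
#'   `chrom`, `start`, `end`, `scores` (comma-separated reals).
#' * `pvalue` — episomal constructs with activity p-values against scrambled
#'   controls: `chrom`, `start`, `end`, `p_value`.
#' * `starr_peaks` — STARR-seq peak calls with a fold-change style score:
#'   `chrom`, `start`, `end`, `score`.
#' * `hidra` — HiDRA driver elements with RNA/DNA ratios: `chrom`, `start`,
#'   `end`, `rna_dna_ratio`.
#' * `crispr` — CRISPRi element-gene records: `chrom`, `start`, `end`,
#'   `gene`, `adjusted_p`, `beta`, `power_ok`, `outlier_flag`.
#'
#' @format NULL
#' @name record_schemas
#' @keywords internal
NULL

.record_schemas <- list(
  sharpr      = c(chrom = "c", start = "i", end = "i", scores = "c"),
  pvalue      = c(chrom = "c", start = "i", end = "i", p_value = "d"),
  starr_peaks = c(chrom = "c", start = "i", end = "i", score = "d"),
  hidra       = c(chrom = "c", start = "i", end = "i", rna_dna_ratio = "d"),
  crispr      = c(chrom = "c", start = "i", end = "i", gene = "c",
                  adjusted_p = "d", beta = "d", power_ok = "l",
                  outlier_flag = "l")
)

#' Read and validate an assay record table
#'
#' Reads a headered TSV and validates it against one of the named dataset
#' schemas (see [record_schemas]). Required columns must be present and
#' contain no missing values; extra columns are kept as-is and `NA` is
#' allowed in them.
#'
#' @param path Path to a TSV with a header row. Lines starting with `#` are
#'   skipped.
#' @param schema One of `"sharpr"`, `"pvalue"`, `"starr_peaks"`, `"hidra"`,
#'   `"crispr"`.
#' @return A tibble typed per schema, with the schema name attached as the
#'   `"schema"` attribute. For `sharpr`, the `scores` column is parsed into a
#'   list-column of numeric vectors.
#' @export
read_record_table <- function(path, schema) {
  schema <- match.arg(schema, names(.record_schemas))
  spec <- .record_schemas[[schema]]
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  missing_cols <- setdiff(names(spec), names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("schema '%s': missing required column(s): %s",
                 schema, paste(missing_cols, collapse = ", ")))
  }
  for (col in names(spec)) {
    df[[col]] <- switch(spec[[col]],
      c = as.character(df[[col]]),
      i = { v <- as.numeric(df[[col]])
            if (any(v != floor(v), na.rm = TRUE))
              stop("column '", col, "' must be integer")
            as.integer(v) },
      d = as.numeric(df[[col]]),
      l = as.logical(df[[col]])
    )
    if (anyNA(df[[col]])) {
      stop(sprintf("schema '%s': missing values in required column '%s'",
                   schema, col))
    }
  }
  if (schema == "sharpr") {
    df$scores <- lapply(strsplit(df$scores, ","), as.numeric)
    if (any(vapply(df$scores, anyNA, TRUE))) {
      stop("schema 'sharpr': non-numeric entry in 'scores'")
    }
  }
  if (schema == "pvalue" &&
      any(df$p_value < 0 | df$p_value > 1)) {
    stop("p_value outside [0, 1]")
  }
  if (schema == "crispr" &&
      any(df$adjusted_p < 0 | df$adjusted_p > 1)) {
    stop("adjusted_p outside [0, 1]")
  }
  attr(df, "schema") <- schema
  df
}

#' Write an assay record table as TSV
#'
#' @param records Tibble in one of the record schemas. A `scores`
#'   list-column is serialized comma-separated.
#' @param path Output path.
#' @param header Optional comment lines.
#' @return `path`, invisibly.
#' @export
write_record_table <- function(records, path, header = NULL) {
  df <- records
  if ("scores" %in% names(df) && is.list(df$scores)) {
    df$scores <- vapply(df$scores, function(v)
      paste(sprintf("%.17g", v), collapse = ","), "")
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(as.data.frame(df), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
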