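# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed error so callers can distinguish parse/validation failures.
msi_stop <- function(msg, class = "msiburden_error", call. = FALSE) {
  cond <- structure(
    class = c(class, "msiburden_error", "error", "condition"),
    list(message = msg, call = NULL)
  )
  stop(cond)
}

msi_parse_error <- function(msg) msi_stop(msg, class = "msiburden_parse_error")

stopifnot_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min) {
    msi_stop(sprintf("'%s' must be a single finite number >= %s", name, min))
  }
  invisible(x)
}

# Stage-prefixed logging to stderr; keeps stdout clean for data.
msi_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

# "chrom:start:motif" identifier used to track a locus across the cohort.
#' Build locus keys
#'
#' A locus key is the string `"chrom:start:motif"` (0-based start,
#' canonical motif). It identifies one microsatellite locus across all
#' samples of a cohort and is stable across runs on the same reference
#' and scan parameters.
#'
#' @param chrom chromosome names.
#' @param start 0-based start positions.
#' @param motif canonical repeat motifs.
#' @return character vector of keys.
#' @export
locus_key <- function(chrom, start, motif) {
  paste(chrom, start, motif, sep = ":")
}

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, required = character(), what = "table") {
  if (!file.exists(path)) {
    msi_stop(sprintf("missing input file for %s: '%s'", what, path))
  }
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    msi_parse_error(sprintf(
      "%s '%s' lacks required column(s): %s",
      what, path, paste(missing, collapse = ", ")
    ))
  }
  df
}
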