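# Tumor mutational burden: coding consensus mutations per megabase of
# sequenced coding genome (default denominator 57 Mb, the canine exome
# target size), excluding mitochondrial and unplaced contigs.

#' Count coding consensus mutations
#'
#' Counts variants whose effect class is coding (by default both
#' nonsynonymous and synonymous; restrict with `coding_effects`) and
#' whose chromosome is neither explicitly excluded nor matches an
#' unplaced/unaligned name pattern. Effect labels outside
#' \{nonsynonymous, synonymous, noncoding, other\} are an error listing
#' the offending rows.
#'
#' @param variants consensus, PON-filtered variant data.frame with
#'   columns `chrom` and `effect`.
#' @param excluded_contigs contig names to drop (default mitochondrial).
#' @param exclude_patterns regular expressions for unplaced/unaligned
#'   contig names.
#' @param coding_effects effect classes counted as coding.
#' @return integer count.
#' @export
count_coding_mutations <- function(variants,
                                   excluded_contigs = c("chrM", "MT"),
                                   exclude_patterns = c("^chrUn", "_random$", "_alt$", "_hap"),
                                   coding_effects = c("nonsynonymous", "synonymous")) {
  if (nrow(variants) == 0L) return(0L)
  bad <- !(variants$effect %in% .effect_levels)
  if (any(bad)) {
    msi_parse_error(sprintf(
      "unknown effect label(s) %s at row(s) %s (expected one of: %s)",
      paste(unique(variants$effect[bad]), collapse = ", "),
      paste(head(which(bad), 10L), collapse = ", "),
      paste(.effect_levels, collapse = ", ")
    ))
  }
  excl <- variants$chrom %in% excluded_contigs
  for (p in exclude_patterns) excl <- excl | grepl(p, variants$chrom)
  sum(variants$effect %in% coding_effects & !excl)
}

#' Compute tumor mutational burden
#'
#' TMB = coding mutations / megabases of coding sequence.
#'
#' @param n_coding non-negative coding mutation count.
#' @param denominator_mb sequenced coding size in Mb (default 57, the
#'   canine exome target estimate).
#' @param sample optional sample id carried through.
#' @return one-row data.frame: `sample`, `n_coding`, `denominator_mb`,
#'   `tmb`.
#' @examples
#' compute_tmb(114, 57)  # 2 mutations per Mb
#' @export
compute_tmb <- function(n_coding, denominator_mb = 57, sample = NA_character_) {
  stopifnot_scalar_number(n_coding, "n_coding", min = 0)
  if (!is.numeric(denominator_mb) || length(denominator_mb) != 1L ||
      !is.finite(denominator_mb) || denominator_mb <= 0) {
    msi_stop("'denominator_mb' must be a single number > 0")
  }
  data.frame(sample = sample, n_coding = n_coding,
             denominator_mb = denominator_mb,
             tmb = n_coding / denominator_mb,
             stringsAsFactors = FALSE)
}

#' Per-sample TMB from a multi-sample variant table
#'
#' @param variants variant data.frame with a `sample` column (plus
#'   `chrom`, `effect`).
#' @param samples optional character vector of sample ids guaranteeing a
#'   (possibly zero) row per sample.
#' @param ... passed to [count_coding_mutations()].
#' @inheritParams compute_tmb
#' @return data.frame with one row per sample.
#' @export
tmb_by_sample <- function(variants, samples = NULL, denominator_mb = 57, ...) {
  ids <- samples %||% sort(unique(variants$sample))
  rows <- lapply(ids, function(s) {
    n <- count_coding_mutations(variants[variants$sample == s, , drop = FALSE], ...)
    compute_tmb(n, denominator_mb = denominator_mb, sample = s)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
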