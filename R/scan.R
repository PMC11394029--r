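# Microsatellite discovery: maximal perfect tandem repeats (1-5 bp motifs)
# on the reference strand of a nucleotide sequence.

#' Default minimum copy numbers per motif length
#'
#' Minimum number of full tandem copies a run must reach, per motif
#' (unit) length, to be reported as a microsatellite locus. Defaults are
#' 10 copies for homopolymers, 5 for dinucleotide motifs and 4 for
#' 3-5 bp motifs, mirroring common microsatellite-scan settings.
#'
#' @return named integer vector with names `"1"`..`"5"`.
#' @export
default_min_repeats <- function() {
  c(`1` = 10L, `2` = 5L, `3` = 4L, `4` = 4L, `5` = 4L)
}

.check_min_repeats <- function(min_repeats) {
  if (!is.numeric(min_repeats) || length(min_repeats) != 5L ||
      !identical(names(min_repeats), as.character(1:5))) {
    msi_stop("'min_repeats' must be a numeric vector named '1'..'5'")
  }
  if (any(min_repeats < 2)) {
    msi_stop("'min_repeats' entries must be >= 2 (a single copy is not a repeat)")
  }
  as.integer(min_repeats)
}

# Smallest p such that the motif is (substring of) p-periodic repetitions;
# p must divide nchar(motif) for the motif to collapse to a smaller unit.
.primitive_period <- function(motif) {
  n <- nchar(motif)
  for (p in seq_len(n)) {
    if (n %% p == 0L && strrep(substr(motif, 1L, p), n %/% p) == motif) {
      return(p)
    }
  }
  n
}

#' Canonical form of a repeat motif
#'
#' Reduces a motif to its primitive unit (e.g. `"ATAT"` to `"AT"`) and
#' returns the lexicographically smallest rotation, so that locus
#' identity does not depend on the reading frame of the repeat.
#' Idempotent.
#'
#' @param motif character vector of motifs over `{A,C,G,T}`, 1-5 bp.
#' @return character vector of canonical motifs.
#' @examples
#' canonical_motif(c("TA", "A", "CAC", "ATAT"))
#' @export
canonical_motif <- function(motif) {
  if (length(motif) == 0L) return(character())
  vapply(motif, function(m) {
    if (is.na(m) || nchar(m) < 1L) msi_stop("empty motif")
    if (nchar(m) > 5L) msi_stop(sprintf("motif '%s' longer than 5 bp", m))
    if (grepl("[^ACGT]", m)) msi_stop(sprintf("motif '%s' has non-ACGT characters", m))
    p <- .primitive_period(m)
    m <- substr(m, 1L, p)
    if (p == 1L) return(m)
    rot <- vapply(seq_len(p), function(i) {
      paste0(substr(m, i, p), substr(m, 1L, i - 1L))
    }, character(1))
    min(rot)
  }, character(1), USE.NAMES = FALSE)
}

#' Scan one sequence for microsatellite loci
#'
#' Finds all maximal perfect tandem runs of 1-5 bp motifs reaching the
#' per-unit-length minimum copy number. Runs never cross `N` bases.
#' A run whose motif is a repetition of a smaller unit is reported once,
#' at the primitive unit. Overlapping candidate runs are resolved
#' deterministically: longer total run wins, ties go to the smaller unit
#' length, then to the smaller start. Output coordinates are 0-based
#' half-open (BED convention); `end - start == unit_len * ref_repeats`
#' always holds (partial trailing copies are not counted).
#'
#' @param seq a single nucleotide string over `{A,C,G,T,N}` (case
#'   insensitive). Any other character raises a parse error.
#' @param chrom sequence name to report.
#' @param min_repeats named vector of minimum copy numbers per unit
#'   length, see [default_min_repeats()].
#' @return data.frame with columns `chrom`, `start`, `end`, `motif`
#'   (canonical), `unit_len`, `ref_repeats`, `locus_key`, sorted by
#'   `start`, non-overlapping.
#' @examples
#' scan_sequence(strrep("A", 12), "chr1")
#' @export
scan_sequence <- function(seq, chrom, min_repeats = default_min_repeats()) {
  min_repeats <- .check_min_repeats(min_repeats)
  if (!is.character(seq) || length(seq) != 1L) {
    msi_stop("'seq' must be a single string")
  }
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) {
    bad <- unique(strsplit(gsub("[ACGTN]", "", seq), "")[[1]])
    msi_parse_error(sprintf(
      "sequence '%s' contains non-nucleotide characters: %s",
      chrom, paste(bad, collapse = ", ")
    ))
  }
  n <- nchar(seq)
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  valid <- s != "N"

  cand <- list()
  for (u in 1:5) {
    if (n <= u) next
    i <- seq_len(n - u)
    m <- (s[i] == s[i + u]) & valid[i] & valid[i + u]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values)
    for (h in hit) {
      span <- r$lengths[h] + u           # bases with period u from run start
      copies <- span %/% u
      if (copies < min_repeats[u]) next
      st <- starts[h]                    # 1-based run start
      unit <- substr(seq, st, st + u - 1L)
      if (.primitive_period(unit) != u) next  # reported at its primitive unit
      cand[[length(cand) + 1L]] <- list(
        start = st - 1L, u = u, copies = copies, unit = unit
      )
    }
  }
  if (length(cand) == 0L) return(.empty_sites(chrom))

  start <- vapply(cand, `[[`, integer(1), "start")
  u <- vapply(cand, `[[`, integer(1), "u")
  copies <- vapply(cand, `[[`, integer(1), "copies")
  unit <- vapply(cand, `[[`, character(1), "unit")
  len <- u * copies
  end <- start + len

  # Greedy overlap resolution: longest first, then smaller unit, then start.
  ord <- order(-len, u, start)
  keep <- logical(length(ord))
  acc_start <- integer(0)
  acc_end <- integer(0)
  for (k in ord) {
    if (!any(start[k] < acc_end & end[k] > acc_start)) {
      keep[k] <- TRUE
      acc_start <- c(acc_start, start[k])
      acc_end <- c(acc_end, end[k])
    }
  }
  start <- start[keep]; end <- end[keep]
  u <- u[keep]; copies <- copies[keep]; unit <- unit[keep]
  ord <- order(start)

  motif <- canonical_motif(unit[ord])
  out <- data.frame(
    chrom = chrom,
    start = start[ord],
    end = end[ord],
    motif = motif,
    unit_len = u[ord],
    ref_repeats = copies[ord],
    stringsAsFactors = FALSE
  )
  out$locus_key <- locus_key(out$chrom, out$start, out$motif)
  out
}

.empty_sites <- function(chrom = character(0)) {
  data.frame(
    chrom = character(0), start = integer(0), end = integer(0),
    motif = character(0), unit_len = integer(0), ref_repeats = integer(0),
    locus_key = character(0), stringsAsFactors = FALSE
  )
}

#' Scan a reference FASTA for microsatellite loci
#'
#' Applies [scan_sequence()] to every record of a FASTA file (or a
#' `Biostrings::DNAStringSet`), concatenating the per-chromosome site
#' lists.
#'
#' @param fasta path to a FASTA file, or a `DNAStringSet`.
#' @param min_repeats see [scan_sequence()].
#' @return site-list data.frame as in [scan_sequence()].
#' @export
scan_reference <- function(fasta, min_repeats = default_min_repeats()) {
  if (is.character(fasta)) {
    fasta <- Biostrings::readDNAStringSet(fasta)
  }
  seqs <- as.character(fasta)
  names(seqs) <- sub("\\s.*$", "", names(fasta))  # FASTA id up to first space
  parts <- lapply(names(seqs), function(nm) {
    scan_sequence(seqs[[nm]], nm, min_repeats = min_repeats)
  })
  do.call(rbind, c(parts, list(make.row.names = FALSE)))
}

.check_sites_sorted <- function(sites) {
  for (chr in unique(sites$chrom)) {
    x <- sites[sites$chrom == chr, , drop = FALSE]
    if (is.unsorted(x$start, strictly = TRUE) ||
        any(x$start[-1] < x$end[-nrow(x)])) {
      msi_stop(sprintf("site list is unsorted or overlapping on '%s'", chr))
    }
    if (any(x$end - x$start != nchar(x$motif) * x$ref_repeats)) {
      msi_stop(sprintf("site list violates end-start = unit_len*ref_repeats on '%s'", chr))
    }
  }
  invisible(sites)
}

#' Write a microsatellite site list
#'
#' Serializes loci as a 5-column BED-like TSV (`chrom`, `start`, `end`,
#' `motif`, `ref_repeats`; 0-based half-open) with a header row. Input
#' must be sorted and non-overlapping per chromosome. Round-trips
#' losslessly through [read_sites()].
#'
#' @param sites site-list data.frame from [scan_reference()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_sites <- function(sites, path) {
  .check_sites_sorted(sites)
  cols <- c("chrom", "start", "end", "motif", "ref_repeats")
  write_tsv(sites[, cols, drop = FALSE], path)
  invisible(path)
}

#' Read a microsatellite site list
#'
#' @param path TSV written by [write_sites()].
#' @return site-list data.frame with derived `unit_len` and `locus_key`.
#' @export
read_sites <- function(path) {
  df <- read_tsv(path, required = c("chrom", "start", "end", "motif", "ref_repeats"),
                 what = "site list")
  df$chrom <- as.character(df$chrom)
  df$motif <- as.character(df$motif)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$ref_repeats <- as.integer(df$ref_repeats)
  df$unit_len <- nchar(df$motif)
  df$locus_key <- locus_key(df$chrom, df$start, df$motif)
  df <- df[, c("chrom", "start", "end", "motif", "unit_len", "ref_repeats", "locus_key")]
  .check_sites_sorted(df)
  df
}
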