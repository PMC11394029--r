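# VCF 4.2 adapters. Reading goes through vcfR; only CHROM, POS, REF, ALT
# and one configurable INFO tag (the effect class) are consumed.
# Writing is a minimal plain-text VCF 4.2 serializer (site-level records,
# no genotypes), so outputs stay greppable and diffable.

#' Read a caller VCF into a variant table
#'
#' Parses CHROM, POS, REF, ALT and one INFO tag carrying the functional
#' effect class. Multi-allelic records are split into one row per ALT
#' allele before normalization.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param effect_tag INFO tag holding the effect class (default `"EFF"`);
#'   set to `NA` to skip effect extraction.
#' @param reference optional reference sequences for left-alignment, see
#'   [normalize_variant()].
#' @return normalized variant data.frame (`chrom`, `pos`, `ref`, `alt`,
#'   `effect`, `key`).
#' @export
read_caller_vcf <- function(path, effect_tag = "EFF", reference = NULL) {
  if (!file.exists(path)) msi_stop(sprintf("missing VCF: '%s'", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      effect = character(0), key = character(0),
                      stringsAsFactors = FALSE))
  }
  eff <- if (is.na(effect_tag)) rep(NA_character_, nrow(fix))
         else as.character(vcfR::extract.info(v, element = effect_tag))
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  effs <- strsplit(ifelse(is.na(eff), "", eff), ",", fixed = TRUE)
  rows <- lapply(seq_len(nrow(fix)), function(i) {
    a <- alts[[i]]
    e <- effs[[i]]
    if (length(e) != length(a)) e <- rep(if (length(e) >= 1L) e[1L] else NA_character_, length(a))
    e[!nzchar(e)] <- NA_character_
    data.frame(chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
               ref = fix$REF[i], alt = a, effect = e,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  normalize_variants(df, reference = reference)
}

#' Write a variant table as a minimal VCF 4.2 file
#'
#' Site-level records only; the effect class is stored in the INFO field
#' under `effect_tag`. Round-trips through [read_caller_vcf()].
#'
#' @param variants variant data.frame (`chrom`, `pos`, `ref`, `alt`,
#'   optional `effect`).
#' @param path output path.
#' @param effect_tag INFO tag name (default `"EFF"`).
#' @param contigs optional character vector of contig names for the
#'   header (defaults to the contigs present).
#' @return the path, invisibly.
#' @export
write_vcf <- function(variants, path, effect_tag = "EFF", contigs = NULL) {
  if (is.null(contigs)) contigs <- unique(variants$chrom)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=msiburden",
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Variant effect class\">",
            effect_tag),
    sprintf("##contig=<ID=%s>", contigs),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  if (nrow(variants) > 0L) {
    ord <- order(variants$chrom, variants$pos, variants$ref, variants$alt)
    variants <- variants[ord, , drop = FALSE]
    eff <- if ("effect" %in% names(variants)) variants$effect else NA_character_
    info <- ifelse(is.na(eff), ".", paste0(effect_tag, "=", eff))
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                    variants$chrom, as.integer(variants$pos),
                    variants$ref, variants$alt, info)
  } else {
    body <- character(0)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read / write flat variant tables
#'
#' TSV with columns `sample` (optional), `chrom`, `pos`, `ref`, `alt`,
#' `effect` plus any audit columns (`callers`, `n_callers`, `in_pon`).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_variant_table <- function(path) {
  df <- read_tsv(path, required = c("chrom", "pos", "ref", "alt"),
                 what = "variant table")
  df$pos <- as.integer(df$pos)
  df$key <- variant_key(df$chrom, df$pos, df$ref, df$alt)
  df
}

#' @rdname read_variant_table
#' @param variants data.frame to serialize.
#' @export
write_variant_table <- function(variants, path) {
  variants$key <- NULL
  write_tsv(variants, path)
}
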