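# Somatic-variant consensus: caller-independent variant identity
# (trimmed, left-aligned alleles), majority voting across three callers,
# and Panel-of-Normals blacklist filtering.

.effect_levels <- c("nonsynonymous", "synonymous", "noncoding", "other")

.drop_last <- function(x) substr(x, 1L, nchar(x) - 1L)
.last_char <- function(x) substr(x, nchar(x), nchar(x))

# vt-style normalization of a single (pos, ref, alt) pair. `refseq` is the
# full chromosome sequence (1-based substr indexing) or NULL; without a
# reference only prefix/suffix trimming is possible (no left-shifting).
.normalize_one <- function(pos, ref, alt, refseq = NULL) {
  if (is.na(ref) || is.na(alt) || nchar(ref) == 0L || nchar(alt) == 0L) {
    msi_parse_error("empty REF or ALT allele")
  }
  if (ref == alt) msi_stop("null variant: REF equals ALT", class = "msiburden_null_variant")
  repeat {
    rl <- nchar(ref); al <- nchar(alt)
    if (rl > 0L && al > 0L && .last_char(ref) == .last_char(alt)) {
      if (rl > 1L && al > 1L) {
        ref <- .drop_last(ref); alt <- .drop_last(alt)
      } else if (!is.null(refseq) && pos > 1L) {
        b <- substr(refseq, pos - 1L, pos - 1L)
        ref <- paste0(b, .drop_last(ref))
        alt <- paste0(b, .drop_last(alt))
        pos <- pos - 1L
      } else {
        break
      }
    } else {
      break
    }
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  if (ref == alt) msi_stop("null variant after trimming", class = "msiburden_null_variant")
  list(pos = pos, ref = ref, alt = alt)
}

#' Normalize a variant to its minimal left-aligned representation
#'
#' Trims the common suffix, then the common prefix of REF/ALT (always
#' retaining one anchor base for indels) and, when the reference
#' sequence is supplied, left-aligns indels to their leftmost equivalent
#' position. Idempotent; caller-independent variant identity for the
#' majority vote. Genotype and quality fields play no role.
#'
#' @param chrom chromosome name.
#' @param pos 1-based position (VCF convention).
#' @param ref,alt allele strings (multi-allelic records must be split
#'   beforehand).
#' @param reference optional named character vector (or `DNAStringSet`)
#'   of chromosome sequences enabling left-alignment.
#' @return list with fields `chrom`, `pos`, `ref`, `alt`, `key`.
#' @examples
#' normalize_variant("chr1", 100, "AT", "GT")
#' @export
normalize_variant <- function(chrom, pos, ref, alt, reference = NULL) {
  refseq <- .reference_seq(reference, chrom)
  v <- .normalize_one(as.integer(pos), toupper(ref), toupper(alt), refseq)
  list(chrom = chrom, pos = v$pos, ref = v$ref, alt = v$alt,
       key = variant_key(chrom, v$pos, v$ref, v$alt))
}

.reference_seq <- function(reference, chrom) {
  if (is.null(reference)) return(NULL)
  if (!is.character(reference)) reference <- as.character(reference)
  names(reference) <- sub("\\s.*$", "", names(reference))
  if (!chrom %in% names(reference)) return(NULL)
  reference[[chrom]]
}

#' Normalize a variant table
#'
#' Applies [normalize_variant()] row-wise to a data.frame with columns
#' `chrom`, `pos`, `ref`, `alt` (other columns pass through).
#'
#' @param variants variant data.frame.
#' @param reference see [normalize_variant()].
#' @return the data.frame with normalized `pos`, `ref`, `alt` and a
#'   `key` column.
#' @export
normalize_variants <- function(variants, reference = NULL) {
  if (nrow(variants) == 0L) {
    variants$key <- character(0)
    return(variants)
  }
  refs <- if (is.null(reference)) NULL else {
    r <- if (is.character(reference)) reference else as.character(reference)
    names(r) <- sub("\\s.*$", "", names(r))
    r
  }
  for (i in seq_len(nrow(variants))) {
    rs <- if (is.null(refs)) NULL else refs[[match(variants$chrom[i], names(refs))]]
    v <- .normalize_one(as.integer(variants$pos[i]),
                        toupper(variants$ref[i]), toupper(variants$alt[i]), rs)
    variants$pos[i] <- v$pos
    variants$ref[i] <- v$ref
    variants$alt[i] <- v$alt
  }
  variants$key <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  variants
}

#' Majority-vote consensus across three callers
#'
#' Keeps every variant supported by at least `min_callers` of the input
#' call-sets (default 2 of 3). Variant identity is the normalized
#' (chrom, pos, ref, alt) key; duplicate keys within one caller's list
#' are deduplicated with a warning. The output records the full caller
#' support and is sorted by (chrom, pos, ref, alt); permuting the input
#' call-sets or their rows does not change it.
#'
#' @param callsets named list of variant data.frames (one per caller;
#'   names default to `caller_A`, `caller_B`, `caller_C`), each with
#'   columns `chrom`, `pos`, `ref`, `alt` and optionally `effect`.
#' @param min_callers minimum supporting callers (default 2).
#' @return data.frame with `chrom`, `pos`, `ref`, `alt`, `effect`,
#'   `callers` (comma-joined, sorted), `n_callers`, `key`.
#' @export
consensus_vote <- function(callsets, min_callers = 2) {
  if (is.null(names(callsets)) || any(!nzchar(names(callsets)))) {
    names(callsets) <- paste0("caller_", LETTERS[seq_along(callsets)])
  }
  stopifnot_scalar_number(min_callers, "min_callers", min = 1)
  stacked <- do.call(rbind, c(lapply(names(callsets), function(nm) {
    df <- callsets[[nm]]
    if (nrow(df) == 0L) {
      return(data.frame(chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        effect = character(0), caller = character(0),
                        stringsAsFactors = FALSE))
    }
    if (!"effect" %in% names(df)) df$effect <- NA_character_
    df <- df[, c("chrom", "pos", "ref", "alt", "effect"), drop = FALSE]
    key <- variant_key(df$chrom, df$pos, df$ref, df$alt)
    if (anyDuplicated(key)) {
      warning(sprintf("caller '%s': %d duplicate variant record(s) dropped",
                      nm, sum(duplicated(key))), call. = FALSE)
      df <- df[!duplicated(key), , drop = FALSE]
    }
    df$caller <- nm
    df
  }), list(make.row.names = FALSE)))

  if (nrow(stacked) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      effect = character(0), callers = character(0),
                      n_callers = integer(0), key = character(0),
                      stringsAsFactors = FALSE))
  }
  stacked$key <- variant_key(stacked$chrom, stacked$pos, stacked$ref, stacked$alt)
  supp <- lapply(split(stacked$caller, stacked$key), function(x) sort(unique(x)))
  nsupp <- lengths(supp)
  kept_keys <- names(supp)[nsupp >= min_callers]
  # representative row per key (first caller alphabetically, for effect)
  stacked <- stacked[order(stacked$key, stacked$caller), , drop = FALSE]
  rep_rows <- stacked[!duplicated(stacked$key), , drop = FALSE]
  # prefer a non-missing effect from any supporting caller
  eff_by_key <- vapply(split(stacked$effect, stacked$key), function(e) {
    e <- e[!is.na(e)]
    if (length(e) == 0L) NA_character_ else e[1L]
  }, character(1))
  out <- rep_rows[rep_rows$key %in% kept_keys, , drop = FALSE]
  out$effect <- unname(eff_by_key[out$key])
  out$callers <- vapply(supp[out$key], paste, character(1), collapse = ",")
  out$n_callers <- unname(nsupp[out$key])
  out$caller <- NULL
  out <- out[order(out$chrom, out$pos, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Panel of Normals from a variant table
#'
#' The PON is the set of normalized variant keys observed in any normal
#' sample of the cohort/project; membership is exact-key.
#'
#' @param variants variant data.frame (`chrom`, `pos`, `ref`, `alt`) or
#'   a character vector of keys.
#' @return object of class `panel_of_normals` (character key set).
#' @export
panel_of_normals <- function(variants) {
  keys <- if (is.character(variants)) variants
          else variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  structure(sort(unique(keys)), class = "panel_of_normals")
}

#' Remove Panel-of-Normals artifacts from a call-set
#'
#' Drops every variant whose normalized key appears in the PON and keeps
#' the removed records, flagged `in_pon = TRUE`, as an audit trail.
#'
#' @param variants consensus variant data.frame with a `key` column (or
#'   `chrom`/`pos`/`ref`/`alt` to derive one).
#' @param pon [panel_of_normals()] object (or coercible input).
#' @return list with `variants` (retained, `in_pon = FALSE`) and
#'   `removed` (PON hits, `in_pon = TRUE`).
#' @export
apply_pon <- function(variants, pon) {
  if (!inherits(pon, "panel_of_normals")) pon <- panel_of_normals(pon)
  if (!"key" %in% names(variants)) {
    variants$key <- variant_key(variants$chrom, variants$pos,
                                variants$ref, variants$alt)
  }
  hit <- variants$key %in% pon
  variants$in_pon <- hit
  list(variants = variants[!hit, , drop = FALSE],
       removed = variants[hit, , drop = FALSE])
}
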