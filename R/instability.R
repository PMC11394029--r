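# Per-locus somatic instability test: chi-square homogeneity of the tumor
# vs. matched-normal repeat-length read histograms, with low-count bins
# pooled before testing.

#' Construct a repeat-length read histogram
#'
#' Read support per repeat copy-number at one locus, in one tissue of one
#' sample.
#'
#' @param locus_key locus identifier (see [locus_key()]).
#' @param sample sample identifier.
#' @param tissue `"tumor"` or `"normal"`.
#' @param counts named non-negative numeric vector; names are repeat
#'   copy-numbers, values are supporting read counts.
#' @return object of class `repeat_histogram`.
#' @export
repeat_histogram <- function(locus_key, sample, tissue, counts) {
  tissue <- match.arg(tissue, c("tumor", "normal"))
  if (is.null(names(counts)) || anyNA(suppressWarnings(as.numeric(names(counts))))) {
    msi_stop("'counts' must be named by integer repeat copy-numbers")
  }
  if (any(counts < 0) || any(as.numeric(names(counts)) < 0)) {
    msi_stop("read counts and repeat copy-numbers must be non-negative")
  }
  counts <- counts[counts > 0]
  structure(
    list(locus_key = locus_key, sample = sample, tissue = tissue,
         counts = counts, total_reads = sum(counts)),
    class = "repeat_histogram"
  )
}

#' @export
print.repeat_histogram <- function(x, ...) {
  cat(sprintf("<repeat_histogram> %s | %s | %s | %d reads\n",
              x$locus_key, x$sample, x$tissue, x$total_reads))
  print(x$counts)
  invisible(x)
}

# Core test on two count vectors aligned over the union of repeat lengths.
# Pools bins whose expected count falls below `min_expected` into the
# numerically nearest neighboring bin; if a single bin remains the
# distributions are indistinguishable at this coverage and p = 1.
.chisq_hist_core <- function(tumor_counts, normal_counts, min_expected = 5) {
  lens <- sort(unique(c(as.numeric(names(tumor_counts)),
                        as.numeric(names(normal_counts)))))
  t_obs <- setNames(numeric(length(lens)), lens)
  n_obs <- t_obs
  t_obs[names(tumor_counts)] <- as.numeric(tumor_counts)
  n_obs[names(normal_counts)] <- as.numeric(normal_counts)
  repval <- lens

  repeat {
    k <- length(t_obs)
    if (k <= 1L) return(list(statistic = 0, df = 0L, p_value = 1))
    rowsum <- c(sum(t_obs), sum(n_obs))
    colsum <- t_obs + n_obs
    total <- sum(rowsum)
    # min expected cell in a column = colsum * min(rowsum) / total
    col_min_exp <- colsum * min(rowsum) / total
    if (all(col_min_exp >= min_expected)) break
    j <- which.min(col_min_exp)
    # merge into the numerically nearest neighbor; tie -> larger total, then left
    nb <- c(if (j > 1L) j - 1L, if (j < k) j + 1L)
    d <- abs(repval[nb] - repval[j])
    nb <- nb[order(d, -colsum[nb], nb)][1L]
    t_obs[nb] <- t_obs[nb] + t_obs[j]
    n_obs[nb] <- n_obs[nb] + n_obs[j]
    # pooled bin keeps the count-weighted mean repeat value for distances
    w <- colsum[nb] + colsum[j]
    repval[nb] <- if (w > 0) (repval[nb] * colsum[nb] + repval[j] * colsum[j]) / w else repval[nb]
    t_obs <- t_obs[-j]; n_obs <- n_obs[-j]; repval <- repval[-j]
  }

  obs <- rbind(t_obs, n_obs)
  exp <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  stat <- sum((obs - exp)^2 / exp)
  df <- length(t_obs) - 1L
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Test one locus for somatic instability
#'
#' Two-sided chi-square homogeneity test of the tumor vs. matched-normal
#' repeat-length histograms over the union of observed repeat lengths.
#' Bins with expected count below 5 are pooled into their numerically
#' nearest neighbor; if pooling leaves a single bin the locus is
#' uninformative at this coverage and p = 1. If either tissue has fewer
#' than `min_cov` reads the locus is not assessable: the call is stable
#' with p reported as 1 and reason `"insufficient_coverage"`. A locus is
#' unstable iff p <= alpha (no directionality is inferred; swapping the
#' tissues leaves p unchanged).
#'
#' @param tumor,normal [repeat_histogram()] objects for the same locus
#'   and sample.
#' @param alpha per-locus significance level (default 0.05).
#' @param min_cov minimum reads per tissue (default 20).
#' @return one-row data.frame: `locus_key`, `sample`, `statistic`,
#'   `p_value`, `unstable`, `reason`.
#' @export
test_locus <- function(tumor, normal, alpha = 0.05, min_cov = 20) {
  if (!inherits(tumor, "repeat_histogram") || !inherits(normal, "repeat_histogram")) {
    msi_stop("'tumor' and 'normal' must be repeat_histogram objects")
  }
  if (tumor$locus_key != normal$locus_key) {
    msi_stop(sprintf("locus mismatch: '%s' vs '%s'", tumor$locus_key, normal$locus_key))
  }
  if (tumor$sample != normal$sample) {
    msi_stop(sprintf("sample mismatch: '%s' vs '%s'", tumor$sample, normal$sample))
  }
  if (tumor$tissue != "tumor" || normal$tissue != "normal") {
    msi_stop("'tumor' must have tissue 'tumor' and 'normal' tissue 'normal'")
  }
  if (tumor$total_reads < min_cov || normal$total_reads < min_cov) {
    return(data.frame(
      locus_key = tumor$locus_key, sample = tumor$sample,
      statistic = NA_real_, p_value = 1, unstable = FALSE,
      reason = "insufficient_coverage", stringsAsFactors = FALSE
    ))
  }
  res <- .chisq_hist_core(tumor$counts, normal$counts)
  data.frame(
    locus_key = tumor$locus_key, sample = tumor$sample,
    statistic = res$statistic, p_value = res$p_value,
    unstable = res$p_value <= alpha, reason = "ok",
    stringsAsFactors = FALSE
  )
}

#' Call all loci of one sample
#'
#' Applies [test_locus()] to every locus with both a tumor and a normal
#' histogram. Tumor loci without a matched normal entry are skipped with
#' a log message. Duplicate locus keys within one tissue are an error.
#'
#' @param tumor_hists,normal_hists lists of [repeat_histogram()] objects
#'   for one sample (tumor and normal tissue respectively).
#' @param sample sample identifier.
#' @param histotype histological tumor-type label.
#' @param alpha,min_cov see [test_locus()].
#' @return object of class `msi_profile`: list with `sample`,
#'   `histotype`, `raw_unstable` (character vector of unstable locus
#'   keys), `raw_event_count` and the per-locus `calls` data.frame.
#' @export
call_sample <- function(tumor_hists, normal_hists, sample, histotype,
                        alpha = 0.05, min_cov = 20) {
  tk <- vapply(tumor_hists, `[[`, character(1), "locus_key")
  nk <- vapply(normal_hists, `[[`, character(1), "locus_key")
  if (anyDuplicated(tk)) msi_stop("duplicate locus_key in tumor histograms")
  if (anyDuplicated(nk)) msi_stop("duplicate locus_key in normal histograms")
  names(tumor_hists) <- tk
  names(normal_hists) <- nk
  skipped <- setdiff(tk, nk)
  if (length(skipped) > 0L) {
    msi_log("call", "sample %s: skipping %d tumor locus/loci without matched normal",
            sample, length(skipped))
  }
  shared <- intersect(tk, nk)
  calls <- if (length(shared) == 0L) {
    data.frame(locus_key = character(0), sample = character(0),
               statistic = numeric(0), p_value = numeric(0),
               unstable = logical(0), reason = character(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, c(lapply(shared, function(k) {
      test_locus(tumor_hists[[k]], normal_hists[[k]], alpha = alpha, min_cov = min_cov)
    }), list(make.row.names = FALSE)))
  }
  msi_profile(sample, histotype, calls)
}

msi_profile <- function(sample, histotype, calls) {
  raw_unstable <- sort(calls$locus_key[calls$unstable])
  structure(
    list(sample = sample, histotype = histotype,
         raw_unstable = raw_unstable,
         raw_event_count = length(raw_unstable),
         calls = calls),
    class = "msi_profile"
  )
}

#' @export
print.msi_profile <- function(x, ...) {
  cat(sprintf("<msi_profile> %s (%s): %d unstable of %d tested loci\n",
              x$sample, x$histotype, x$raw_event_count, nrow(x$calls)))
  invisible(x)
}

#' Call instability across a cohort histogram table
#'
#' Vectorized cohort-level driver over a long-format histogram table
#' (columns `locus_key`, `sample`, `tissue`, `repeat_count`,
#' `read_count`). Each (sample, locus) pair with both tissues present is
#' tested with the pooled chi-square test; tumor-only loci are skipped.
#'
#' @param histograms histogram data.frame (see [read_histograms()]).
#' @param samples sample sheet data.frame with columns `sample`,
#'   `histotype`.
#' @param alpha,min_cov see [test_locus()].
#' @param fdr if `TRUE`, apply Benjamini-Hochberg correction across loci
#'   within each sample and call unstable on the adjusted p-values
#'   (off by default: the flat per-locus p <= alpha rule).
#' @return list with `calls` (data.frame over all tested sample/locus
#'   pairs) and `profiles` (named list of `msi_profile` objects, one per
#'   sample in the sample sheet).
#' @export
call_cohort <- function(histograms, samples, alpha = 0.05, min_cov = 20,
                        fdr = FALSE) {
  need <- c("locus_key", "sample", "tissue", "repeat_count", "read_count")
  missing <- setdiff(need, names(histograms))
  if (length(missing) > 0L) {
    msi_stop(sprintf("histogram table lacks column(s): %s",
                     paste(missing, collapse = ", ")))
  }
  if (!all(histograms$tissue %in% c("tumor", "normal"))) {
    msi_parse_error("histogram 'tissue' must be 'tumor' or 'normal'")
  }
  if (!all(c("sample", "histotype") %in% names(samples))) {
    msi_stop("sample sheet must have columns 'sample' and 'histotype'")
  }

  grp <- paste(histograms$sample, histograms$locus_key, sep = "\r")
  idx <- split(seq_len(nrow(histograms)), grp)
  rc <- as.character(histograms$repeat_count)
  reads <- histograms$read_count
  tissue <- histograms$tissue

  rows <- lapply(idx, function(ii) {
    it <- ii[tissue[ii] == "tumor"]
    im <- ii[tissue[ii] == "normal"]
    if (length(it) == 0L || length(im) == 0L) return(NULL)
    if (anyDuplicated(rc[it]) || anyDuplicated(rc[im])) {
      msi_stop("duplicate repeat_count rows within one tissue/locus/sample")
    }
    tc <- setNames(reads[it], rc[it])
    nc <- setNames(reads[im], rc[im])
    if (sum(tc) < min_cov || sum(nc) < min_cov) {
      return(list(stat = NA_real_, p = 1, reason = "insufficient_coverage"))
    }
    res <- .chisq_hist_core(tc, nc)
    list(stat = res$statistic, p = res$p_value, reason = "ok")
  })
  keep <- !vapply(rows, is.null, logical(1))
  rows <- rows[keep]
  key2 <- strsplit(names(rows), "\r", fixed = TRUE)
  calls <- data.frame(
    locus_key = vapply(key2, `[[`, character(1), 2L),
    sample = vapply(key2, `[[`, character(1), 1L),
    statistic = vapply(rows, `[[`, numeric(1), "stat"),
    p_value = vapply(rows, `[[`, numeric(1), "p"),
    reason = vapply(rows, `[[`, character(1), "reason"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (fdr) {
    calls$q_value <- NA_real_
    for (s in unique(calls$sample)) {
      i <- calls$sample == s & calls$reason == "ok"
      calls$q_value[i] <- p.adjust(calls$p_value[i], method = "BH")
    }
    calls$unstable <- !is.na(calls$q_value) & calls$q_value <= alpha
  } else {
    calls$unstable <- calls$reason == "ok" & calls$p_value <= alpha
  }
  calls <- calls[order(calls$sample, calls$locus_key), , drop = FALSE]
  rownames(calls) <- NULL

  profiles <- lapply(seq_len(nrow(samples)), function(i) {
    s <- samples$sample[i]
    msi_profile(s, samples$histotype[i], calls[calls$sample == s, , drop = FALSE])
  })
  names(profiles) <- samples$sample
  list(calls = calls, profiles = profiles)
}

#' Read / write histogram and call tables
#'
#' Histogram TSVs are long format with columns `locus_key`, `sample`,
#' `tissue`, `repeat_count`, `read_count`; call TSVs carry `locus_key`,
#' `sample`, `statistic`, `p_value`, `unstable`, `reason`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_histograms <- function(path) {
  read_tsv(path, required = c("locus_key", "sample", "tissue",
                              "repeat_count", "read_count"),
           what = "histogram table")
}

#' @rdname read_histograms
#' @param histograms,calls data.frames to serialize.
#' @export
write_histograms <- function(histograms, path) write_tsv(histograms, path)

#' @rdname read_histograms
#' @export
write_calls <- function(calls, path) write_tsv(calls, path)

#' @rdname read_histograms
#' @export
read_calls <- function(path) {
  df <- read_tsv(path, required = c("locus_key", "sample", "p_value", "unstable"),
                 what = "call table")
  df$unstable <- as.logical(df$unstable)
  df
}

#' Rebuild per-sample MSI profiles from a call table
#'
#' @param calls call data.frame (as from [call_cohort()]).
#' @param samples sample sheet with `sample` and `histotype`.
#' @return named list of `msi_profile` objects.
#' @export
profiles_from_calls <- function(calls, samples) {
  lapply(setNames(seq_len(nrow(samples)), samples$sample), function(i) {
    s <- samples$sample[i]
    msi_profile(s, samples$histotype[i], calls[calls$sample == s, , drop = FALSE])
  })
}
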