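# Cohort statistics: category-wise rank-sum comparisons, quartile
# summaries, the burden-TMB association, per-histotype tables and the
# assembled report.

#' Pairwise two-sample rank-sum tests
#'
#' Two-sided Mann-Whitney (unpaired Wilcoxon rank-sum) test for every
#' pair of categories. The exact null distribution is used when both
#' groups have at most 25 observations and there are no ties; otherwise
#' the normal approximation with tie and continuity correction (the
#' behavior of [stats::wilcox.test()]). A pair involving an empty
#' category is reported as not computable (`p_value = NA`), not an
#' error.
#'
#' @param values_by_category named list of numeric vectors.
#' @return data.frame with `group1`, `group2`, `n1`, `n2`, `p_value`.
#' @examples
#' wilcoxon_pairwise(list(a = c(1, 2, 3), b = c(10, 11, 12)))
#' @export
wilcoxon_pairwise <- function(values_by_category) {
  nms <- names(values_by_category)
  if (is.null(nms) || length(nms) < 2L) {
    msi_stop("'values_by_category' must be a named list of >= 2 categories")
  }
  pairs <- combn(nms, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    x <- values_by_category[[a]]; y <- values_by_category[[b]]
    p <- if (length(x) == 0L || length(y) == 0L) NA_real_ else {
      suppressWarnings(wilcox.test(x, y, alternative = "two.sided")$p.value)
    }
    data.frame(group1 = a, group2 = b, n1 = length(x), n2 = length(y),
               p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Quartile summary
#'
#' Median and quartiles by linear interpolation between order statistics
#' (quantile type 7, the default of mainstream statistical
#' environments).
#'
#' @param values non-empty numeric vector.
#' @return list with `n`, `median`, `q1`, `q3`.
#' @examples
#' quartile_summary(1:100)
#' @export
quartile_summary <- function(values) {
  if (length(values) == 0L || !all(is.finite(values))) {
    msi_stop("'values' must be a non-empty finite numeric vector")
  }
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  list(n = length(values), median = q[2L], q1 = q[1L], q3 = q[3L])
}

#' Burden-TMB association
#'
#' Pearson correlation (with the two-sided t-test p-value) and an
#' ordinary least-squares regression of TMB on burden. The report
#' exposes both r and R-squared. Zero variance in either variable makes
#' the association not computable.
#'
#' @param burden,tmb equal-length numeric vectors (>= 3 finite pairs),
#'   paired by sample.
#' @return list with `computable`, `n`, `pearson_r`, `p_value`, `slope`,
#'   `intercept`, `r_squared`.
#' @export
burden_tmb_association <- function(burden, tmb) {
  if (length(burden) != length(tmb)) msi_stop("'burden' and 'tmb' lengths differ")
  if (length(burden) < 3L) msi_stop("need >= 3 paired observations")
  if (!all(is.finite(burden)) || !all(is.finite(tmb))) {
    msi_stop("non-finite values in 'burden' or 'tmb'")
  }
  if (stats::sd(burden) == 0 || stats::sd(tmb) == 0) {
    return(list(computable = FALSE, n = length(burden),
                pearson_r = NA_real_, p_value = NA_real_,
                slope = NA_real_, intercept = NA_real_, r_squared = NA_real_))
  }
  ct <- cor.test(burden, tmb, method = "pearson")
  fit <- lm(tmb ~ burden)
  r <- unname(ct$estimate)
  list(computable = TRUE, n = length(burden),
       pearson_r = r, p_value = ct$p.value,
       slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r_squared = r^2)
}

#' Per-histotype summary table
#'
#' For each histotype: sample count, MSI prevalence (fraction of samples
#' with at least one raw instability event), median burden among
#' classified samples (those with >= 1 recurrent-panel locus), mean raw
#' event count, category tally, and (when TMB is supplied) the median
#' TMB.
#'
#' @param records classified burden data.frame ([classify_cohort()]).
#' @param tmb optional TMB data.frame (`sample`, `tmb`); sample ids must
#'   match `records` exactly, otherwise the offending samples are named
#'   in an error.
#' @return data.frame with one row per histotype.
#' @export
histotype_summary <- function(records, tmb = NULL) {
  if (!is.null(tmb)) {
    only_b <- setdiff(records$sample, tmb$sample)
    only_t <- setdiff(tmb$sample, records$sample)
    if (length(only_b) > 0L || length(only_t) > 0L) {
      msi_stop(sprintf(
        "sample id mismatch between burden and TMB tables: %s",
        paste(head(c(only_b, only_t), 10L), collapse = ", ")
      ))
    }
    records$tmb <- tmb$tmb[match(records$sample, tmb$sample)]
  }
  rows <- lapply(split(records, records$histotype), function(g) {
    classified <- g$n_recurrent_affected >= 1L
    data.frame(
      histotype = g$histotype[1L],
      n = nrow(g),
      n_msi = sum(g$raw_event_count >= 1L),
      msi_prevalence_pct = 100 * mean(g$raw_event_count >= 1L),
      median_burden_pct = if (any(classified)) 100 * median(g$burden[classified]) else NA_real_,
      mean_raw_events = mean(g$raw_event_count),
      n_msi_h = sum(g$category == "MSI-H"),
      n_msi_l = sum(g$category == "MSI-L"),
      n_mss = sum(g$category == "MSS"),
      n_excluded = sum(g$category == "EXCLUDED"),
      median_tmb = if (!is.null(tmb)) median(g$tmb) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(-out$n, out$histotype), , drop = FALSE]
}

#' Arithmetic summary of a published cohort composition
#'
#' Given a per-histotype sample-count table and the cohort-level counts
#' of MSI-positive and classified samples, recomputes the cohort size,
#' the rounded MSI prevalence percentage and the number of samples with
#' only patient-specific events (positive minus classified).
#'
#' @param counts data.frame with columns `histotype`, `n_samples`.
#' @param n_msi_positive samples with at least one instability event.
#' @param n_classified samples with at least one recurrent-panel event.
#' @return list with `n_total`, `msi_positive_pct` (rounded to integer
#'   percent), `n_patient_specific_only`.
#' @export
summarize_published_cohort <- function(counts, n_msi_positive, n_classified) {
  if (!all(c("histotype", "n_samples") %in% names(counts))) {
    msi_stop("'counts' needs columns 'histotype' and 'n_samples'")
  }
  stopifnot_scalar_number(n_msi_positive, "n_msi_positive", min = 0)
  stopifnot_scalar_number(n_classified, "n_classified", min = 0)
  n_total <- sum(counts$n_samples)
  if (n_msi_positive > n_total || n_classified > n_msi_positive) {
    msi_stop("counts must satisfy n_classified <= n_msi_positive <= total")
  }
  list(
    n_total = n_total,
    msi_positive_pct = round(100 * n_msi_positive / n_total),
    n_patient_specific_only = n_msi_positive - n_classified
  )
}

#' Assemble the cohort statistics report
#'
#' Per-category quartile summaries of somatic mutation counts and TMB,
#' the three pairwise rank-sum comparisons for each, the burden-TMB
#' association, and the per-histotype table. MSS/MSI-L/MSI-H samples
#' enter the comparisons; EXCLUDED samples are reported separately.
#'
#' @param records classified burden data.frame.
#' @param tmb TMB data.frame (`sample`, `n_coding`, `tmb`).
#' @param threshold classification threshold from [classify_cohort()].
#' @param alpha significance level recorded in the report (default 0.05).
#' @return list of class `cohort_stats_report` (JSON-serializable).
#' @export
cohort_stats_report <- function(records, tmb, threshold, alpha = 0.05) {
  m <- match(records$sample, tmb$sample)
  if (anyNA(m)) {
    msi_stop(sprintf("samples missing from TMB table: %s",
                     paste(head(records$sample[is.na(m)], 10L), collapse = ", ")))
  }
  records$tmb <- tmb$tmb[m]
  records$n_coding <- tmb$n_coding[m]

  cats <- c("MSI-H", "MSI-L", "MSS")
  in_comp <- records$category %in% cats
  muts_by_cat <- lapply(setNames(cats, cats),
                        function(k) records$n_coding[records$category == k])
  tmb_by_cat <- lapply(setNames(cats, cats),
                       function(k) records$tmb[records$category == k])

  summarize_cats <- function(by_cat) {
    lapply(by_cat, function(v) {
      if (length(v) == 0L) list(n = 0L, median = NA_real_, q1 = NA_real_, q3 = NA_real_)
      else quartile_summary(v)
    })
  }

  category_counts <- as.list(table(factor(records$category,
                                          levels = c(cats, "EXCLUDED"))))
  category_counts <- lapply(category_counts, as.integer)

  structure(list(
    alpha = alpha,
    quartile_convention = "type 7 (linear interpolation)",
    threshold = threshold,
    threshold_pct = 100 * threshold,
    n_samples = nrow(records),
    n_in_comparisons = sum(in_comp),
    category_counts = category_counts,
    mutation_count_summary = summarize_cats(muts_by_cat),
    tmb_summary = summarize_cats(tmb_by_cat),
    mutation_count_wilcoxon = wilcoxon_pairwise(muts_by_cat),
    tmb_wilcoxon = wilcoxon_pairwise(tmb_by_cat),
    burden_tmb = burden_tmb_association(records$burden[in_comp],
                                        records$tmb[in_comp]),
    histotypes = histotype_summary(records[, setdiff(names(records), c("tmb", "n_coding"))],
                                   tmb = tmb)
  ), class = "cohort_stats_report")
}

#' @export
print.cohort_stats_report <- function(x, ...) {
  cat("<cohort_stats_report>\n")
  cat(sprintf("  samples: %d (threshold %.3f%%, alpha %.2f)\n",
              x$n_samples, x$threshold_pct, x$alpha))
  cat(sprintf("  categories: MSI-H %d | MSI-L %d | MSS %d | EXCLUDED %d\n",
              x$category_counts[["MSI-H"]], x$category_counts[["MSI-L"]],
              x$category_counts[["MSS"]], x$category_counts[["EXCLUDED"]]))
  bt <- x$burden_tmb
  if (isTRUE(bt$computable)) {
    cat(sprintf("  burden~TMB: r = %.3f (R^2 = %.3f), p = %.3g, slope = %.3f\n",
                bt$pearson_r, bt$r_squared, bt$p_value, bt$slope))
  } else {
    cat("  burden~TMB: not computable\n")
  }
  invisible(x)
}

#' Write a statistics report as JSON
#'
#' @param report a `cohort_stats_report`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_stats_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", na = "null",
                       pretty = TRUE)
  invisible(path)
}
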