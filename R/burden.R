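# Recurrent-locus panel, per-sample MSI-burden score and the
# MSI-H / MSI-L / MSS / EXCLUDED classification against the cohort mean.

#' Build the recurrent-locus panel
#'
#' Keeps the loci called unstable in at least `min_samples` distinct
#' samples (support counts samples, not events). Samples of histotypes
#' listed in `excluded_histotypes` do not contribute support (useful
#' when one histotype's massive event load would swamp the panel), but
#' such samples are still scored against the final panel downstream.
#'
#' @param profiles list of `msi_profile` objects (see [call_sample()]).
#' @param min_samples recurrence threshold k (default 5).
#' @param excluded_histotypes histotype labels omitted from support
#'   counting (default none).
#' @return object of class `recurrent_panel`: list with `loci` (sorted
#'   character vector), `support` (named integer vector over all loci
#'   with any support), `min_samples`, `excluded_histotypes`.
#' @export
build_panel <- function(profiles, min_samples = 5,
                        excluded_histotypes = character()) {
  stopifnot_scalar_number(min_samples, "min_samples", min = 1)
  counted <- Filter(function(p) !(p$histotype %in% excluded_histotypes), profiles)
  events <- unlist(lapply(counted, function(p) unique(p$raw_unstable)),
                   use.names = FALSE)
  support <- if (length(events) == 0L) integer(0) else table(events)
  support <- setNames(as.integer(support), names(support))
  loci <- sort(names(support)[support >= min_samples])
  structure(
    list(loci = loci, support = support, min_samples = min_samples,
         excluded_histotypes = excluded_histotypes),
    class = "recurrent_panel"
  )
}

#' @export
print.recurrent_panel <- function(x, ...) {
  cat(sprintf("<recurrent_panel> %d loci (support >= %d sample(s)%s)\n",
              length(x$loci), x$min_samples,
              if (length(x$excluded_histotypes) > 0L)
                paste0("; excluding ", paste(x$excluded_histotypes, collapse = ", "))
              else ""))
  invisible(x)
}

#' Score one sample's MSI burden
#'
#' burden = |unstable loci in the panel| / |panel|. The category is left
#' unset (`NA`); see [classify_cohort()].
#'
#' @param profile an `msi_profile`.
#' @param panel a non-empty [build_panel()] result.
#' @return one-row data.frame: `sample`, `histotype`,
#'   `n_recurrent_affected`, `panel_size`, `burden` (fraction),
#'   `raw_event_count`, `category` (`NA`).
#' @export
msi_burden <- function(profile, panel) {
  if (!inherits(panel, "recurrent_panel")) msi_stop("'panel' must be a recurrent_panel")
  if (length(panel$loci) == 0L) msi_stop("empty recurrent panel: no burden is defined")
  n_aff <- length(intersect(profile$raw_unstable, panel$loci))
  data.frame(
    sample = profile$sample, histotype = profile$histotype,
    n_recurrent_affected = n_aff, panel_size = length(panel$loci),
    burden = n_aff / length(panel$loci),
    raw_event_count = profile$raw_event_count,
    category = NA_character_, stringsAsFactors = FALSE
  )
}

#' Burden table for a cohort
#'
#' @param profiles list of `msi_profile` objects.
#' @param panel a [build_panel()] result.
#' @return data.frame with one [msi_burden()] row per profile.
#' @export
burden_table <- function(profiles, panel) {
  do.call(rbind, c(lapply(profiles, msi_burden, panel = panel),
                   list(make.row.names = FALSE)))
}

#' Classify a cohort into MSI-H / MSI-L / MSS / EXCLUDED
#'
#' Samples without any raw instability event are MSS. Samples with raw
#' events but none on the recurrent panel are EXCLUDED (patient-specific
#' instability only) and take no part in the threshold. The remaining
#' ("classifiable") samples are MSI-H when their burden is strictly
#' above the threshold and MSI-L otherwise (a burden exactly equal to
#' the mean is MSI-L). The threshold is the mean burden over the
#' classifiable samples (`threshold_population = "classified"`, the
#' default) or over all samples including zeros (`"all"`).
#'
#' @param records burden data.frame from [burden_table()].
#' @param threshold_population `"classified"` or `"all"`.
#' @return list with `records` (categories filled), `threshold` (the
#'   mean burden used; `NA` when no sample is classifiable) and
#'   `threshold_population`.
#' @export
classify_cohort <- function(records,
                            threshold_population = c("classified", "all")) {
  threshold_population <- match.arg(threshold_population)
  if (nrow(records) == 0L) msi_stop("no samples to classify")
  classifiable <- records$n_recurrent_affected >= 1L
  threshold <- if (!any(classifiable)) {
    NA_real_
  } else if (threshold_population == "classified") {
    mean(records$burden[classifiable])
  } else {
    mean(records$burden)
  }
  cat_vec <- ifelse(
    records$raw_event_count == 0L, "MSS",
    ifelse(!classifiable, "EXCLUDED",
           ifelse(records$burden > threshold, "MSI-H", "MSI-L"))
  )
  records$category <- cat_vec
  list(records = records, threshold = threshold,
       threshold_population = threshold_population)
}

#' Serialize / read panel and burden tables
#'
#' The panel TSV has columns `locus_key`, `support` (panel members
#' only); the burden TSV carries `sample`, `histotype`,
#' `n_recurrent_affected`, `panel_size`, `burden_pct` (percent),
#' `raw_event_count`, `category`.
#'
#' @param panel a `recurrent_panel`.
#' @param path file path.
#' @return the path (writers) or a data.frame (readers).
#' @export
write_panel <- function(panel, path) {
  df <- data.frame(locus_key = panel$loci,
                   support = as.integer(panel$support[panel$loci]),
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_panel
#' @param records classified burden data.frame.
#' @export
write_burden <- function(records, path) {
  out <- records
  out$burden_pct <- 100 * out$burden
  out$burden <- NULL
  cols <- c("sample", "histotype", "n_recurrent_affected", "panel_size",
            "burden_pct", "raw_event_count", "category")
  write_tsv(out[, cols, drop = FALSE], path)
}

#' @rdname write_panel
#' @export
read_burden <- function(path) {
  df <- read_tsv(path, required = c("sample", "histotype", "n_recurrent_affected",
                                    "panel_size", "burden_pct",
                                    "raw_event_count", "category"),
                 what = "burden table")
  df$burden <- df$burden_pct / 100
  df
}
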