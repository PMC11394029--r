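# End-to-end orchestration: scan -> call -> consensus -> tmb -> burden ->
# stats, with resolved-config capture, stage checksums and a JSON report.

.default_run_params <- function() {
  list(
    alpha = 0.05, min_cov = 20, fdr = FALSE,
    min_callers = 2, min_samples = 5,
    excluded_histotypes = character(),
    denominator_mb = 57,
    excluded_contigs = c("chrM", "MT"),
    threshold_population = "classified"
  )
}

#' Run the full MSI-burden pipeline
#'
#' Chains every stage over files on disk: microsatellite scan (or a
#' precomputed site list), per-locus instability calling, three-caller
#' consensus with Panel-of-Normals filtering, TMB, recurrent-panel
#' burden scoring with classification, and the statistics report. Each
#' stage writes its artifact into `out_dir`; the run report embeds the
#' classification threshold, category counts and per-file MD5 checksums,
#' and the fully resolved configuration is written next to the outputs.
#' The pipeline itself is deterministic: identical inputs and config
#' give identical outputs.
#'
#' @param config named list (or path to a JSON/YAML file) with fields:
#'   `out_dir`; inputs `reference` (FASTA) or `sites` (TSV),
#'   `histograms`, `samples`, `callers` (named character vector/list of
#'   per-caller variant-table TSVs), `pon` (optional TSV); and any of
#'   the parameters `alpha`, `min_cov`, `fdr`, `min_callers`,
#'   `min_samples`, `excluded_histotypes`, `denominator_mb`,
#'   `excluded_contigs`, `threshold_population`. Unknown keys are
#'   rejected.
#' @return the run report (list), invisibly; also written as
#'   `report.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) config <- read_run_config(config)
  known <- c("out_dir", "reference", "sites", "histograms", "samples",
             "callers", "pon", names(.default_run_params()))
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0L) {
    msi_stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  params <- modifyList(.default_run_params(),
                       config[intersect(names(config), names(.default_run_params()))])
  if (is.null(config$out_dir)) msi_stop("config needs 'out_dir'")
  for (f in c("histograms", "samples")) {
    if (is.null(config[[f]])) msi_stop(sprintf("config needs input '%s'", f))
  }
  if (is.null(config$reference) && is.null(config$sites)) {
    msi_stop("config needs 'reference' (FASTA) or 'sites' (TSV)")
  }
  inputs <- c(config$reference, config$sites, config$histograms,
              config$samples, unlist(config$callers), config$pon)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing) > 0L) {
    msi_stop(sprintf("missing input file(s): %s", paste(missing, collapse = ", ")))
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifact <- function(name) file.path(out_dir, name)

  # -- scan ---------------------------------------------------------------
  if (!is.null(config$sites)) {
    msi_log("scan", "using precomputed site list %s", config$sites)
    sites <- read_sites(config$sites)
  } else {
    msi_log("scan", "scanning reference %s", config$reference)
    sites <- scan_reference(config$reference)
  }
  write_sites(sites, artifact("sites.tsv"))
  msi_log("scan", "%d microsatellite loci", nrow(sites))

  # -- call ---------------------------------------------------------------
  histograms <- read_histograms(config$histograms)
  samples <- read_tsv(config$samples, required = c("sample", "histotype"),
                      what = "sample sheet")
  called <- call_cohort(histograms, samples, alpha = params$alpha,
                        min_cov = params$min_cov, fdr = params$fdr)
  write_calls(called$calls, artifact("calls.tsv"))
  msi_log("call", "%d sample-locus tests, %d unstable",
          nrow(called$calls), sum(called$calls$unstable))

  # -- consensus ----------------------------------------------------------
  consensus <- NULL
  if (!is.null(config$callers)) {
    caller_paths <- unlist(config$callers)
    callsets <- lapply(caller_paths, read_variant_table)
    names(callsets) <- names(caller_paths) %||% paste0("caller_", LETTERS[seq_along(callsets)])
    per_sample_ids <- sort(unique(unlist(lapply(callsets, `[[`, "sample"))))
    cons_rows <- lapply(per_sample_ids, function(s) {
      one <- lapply(callsets, function(cs) cs[cs$sample == s, , drop = FALSE])
      v <- consensus_vote(one, min_callers = params$min_callers)
      if (nrow(v) > 0L) v$sample <- s
      v
    })
    consensus <- do.call(rbind, c(cons_rows, list(make.row.names = FALSE)))
    n_before <- nrow(consensus)
    if (!is.null(config$pon)) {
      pon <- panel_of_normals(read_variant_table(config$pon))
      filtered <- apply_pon(consensus, pon)
      consensus <- filtered$variants
      write_variant_table(filtered$removed, artifact("pon_removed.tsv"))
    }
    write_variant_table(consensus, artifact("consensus.tsv"))
    msi_log("consensus", "%d consensus variants (%d removed by PON)",
            nrow(consensus), n_before - nrow(consensus))
  }

  # -- tmb ----------------------------------------------------------------
  tmb <- NULL
  if (!is.null(consensus)) {
    tmb <- tmb_by_sample(consensus, samples = samples$sample,
                         denominator_mb = params$denominator_mb,
                         excluded_contigs = params$excluded_contigs)
    write_tsv(tmb, artifact("tmb.tsv"))
    msi_log("tmb", "median TMB %.3f mutations/Mb", median(tmb$tmb))
  }

  # -- burden -------------------------------------------------------------
  panel <- build_panel(called$profiles, min_samples = params$min_samples,
                       excluded_histotypes = params$excluded_histotypes)
  if (length(panel$loci) == 0L) {
    msi_stop("burden stage failed: recurrent panel is empty at this min_samples")
  }
  write_panel(panel, artifact("panel.tsv"))
  records <- burden_table(called$profiles, panel)
  classified <- classify_cohort(records,
                                threshold_population = params$threshold_population)
  write_burden(classified$records, artifact("burden.tsv"))
  counts <- table(factor(classified$records$category,
                         levels = c("MSI-H", "MSI-L", "MSS", "EXCLUDED")))
  if (sum(counts) != nrow(classified$records)) {
    msi_stop("burden stage failed: category partition does not cover the cohort")
  }
  msi_log("burden", "panel %d loci; threshold %.4f; H/L/S/X = %s",
          length(panel$loci), classified$threshold,
          paste(counts, collapse = "/"))

  # -- stats --------------------------------------------------------------
  stats_report <- NULL
  if (!is.null(tmb)) {
    stats_report <- cohort_stats_report(classified$records, tmb,
                                        classified$threshold,
                                        alpha = params$alpha)
    write_stats_report(stats_report, artifact("stats.json"))
  }

  # -- report -------------------------------------------------------------
  resolved <- c(config[setdiff(names(config), names(params))], params)
  jsonlite::write_json(resolved, artifact("config_resolved.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  artifacts <- list.files(out_dir, full.names = TRUE)
  artifacts <- artifacts[!basename(artifacts) %in% c("report.json")]
  report <- list(
    n_samples = nrow(samples),
    n_sites = nrow(sites),
    panel_size = length(panel$loci),
    threshold = classified$threshold,
    category_counts = as.list(setNames(as.integer(counts), names(counts))),
    stats = if (!is.null(stats_report)) unclass(stats_report) else NULL,
    checksums = as.list(md5sum(sort(artifacts)))
  )
  names(report$checksums) <- basename(names(report$checksums))
  jsonlite::write_json(report, artifact("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  msi_log("report", "written to %s", artifact("report.json"))
  invisible(report)
}

#' Read a pipeline run configuration
#'
#' JSON (`.json`) or YAML (`.yml`/`.yaml`) file with the fields
#' described in [run_pipeline()].
#'
#' @param path config file path.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) msi_stop(sprintf("missing config file: '%s'", path))
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}
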