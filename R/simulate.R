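# Seeded synthetic tumor-normal cohorts with planted ground truth:
# a small reference with known microsatellites, per-sample repeat
# histograms, three imperfect caller call-sets with a Panel of Normals,
# and a linear burden-TMB coupling. Every file dialect matches what the
# analysis stages consume.

#' Default histotype template
#'
#' Ten histological tumor types with sample counts mirroring a large
#' published canine pan-cancer cohort (137, 136, 103, 98, 65, 64, 52,
#' 28, 5, 4 at full scale), per-panel-locus instability rates spanning
#' the reported orders of magnitude (0.192 for B-cell lymphoma down to
#' 0.0005 for T-cell lymphoma), and a common patient-specific event rate
#' on background loci.
#'
#' @param scale cohort scale factor (1 = full size; 0.2 = desk scale).
#' @return data.frame with `histotype`, `n_samples`,
#'   `locus_instability_rate`, `patient_specific_rate`.
#' @export
default_histotypes <- function(scale = 0.2) {
  full_n <- c(137L, 136L, 103L, 98L, 65L, 64L, 52L, 28L, 5L, 4L)
  data.frame(
    histotype = c("melanoma", "mammary_carcinoma", "b_cell_lymphoma",
                  "osteosarcoma", "t_cell_lymphoma", "hemangiosarcoma",
                  "glioma", "mast_cell_tumor", "pulmonary_adenocarcinoma",
                  "urinary_carcinoma"),
    n_samples = pmax(1L, as.integer(round(full_n * scale))),
    locus_instability_rate = c(0.005, 0.008, 0.192, 0.015, 0.0005,
                               0.012, 0.018, 0.002, 0.027, 0.004),
    patient_specific_rate = 0.001,
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic-cohort generator. Defaults are
#' the desk-scale study conditions: a 0.2x cohort (139 samples), 200
#' shared panel loci plus 100 background loci, mean coverage 100 reads
#' per tissue, a 3-repeat contraction at unstable loci, per-read stutter
#' probability 0.01 per adjacent repeat length, and a linear burden-TMB
#' coupling TMB = 0.42 + 8 x burden + N(0, 0.35) truncated at 0.
#'
#' @param seed integer RNG seed (< 2^31 - 16; the generator derives
#'   small per-stage offsets).
#' @param scale cohort scale factor used by [default_histotypes()].
#' @param histotypes histotype template data.frame.
#' @param panel_size number of shared recurrent loci planted.
#' @param n_background_loci loci only ever hit patient-specifically.
#' @param coverage mean reads per locus per tissue (Poisson).
#' @param stutter_prob per-read probability of slipping one repeat unit
#'   to each side (symmetric).
#' @param shift_magnitude repeat-unit contraction at unstable tumor loci.
#' @param tmb_base,tmb_slope,tmb_noise_sd TMB coupling parameters
#'   (mutations/Mb; TMB truncated at 0).
#' @param caller_sensitivities named length-3 vector of per-caller
#'   true-positive rates.
#' @param caller_fp_rate per-caller false calls per true variant
#'   (Poisson rate multiplier).
#' @param n_artifacts mean systematic artifacts per sample (seen by all
#'   callers).
#' @param pon_contamination_rate fraction of artifact sites present in
#'   the Panel of Normals.
#' @param denominator_mb TMB denominator in Mb.
#' @param alpha,min_cov,min_samples pipeline parameters bundled for the
#'   end-to-end runs (min_samples defaults to 2 at desk scale: the
#'   paper-style recurrence rule of ~5 per ~700 samples, rescaled, while
#'   still requiring events in more than one animal).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, scale = 0.2,
                       histotypes = default_histotypes(scale),
                       panel_size = 200L, n_background_loci = 100L,
                       coverage = 100, stutter_prob = 0.01,
                       shift_magnitude = 3L,
                       tmb_base = 0.42, tmb_slope = 8, tmb_noise_sd = 0.35,
                       caller_sensitivities = c(caller_A = 0.95,
                                                caller_B = 0.90,
                                                caller_C = 0.85),
                       caller_fp_rate = 0.05, n_artifacts = 4,
                       pon_contamination_rate = 0.8,
                       denominator_mb = 57,
                       alpha = 0.05, min_cov = 20, min_samples = 2L) {
  stopifnot_scalar_number(seed, "seed", min = 0)
  if (seed >= 2^31 - 16) msi_stop("'seed' must be below 2^31 - 16")
  if (panel_size < 1) msi_stop("'panel_size' must be >= 1")
  if (n_background_loci < 0) msi_stop("'n_background_loci' must be >= 0")
  rates <- c(histotypes$locus_instability_rate,
             histotypes$patient_specific_rate,
             stutter_prob, caller_sensitivities,
             caller_fp_rate, pon_contamination_rate)
  if (any(rates < 0 | rates > 1)) msi_stop("all rates must lie in [0, 1]")
  if (any(histotypes$n_samples < 1)) msi_stop("each histotype needs >= 1 sample")
  if (length(caller_sensitivities) != 3L) {
    msi_stop("exactly three caller sensitivities are required")
  }
  if (is.null(names(caller_sensitivities))) {
    names(caller_sensitivities) <- paste0("caller_", LETTERS[1:3])
  }
  structure(list(
    seed = as.integer(seed), scale = scale, histotypes = histotypes,
    panel_size = as.integer(panel_size),
    n_background_loci = as.integer(n_background_loci),
    coverage = coverage, stutter_prob = stutter_prob,
    shift_magnitude = as.integer(shift_magnitude),
    tmb_base = tmb_base, tmb_slope = tmb_slope, tmb_noise_sd = tmb_noise_sd,
    caller_sensitivities = caller_sensitivities,
    caller_fp_rate = caller_fp_rate, n_artifacts = n_artifacts,
    pon_contamination_rate = pon_contamination_rate,
    denominator_mb = denominator_mb,
    alpha = alpha, min_cov = min_cov, min_samples = as.integer(min_samples)
  ), class = "sim_config")
}

#' Location shift for a target Mann-Whitney power
#'
#' Normal-approximation effect size (in units of the common standard
#' deviation) at which the two-sided Mann-Whitney test on two normal
#' samples attains the requested power, using the asymptotic relative
#' efficiency 3/pi relative to the t-test. Used to plant TMB shifts of
#' calibrated detectability in simulated category comparisons.
#'
#' @param n1,n2 group sizes.
#' @param power target power (default 0.9).
#' @param alpha two-sided significance level (default 0.05).
#' @return the location shift in standard-deviation units.
#' @export
mw_shift_for_power <- function(n1, n2, power = 0.9, alpha = 0.05) {
  (qnorm(1 - alpha / 2) + qnorm(power)) *
    sqrt((n1 + n2) / (n1 * n2)) / sqrt(3 / pi)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> seed %d | %d samples, %d histotypes | %d panel + %d background loci | coverage %g\n",
    x$seed, sum(x$histotypes$n_samples), nrow(x$histotypes),
    x$panel_size, x$n_background_loci, x$coverage))
  invisible(x)
}

.BASES <- c("A", "C", "G", "T")

# Random flank that never forms a tandem of >= 3 copies for any period
# 1-5 ending at the growing tip, and respects forbidden first/last bases
# at the planted-run boundaries.
.safe_flank <- function(len, forbid_first = NULL, forbid_last = NULL) {
  out <- character(len)
  for (i in seq_len(len)) {
    cand <- sample(.BASES)
    if (i == 1L && !is.null(forbid_first)) cand <- setdiff(cand, forbid_first)
    if (i == len && !is.null(forbid_last)) cand <- setdiff(cand, forbid_last)
    for (b in cand) {
      trial <- c(out[seq_len(i - 1L)], b)
      ok <- TRUE
      for (p in 1:5) {
        if (i >= 3L * p) {
          tail3 <- trial[(i - 3L * p + 1L):i]
          if (all(tail3[1:(2L * p)] == tail3[(p + 1L):(3L * p)])) { ok <- FALSE; break }
        }
      }
      if (ok) { out[i] <- b; break }
    }
    if (out[i] == "") out[i] <- cand[1L]  # unreachable fallback
  }
  paste(out, collapse = "")
}

.random_motif <- function() {
  u <- sample(1:5, 1L, prob = c(0.45, 0.30, 0.15, 0.06, 0.04))
  repeat {
    m <- paste(sample(.BASES, u, replace = TRUE), collapse = "")
    if (.primitive_period(m) == u) return(canonical_motif(m))
  }
}

# Assemble one chromosome from planted loci; regenerate flanks until the
# scanner recovers exactly the planted site list (boundary effects are
# rare but possible with random flanks).
.build_chromosome <- function(chrom, motifs, copies, min_repeats, max_tries = 25L) {
  k <- length(motifs)
  for (try in seq_len(max_tries)) {
    pieces <- character(2L * k + 1L)
    starts <- integer(k)
    pos <- 0L
    prev_forbid <- NULL
    for (j in seq_len(k)) {
      m <- motifs[j]
      flank <- .safe_flank(20L + sample(0:20, 1L),
                           forbid_first = prev_forbid,
                           forbid_last = .last_char(m))
      pieces[2L * j - 1L] <- flank
      pos <- pos + nchar(flank)
      starts[j] <- pos
      run <- strrep(m, copies[j])
      pieces[2L * j] <- run
      pos <- pos + nchar(run)
      prev_forbid <- substr(m, 1L, 1L)
    }
    pieces[2L * k + 1L] <- .safe_flank(20L + sample(0:20, 1L),
                                       forbid_first = prev_forbid)
    seq <- paste(pieces, collapse = "")
    planted <- data.frame(
      chrom = chrom, start = starts,
      end = starts + nchar(motifs) * copies,
      motif = motifs, unit_len = nchar(motifs), ref_repeats = copies,
      stringsAsFactors = FALSE
    )
    planted$locus_key <- locus_key(planted$chrom, planted$start, planted$motif)
    found <- scan_sequence(seq, chrom, min_repeats = min_repeats)
    if (identical(found$locus_key, planted$locus_key) &&
        identical(found$end, planted$end)) {
      return(list(seq = seq, sites = planted))
    }
  }
  msi_stop(sprintf("failed to assemble chromosome '%s' after %d tries", chrom, max_tries))
}

#' Generate a synthetic reference with planted microsatellites
#'
#' Builds a small multi-chromosome reference containing exactly
#' `panel_size + n_background_loci` microsatellite runs at known
#' coordinates, separated by random flanking sequence constructed so the
#' scanner recovers every planted locus and nothing else. Seeds the RNG
#' from `config$seed`; the same config yields a byte-identical FASTA.
#'
#' @param config a [sim_config()].
#' @param n_chromosomes number of chromosomes to spread loci over.
#' @return list with `sequences` (named character vector), `sites`
#'   (planted site list with a `role` column, `"panel"` or
#'   `"background"`).
#' @export
generate_reference <- function(config, n_chromosomes = 4L) {
  if (!inherits(config, "sim_config")) msi_stop("'config' must be a sim_config")
  set.seed(config$seed)
  n_loci <- config$panel_size + config$n_background_loci
  min_rep <- default_min_repeats()
  motifs <- vapply(seq_len(n_loci), function(i) .random_motif(), character(1))
  copies <- as.integer(min_rep[as.character(nchar(motifs))] + rpois(n_loci, 3))
  chrom_of <- rep_len(paste0("chr", seq_len(n_chromosomes)), n_loci)

  seqs <- character(0)
  sites <- list()
  for (chr in unique(chrom_of)) {
    i <- chrom_of == chr
    built <- .build_chromosome(chr, motifs[i], unname(copies[i]), min_rep)
    seqs[[chr]] <- built$seq
    sites[[chr]] <- built$sites
  }
  sites <- do.call(rbind, c(sites, list(make.row.names = FALSE)))
  # roles follow generation order; `sites` rows are grouped by chromosome,
  # within a chromosome in generation order, so map indices accordingly
  role <- rep("background", n_loci)
  role[seq_len(config$panel_size)] <- "panel"
  gen_order <- unlist(lapply(unique(chrom_of), function(chr) which(chrom_of == chr)),
                      use.names = FALSE)
  sites$role <- role[gen_order]
  list(sequences = seqs, sites = sites)
}

#' Write reference FASTA
#'
#' @param sequences named character vector of chromosome sequences.
#' @param path output FASTA path.
#' @return the path, invisibly.
#' @export
write_reference_fasta <- function(sequences, path) {
  dna <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(dna, path, width = 70L)
  invisible(path)
}

# Vectorized stutter histogram: reads at center +/- 1 repeat unit.
.stutter_counts <- function(coverage, q) {
  left <- rbinom(length(coverage), coverage, q)
  right <- rbinom(length(coverage), coverage - left, q / (1 - q))
  cbind(left = left, center = coverage - left - right, right = right)
}

#' Generate the cohort histograms and ground truth
#'
#' For every sample and locus, draws a normal-tissue histogram
#' concentrated at the reference repeat count (with symmetric one-unit
#' stutter) and a tumor histogram that is either identical in law
#' (stable locus) or contracted by `shift_magnitude` repeat units
#' (unstable locus). Panel loci become unstable with the histotype's
#' rate; background loci with the patient-specific rate. Coverage is
#' Poisson around `config$coverage`. Seeds the RNG at
#' `config$seed + 1`.
#'
#' @param config a [sim_config()].
#' @param sites planted site list from [generate_reference()] (needs
#'   `locus_key`, `ref_repeats`, `role`).
#' @return list with `histograms` (long data.frame), `samples` (sample
#'   sheet), `truth` (per-sample true unstable sets, burdens, raw event
#'   counts and categories under the generator's threshold).
#' @export
generate_cohort <- function(config, sites) {
  if (!inherits(config, "sim_config")) msi_stop("'config' must be a sim_config")
  set.seed(config$seed + 1L)
  ht <- config$histotypes
  samples <- data.frame(
    sample = sprintf("S%03d", seq_len(sum(ht$n_samples))),
    histotype = rep(ht$histotype, ht$n_samples),
    stringsAsFactors = FALSE
  )
  rate_panel <- rep(ht$locus_instability_rate, ht$n_samples)
  rate_bg <- rep(ht$patient_specific_rate, ht$n_samples)
  n <- nrow(samples)
  panel_keys <- sites$locus_key[sites$role == "panel"]
  bg_keys <- sites$locus_key[sites$role == "background"]
  P <- length(panel_keys); B <- length(bg_keys)

  unstable_panel <- matrix(rbinom(n * P, 1L, rep(rate_panel, each = P)) == 1L,
                           nrow = P, ncol = n)
  unstable_bg <- if (B > 0L) {
    matrix(rbinom(n * B, 1L, rep(rate_bg, each = B)) == 1L, nrow = B, ncol = n)
  } else matrix(FALSE, 0L, n)

  all_keys <- c(panel_keys, bg_keys)
  ref_rep <- sites$ref_repeats[match(all_keys, sites$locus_key)]
  unstable <- rbind(unstable_panel, unstable_bg)
  L <- length(all_keys)

  # long grid: locus fastest, then sample, then tissue
  grid_sample <- rep(rep(samples$sample, each = L), times = 2L)
  grid_locus <- rep(rep(all_keys, times = n), times = 2L)
  grid_ref <- rep(rep(ref_rep, times = n), times = 2L)
  grid_tissue <- rep(c("normal", "tumor"), each = n * L)
  grid_unstable <- c(rep(FALSE, n * L), as.vector(unstable))

  center <- ifelse(grid_tissue == "tumor" & grid_unstable,
                   pmax(1L, grid_ref - config$shift_magnitude), grid_ref)
  coverage <- rpois(length(center), config$coverage)
  st <- .stutter_counts(coverage, config$stutter_prob)

  histograms <- data.frame(
    locus_key = rep(grid_locus, 3L),
    sample = rep(grid_sample, 3L),
    tissue = rep(grid_tissue, 3L),
    repeat_count = c(pmax(0L, center - 1L), center, center + 1L),
    read_count = c(st[, "left"], st[, "center"], st[, "right"]),
    stringsAsFactors = FALSE
  )
  histograms <- histograms[histograms$read_count > 0L, , drop = FALSE]
  histograms <- histograms[order(histograms$sample, histograms$locus_key,
                                 histograms$tissue, histograms$repeat_count), ,
                           drop = FALSE]
  rownames(histograms) <- NULL

  true_sets <- lapply(seq_len(n), function(i) sort(all_keys[unstable[, i]]))
  names(true_sets) <- samples$sample
  n_panel_events <- colSums(unstable_panel)
  true_burden <- n_panel_events / P
  raw_events <- colSums(unstable)

  classifiable <- n_panel_events >= 1L
  thr <- if (any(classifiable)) mean(true_burden[classifiable]) else NA_real_
  category <- ifelse(raw_events == 0L, "MSS",
                     ifelse(!classifiable, "EXCLUDED",
                            ifelse(true_burden > thr, "MSI-H", "MSI-L")))

  truth <- list(
    samples = samples,
    unstable_loci = true_sets,
    n_panel_events = n_panel_events,
    raw_event_count = raw_events,
    burden = true_burden,
    threshold = thr,
    category = category,
    panel_loci = sort(panel_keys)
  )
  list(histograms = histograms, samples = samples, truth = truth)
}

#' Closed-form burden-TMB correlation implied by the coupling
#'
#' For TMB = base + slope x burden + noise (noise sd `tmb_noise_sd`),
#' the population Pearson correlation is
#' `slope * sd_burden / sqrt(slope^2 * sd_burden^2 + noise_sd^2)`
#' (ignoring the truncation at 0, which is negligible at the default
#' parameters).
#'
#' @param slope,noise_sd coupling parameters.
#' @param sd_burden standard deviation of the burden distribution.
#' @return the implied correlation.
#' @export
coupling_target_r <- function(slope, noise_sd, sd_burden) {
  slope * sd_burden / sqrt(slope^2 * sd_burden^2 + noise_sd^2)
}

#' Noise level for a target burden-TMB correlation
#'
#' Inverse of [coupling_target_r()]: the noise sd that makes the linear
#' coupling produce Pearson correlation `r_target` at a given burden
#' spread.
#'
#' @param r_target desired correlation in (0, 1).
#' @param slope coupling slope.
#' @param sd_burden standard deviation of the burden distribution.
#' @return noise standard deviation.
#' @export
coupling_noise_for_r <- function(r_target, slope, sd_burden) {
  if (r_target <= 0 || r_target >= 1) msi_stop("'r_target' must be in (0, 1)")
  slope * sd_burden * sqrt(1 / r_target^2 - 1)
}

#' Draw paired burden and TMB values from the coupling
#'
#' Samples burdens from the histotype-mixture implied by `config`
#' (binomial panel-event counts over `panel_size` loci) and TMB from the
#' linear coupling truncated at 0. Used for sampling-distribution checks
#' of the correlation estimator at arbitrary n.
#'
#' @param config a [sim_config()].
#' @param n number of samples to draw.
#' @return data.frame with `burden`, `tmb`.
#' @export
simulate_burden_tmb <- function(config, n) {
  ht <- config$histotypes
  w <- ht$n_samples / sum(ht$n_samples)
  h <- sample.int(nrow(ht), n, replace = TRUE, prob = w)
  k <- rbinom(n, config$panel_size, ht$locus_instability_rate[h])
  burden <- k / config$panel_size
  tmb <- pmax(0, config$tmb_base + config$tmb_slope * burden +
                 rnorm(n, 0, config$tmb_noise_sd))
  data.frame(burden = burden, tmb = tmb)
}

.random_positions <- function(n, contigs, max_pos = 5e6L) {
  data.frame(
    chrom = sample(contigs, n, replace = TRUE),
    pos = sample.int(max_pos, n, replace = FALSE),
    stringsAsFactors = FALSE
  )
}

.random_alleles <- function(n, indel_frac = 0.1) {
  ref <- sample(.BASES, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(.BASES, r), 1L), character(1))
  is_indel <- runif(n) < indel_frac
  ins <- runif(n) < 0.5
  ext <- sample(.BASES, n, replace = TRUE)
  ref <- ifelse(is_indel & !ins, paste0(ref, ext), ref)
  alt <- ifelse(is_indel, ifelse(ins, paste0(ref, ext), substr(ref, 1L, 1L)), alt)
  data.frame(ref = ref, alt = unname(alt), stringsAsFactors = FALSE)
}

#' Generate the three caller call-sets and the Panel of Normals
#'
#' Per sample, the number of true coding mutations follows the TMB
#' coupling (`round(tmb * denominator_mb)`); noncoding passengers and
#' mitochondrial variants are added on top (never counted in the true
#' TMB). Each caller detects each true variant independently with its
#' sensitivity, adds its own false positives, and all three callers see
#' a small set of systematic artifact sites, a configured fraction of
#' which also appear in the Panel of Normals. Seeds the RNG at
#' `config$seed + 2`.
#'
#' @param config a [sim_config()].
#' @param truth ground truth from [generate_cohort()].
#' @param contigs coding contig names to place variants on.
#' @return list with `callsets` (named list of three data.frames with a
#'   `sample` column), `pon` (variant data.frame), `truth_variants`
#'   (per-sample true variant table), `tmb_truth` (data.frame `sample`,
#'   `n_coding`, `tmb`).
#' @export
generate_caller_vcfs <- function(config, truth,
                                 contigs = paste0("chr", 1:4)) {
  if (!inherits(config, "sim_config")) msi_stop("'config' must be a sim_config")
  set.seed(config$seed + 2L)
  samples <- truth$samples$sample
  n <- length(samples)
  tmb_drawn <- pmax(0, config$tmb_base + config$tmb_slope * truth$burden +
                       rnorm(n, 0, config$tmb_noise_sd))
  n_coding <- as.integer(round(tmb_drawn * config$denominator_mb))
  tmb_truth <- data.frame(sample = samples, n_coding = n_coding,
                          tmb = n_coding / config$denominator_mb,
                          stringsAsFactors = FALSE)

  sens <- config$caller_sensitivities
  callers <- names(sens)
  per_sample <- lapply(seq_len(n), function(i) {
    nc <- n_coding[i]
    n_noncod <- rpois(1L, 0.3 * nc + 2)
    n_mito <- rpois(1L, 0.5)
    n_true <- nc + n_noncod
    pos <- .random_positions(n_true + n_mito, contigs)
    if (n_mito > 0L) pos$chrom[(n_true + 1L):(n_true + n_mito)] <- "chrM"
    al <- .random_alleles(n_true + n_mito)
    effect <- c(
      sample(c("nonsynonymous", "synonymous"), nc, replace = TRUE, prob = c(0.7, 0.3)),
      rep("noncoding", n_noncod),
      sample(c("nonsynonymous", "synonymous"), n_mito, replace = TRUE)
    )
    truevar <- data.frame(sample = rep(samples[i], n_true + n_mito),
                          chrom = pos$chrom, pos = pos$pos,
                          ref = al$ref, alt = al$alt, effect = effect,
                          stringsAsFactors = FALSE)

    n_art <- rpois(1L, config$n_artifacts)
    art <- if (n_art > 0L) {
      apos <- .random_positions(n_art, contigs)
      aal <- .random_alleles(n_art, indel_frac = 0.3)
      data.frame(sample = samples[i], chrom = apos$chrom, pos = apos$pos,
                 ref = aal$ref, alt = aal$alt,
                 effect = sample(.effect_levels, n_art, replace = TRUE),
                 in_pon = runif(n_art) < config$pon_contamination_rate,
                 stringsAsFactors = FALSE)
    } else NULL

    sets <- lapply(callers, function(cl) {
      det <- truevar[runif(nrow(truevar)) < sens[[cl]], , drop = FALSE]
      n_fp <- rpois(1L, config$caller_fp_rate * max(1L, nrow(truevar)))
      fp <- if (n_fp > 0L) {
        fpos <- .random_positions(n_fp, contigs)
        fal <- .random_alleles(n_fp)
        data.frame(sample = samples[i], chrom = fpos$chrom, pos = fpos$pos,
                   ref = fal$ref, alt = fal$alt,
                   effect = sample(.effect_levels, n_fp, replace = TRUE),
                   stringsAsFactors = FALSE)
      } else NULL
      parts <- list(det, fp)
      if (!is.null(art)) parts <- c(parts, list(art[, names(det), drop = FALSE]))
      do.call(rbind, c(Filter(Negate(is.null), parts), list(make.row.names = FALSE)))
    })
    names(sets) <- callers
    list(truevar = truevar, art = art, sets = sets)
  })

  callsets <- lapply(callers, function(cl) {
    do.call(rbind, c(lapply(per_sample, function(x) x$sets[[cl]]),
                     list(make.row.names = FALSE)))
  })
  names(callsets) <- callers
  pon_rows <- Filter(Negate(is.null), lapply(per_sample, function(x) {
    if (is.null(x$art)) NULL else x$art[x$art$in_pon, c("chrom", "pos", "ref", "alt"), drop = FALSE]
  }))
  pon <- if (length(pon_rows) > 0L) {
    do.call(rbind, c(pon_rows, list(make.row.names = FALSE)))
  } else {
    data.frame(chrom = character(0), pos = integer(0),
               ref = character(0), alt = character(0), stringsAsFactors = FALSE)
  }
  truth_variants <- do.call(rbind, c(lapply(per_sample, `[[`, "truevar"),
                                     list(make.row.names = FALSE)))
  list(callsets = callsets, pon = pon,
       truth_variants = truth_variants, tmb_truth = tmb_truth)
}

#' Generate a complete synthetic cohort on disk
#'
#' Runs [generate_reference()], [generate_cohort()] and
#' [generate_caller_vcfs()] in order under `config$seed` and, if `dir`
#' is given, writes every artifact in the dialects the pipeline
#' consumes: `reference.fa`, `sites_truth.tsv`, `histograms.tsv`,
#' `samples.tsv`, `<caller>.tsv` call tables, `pon.tsv` and
#' `ground_truth.json`.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed), or `NULL` for an
#'   in-memory run.
#' @return list with `reference`, `cohort`, `variants` and (if written)
#'   `paths`.
#' @export
generate_synthetic_cohort <- function(config, dir = NULL) {
  reference <- generate_reference(config)
  cohort <- generate_cohort(config, reference$sites)
  variants <- generate_caller_vcfs(config, cohort$truth)
  out <- list(reference = reference, cohort = cohort, variants = variants)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      reference = file.path(dir, "reference.fa"),
      sites_truth = file.path(dir, "sites_truth.tsv"),
      histograms = file.path(dir, "histograms.tsv"),
      samples = file.path(dir, "samples.tsv"),
      pon = file.path(dir, "pon.tsv"),
      ground_truth = file.path(dir, "ground_truth.json")
    )
    write_reference_fasta(reference$sequences, paths$reference)
    write_tsv(reference$sites, paths$sites_truth)
    write_tsv(cohort$histograms, paths$histograms)
    write_tsv(cohort$samples, paths$samples)
    write_tsv(variants$pon, paths$pon)
    for (cl in names(variants$callsets)) {
      paths[[cl]] <- file.path(dir, paste0(cl, ".tsv"))
      write_tsv(variants$callsets[[cl]], paths[[cl]])
    }
    truth_json <- list(
      threshold = cohort$truth$threshold,
      burden = as.list(setNames(cohort$truth$burden, cohort$truth$samples$sample)),
      category = as.list(setNames(cohort$truth$category, cohort$truth$samples$sample)),
      raw_event_count = as.list(setNames(cohort$truth$raw_event_count,
                                         cohort$truth$samples$sample)),
      panel_loci = cohort$truth$panel_loci,
      tmb = as.list(setNames(variants$tmb_truth$tmb, variants$tmb_truth$sample))
    )
    jsonlite::write_json(truth_json, paths$ground_truth, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    out$paths <- paths
  }
  out
}
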