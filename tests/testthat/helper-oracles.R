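# Independent oracles used to validate the package's algorithms.
# These deliberately take different computational routes from the
# implementation (positional counting instead of run-length encoding,
# full enumeration instead of closed forms).

oracle_primitive_period <- function(m) {
  n <- nchar(m)
  for (p in seq_len(n)) {
    if (n %% p == 0L && strrep(substr(m, 1L, p), n %/% p) == m) return(p)
  }
  n
}

# Brute-force tandem-run enumerator: for every (start, unit length),
# count full copies forward block by block; keep leftmost-anchored runs
# reaching the minimum; resolve overlaps by the same deterministic rule
# (longest, then smaller unit, then smaller start).
oracle_scan <- function(seq, chrom, min_repeats = default_min_repeats()) {
  s <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(s)
  rows <- list()
  for (u in 1:5) {
    if (n < 2L * u) next
    for (st in seq_len(n - 2L * u + 1L)) {
      unit <- s[st:(st + u - 1L)]
      if (any(unit == "N")) next
      if (oracle_primitive_period(paste(unit, collapse = "")) != u) next
      copies <- 1L
      while (st + (copies + 1L) * u - 1L <= n &&
             all(s[(st + copies * u):(st + (copies + 1L) * u - 1L)] == unit)) {
        copies <- copies + 1L
      }
      if (copies < min_repeats[[as.character(u)]]) next
      # leftmost anchor: the period-u match run must not extend left
      if (st > 1L && s[st - 1L] != "N" && s[st - 1L + u] != "N" &&
          s[st - 1L] == s[st - 1L + u]) next
      rows[[length(rows) + 1L]] <- data.frame(
        start = st - 1L, u = u, copies = copies,
        unit = paste(unit, collapse = ""), stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      motif = character(0), unit_len = integer(0),
                      ref_repeats = integer(0), stringsAsFactors = FALSE))
  }
  cand <- do.call(rbind, rows)
  cand$len <- cand$u * cand$copies
  cand$end <- cand$start + cand$len
  ord <- order(-cand$len, cand$u, cand$start)
  keep <- logical(nrow(cand))
  acc_s <- integer(0); acc_e <- integer(0)
  for (k in ord) {
    if (!any(cand$start[k] < acc_e & cand$end[k] > acc_s)) {
      keep[k] <- TRUE
      acc_s <- c(acc_s, cand$start[k]); acc_e <- c(acc_e, cand$end[k])
    }
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(cand$start), , drop = FALSE]
  data.frame(chrom = chrom, start = cand$start, end = cand$end,
             motif = canonical_motif(cand$unit), unit_len = cand$u,
             ref_repeats = cand$copies, stringsAsFactors = FALSE)
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T"), n_prob = 0) {
  b <- sample(alphabet, n, replace = TRUE)
  if (n_prob > 0) b[runif(n) < n_prob] <- "N"
  paste(b, collapse = "")
}

# Sequences enriched for repeats: random backbone with tandem runs and
# occasional N interruptions spliced in.
random_repeatish_dna <- function(n) {
  pieces <- character(0)
  total <- 0L
  while (total < n) {
    if (runif(1) < 0.45) {
      u <- sample(1:5, 1L)
      m <- random_dna(u)
      piece <- strrep(m, sample(2:14, 1L))
    } else {
      piece <- random_dna(sample(3:25, 1L), n_prob = 0.03)
    }
    pieces <- c(pieces, piece)
    total <- total + nchar(piece)
  }
  substr(paste(pieces, collapse = ""), 1L, n)
}

# Full-enumeration two-sided Mann-Whitney p-value (both tails measured
# from the null mean), valid for tie-free inputs.
oracle_mw_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- combn(nx + ny, nx)
  allW <- apply(idx, 2L, function(ii) sum(r[ii])) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  mean(abs(allW - mu) >= abs(W - mu) - 1e-9)
}

oracle_consensus_keys <- function(callsets, min_callers = 2) {
  keys <- unlist(lapply(callsets, function(df) {
    unique(paste(df$chrom, df$pos, df$ref, df$alt, sep = ":"))
  }))
  tab <- table(keys)
  sort(names(tab)[tab >= min_callers])
}

# Leftmost equivalent variant position by exhaustive shift search:
# among representations with the same allele lengths that reproduce the
# same edited sequence, find the smallest 1-based position.
oracle_leftmost_pos <- function(refseq, pos, ref, alt) {
  apply_var <- function(p, r, a) {
    paste0(substr(refseq, 1L, p - 1L), a,
           substr(refseq, p + nchar(r), nchar(refseq)))
  }
  target <- apply_var(pos, ref, alt)
  lr <- nchar(ref); la <- nchar(alt)
  for (p in seq_len(pos)) {
    ref2 <- substr(refseq, p, p + lr - 1L)
    alt2 <- substr(target, p, p + la - 1L)
    if (ref2 != alt2 && apply_var(p, ref2, alt2) == target) return(p)
  }
  pos
}

# Small builders used across test files -----------------------------------

make_hist <- function(locus, sample, tissue, counts) {
  repeat_histogram(locus, sample, tissue, counts)
}

make_profile <- function(sample, histotype, unstable, tested = unstable) {
  calls <- data.frame(
    locus_key = tested,
    sample = rep(sample, length(tested)),
    statistic = NA_real_, p_value = NA_real_,
    unstable = tested %in% unstable, reason = "ok",
    stringsAsFactors = FALSE
  )
  msiburden:::msi_profile(sample, histotype, calls)
}

random_variants <- function(n, chroms = c("chr1", "chr2"), max_pos = 50L) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  data.frame(
    chrom = sample(chroms, n, replace = TRUE),
    pos = sample.int(max_pos, n, replace = TRUE),
    ref = ref, alt = unname(alt), stringsAsFactors = FALSE
  )
}

null_locus_rejections <- function(n_loci, coverage = 100,
                                  probs = c(0.15, 0.35, 0.35, 0.15),
                                  repeats = 8:11, alpha = 0.05) {
  tum <- rmultinom(n_loci, coverage, probs)
  nor <- rmultinom(n_loci, coverage, probs)
  rej <- logical(n_loci)
  for (i in seq_len(n_loci)) {
    t <- setNames(tum[, i], repeats)
    n <- setNames(nor[, i], repeats)
    call <- test_locus(make_hist("L", "S", "tumor", t),
                       make_hist("L", "S", "normal", n), alpha = alpha)
    rej[i] <- call$unstable
  }
  rej
}

tmpfile <- function(fileext = "") tempfile(fileext = fileext)
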