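# Tumor vs. matched-normal instability test: pooled chi-square on
# repeat-length histograms, coverage gating, per-sample profiles.

test_that("identical histograms are stable with p = 1", {
  call <- test_locus(make_hist("L1", "S1", "tumor", c(`10` = 50)),
                     make_hist("L1", "S1", "normal", c(`10` = 50)))
  expect_false(call$unstable)
  expect_equal(call$p_value, 1)
})

test_that("disjoint repeat support gives the hand-computed chi-square", {
  # 2x2 table with all expected counts 20: statistic = 4 * 20^2/20 = 80, df 1
  call <- test_locus(make_hist("L1", "S1", "tumor", c(`7` = 40)),
                     make_hist("L1", "S1", "normal", c(`10` = 40)),
                     min_cov = 20)
  expect_equal(call$statistic, 80)
  expect_equal(call$p_value, pchisq(80, df = 1, lower.tail = FALSE))
  expect_true(call$unstable)
})

test_that("insufficient coverage gates the call without an error", {
  call <- test_locus(make_hist("L1", "S1", "tumor", c(`10` = 5)),
                     make_hist("L1", "S1", "normal", c(`10` = 5)),
                     min_cov = 20)
  expect_false(call$unstable)
  expect_equal(call$p_value, 1)
  expect_equal(call$reason, "insufficient_coverage")
})

test_that("mismatched locus or sample identifiers are an error", {
  t <- make_hist("L1", "S1", "tumor", c(`10` = 50))
  expect_error(test_locus(t, make_hist("L2", "S1", "normal", c(`10` = 50))), "locus mismatch")
  expect_error(test_locus(t, make_hist("L1", "S2", "normal", c(`10` = 50))), "sample mismatch")
  expect_error(test_locus(t, t), "tissue")
})

test_that("statistic matches chisq.test when no pooling is needed", {
  set.seed(21)
  for (i in 1:25) {
    k <- sample(2:5, 1L)
    t <- setNames(rmultinom(1, 400, rep(1 / k, k))[, 1], 8:(7 + k))
    n <- setNames(rmultinom(1, 400, rep(1 / k, k))[, 1], 8:(7 + k))
    if (any(t + n == 0)) next
    call <- test_locus(make_hist("L", "S", "tumor", t),
                       make_hist("L", "S", "normal", n))
    tab <- rbind(t, n)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    if (all(ref$expected >= 5)) {
      expect_equal(call$statistic, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(call$p_value, ref$p.value, tolerance = 1e-12)
    }
  }
})

test_that("the test is symmetric in tumor and normal", {
  set.seed(33)
  for (i in 1:20) {
    a <- setNames(rpois(4, 30) + 1, 7:10)
    b <- setNames(rpois(4, 30) + 1, 7:10)
    p1 <- test_locus(make_hist("L", "S", "tumor", a),
                     make_hist("L", "S", "normal", b))$p_value
    p2 <- test_locus(make_hist("L", "S", "tumor", b),
                     make_hist("L", "S", "normal", a))$p_value
    expect_equal(p1, p2, tolerance = 1e-12)
  }
})

test_that("pooling collapses sparse side bins to a single uninformative bin", {
  # a couple of stray stutter reads around a dominant length: expected
  # side-bin counts are far below 5, so everything pools and p = 1
  call <- test_locus(make_hist("L", "S", "tumor", c(`9` = 1, `10` = 98, `11` = 1)),
                     make_hist("L", "S", "normal", c(`10` = 100)))
  expect_equal(call$p_value, 1)
  expect_false(call$unstable)
})

test_that("lowering min_cov never removes a call made at a higher threshold", {
  set.seed(44)
  for (i in 1:20) {
    cov <- sample(10:60, 2L)
    t <- setNames(rmultinom(1, cov[1], c(0.5, 0.5))[, 1], 9:10)
    n <- setNames(rmultinom(1, cov[2], c(0.1, 0.9))[, 1], 9:10)
    t <- t[t > 0]; n <- n[n > 0]
    hi <- test_locus(make_hist("L", "S", "tumor", t),
                     make_hist("L", "S", "normal", n), min_cov = 40)
    lo <- test_locus(make_hist("L", "S", "tumor", t),
                     make_hist("L", "S", "normal", n), min_cov = 5)
    if (hi$unstable) expect_true(lo$unstable)
  }
})

test_that("call_sample collects unstable loci and skips unmatched tumor loci", {
  none <- call_sample(list(), list(), "S1", "melanoma")
  expect_equal(none$raw_event_count, 0L)

  tum <- list(make_hist("L1", "S1", "tumor", c(`7` = 40)),
              make_hist("L2", "S1", "tumor", c(`10` = 40)),
              make_hist("L3", "S1", "tumor", c(`12` = 40)))
  nor <- list(make_hist("L1", "S1", "normal", c(`10` = 40)),
              make_hist("L2", "S1", "normal", c(`10` = 40)),
              make_hist("L3", "S1", "normal", c(`12` = 40)))
  prof <- call_sample(tum, nor, "S1", "melanoma")
  expect_s3_class(prof, "msi_profile")
  expect_equal(prof$raw_unstable, "L1")  # only the shifted locus
  expect_equal(prof$raw_event_count, 1L)

  expect_message(
    part <- call_sample(tum, nor[1:2], "S1", "melanoma"),
    "without matched normal"
  )
  expect_equal(nrow(part$calls), 2L)

  expect_error(call_sample(c(tum, tum[1]), nor, "S1", "melanoma"), "duplicate")
})

test_that("null calibration: rejection rate tracks alpha at informative coverage", {
  set.seed(501)
  rej <- null_locus_rejections(2000, coverage = 100, alpha = 0.05)
  rate <- mean(rej)
  se <- sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(rate - 0.05), 3.3 * se)
})

test_that("call_cohort agrees with per-locus test_locus calls", {
  set.seed(61)
  loci <- paste0("chr1:", seq(0, 90, 10), ":A")
  samples <- data.frame(sample = c("S1", "S2"),
                        histotype = c("melanoma", "glioma"),
                        stringsAsFactors = FALSE)
  rows <- list()
  for (s in samples$sample) for (l in loci) for (ts in c("tumor", "normal")) {
    shift <- ts == "tumor" && runif(1) < 0.3
    center <- if (shift) 7L else 10L
    cnt <- rmultinom(1, 100, c(0.02, 0.96, 0.02))[, 1]
    rows[[length(rows) + 1L]] <- data.frame(
      locus_key = l, sample = s, tissue = ts,
      repeat_count = center + (-1:1), read_count = cnt,
      stringsAsFactors = FALSE
    )
  }
  hist_df <- do.call(rbind, rows)
  hist_df <- hist_df[hist_df$read_count > 0, ]
  res <- call_cohort(hist_df, samples)
  expect_equal(nrow(res$calls), 20L)
  for (i in sample(nrow(res$calls), 8L)) {
    row <- res$calls[i, ]
    sub <- hist_df[hist_df$sample == row$sample & hist_df$locus_key == row$locus_key, ]
    tc <- setNames(sub$read_count[sub$tissue == "tumor"],
                   sub$repeat_count[sub$tissue == "tumor"])
    nc <- setNames(sub$read_count[sub$tissue == "normal"],
                   sub$repeat_count[sub$tissue == "normal"])
    ref <- test_locus(make_hist(row$locus_key, row$sample, "tumor", tc),
                      make_hist(row$locus_key, row$sample, "normal", nc))
    expect_equal(row$p_value, ref$p_value)
    expect_equal(row$unstable, ref$unstable)
  }
  # profiles partition the calls by sample
  expect_equal(sum(vapply(res$profiles, `[[`, integer(1), "raw_event_count")),
               sum(res$calls$unstable))
})
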