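# Recurrent panel derivation, burden scoring and the four-way
# MSI-H / MSI-L / MSS / EXCLUDED classification.

test_that("panel keeps loci supported by at least min_samples distinct samples", {
  profs <- c(
    lapply(1:3, function(i) make_profile(paste0("A", i), "glioma", "L1")),
    lapply(1:5, function(i) make_profile(paste0("B", i), "melanoma", "L2"))
  )
  panel5 <- build_panel(profs, min_samples = 5)
  expect_equal(panel5$loci, "L2")        # L1 has support 3 < 5
  panel3 <- build_panel(profs, min_samples = 3)
  expect_equal(panel3$loci, c("L1", "L2"))
  expect_error(build_panel(profs, min_samples = 0), ">=")
})

test_that("excluded histotypes contribute no panel support but are still scored", {
  profs <- c(
    lapply(1:6, function(i) make_profile(paste0("B", i), "b_cell_lymphoma", c("L1", "L2"))),
    lapply(1:5, function(i) make_profile(paste0("M", i), "melanoma", "L2"))
  )
  with_bcl <- build_panel(profs, min_samples = 5)
  expect_equal(with_bcl$loci, c("L1", "L2"))
  without_bcl <- build_panel(profs, min_samples = 5,
                             excluded_histotypes = "b_cell_lymphoma")
  expect_equal(without_bcl$loci, "L2")   # L1 carried only by the excluded histotype
  # brute-force recount
  support <- table(unlist(lapply(profs[7:11], `[[`, "raw_unstable")))
  expect_equal(unname(without_bcl$support["L2"]), unname(as.integer(support["L2"])))
  # excluded-histotype samples still receive a burden against the panel
  rec <- msi_burden(profs[[1]], without_bcl)
  expect_equal(rec$burden, 1)            # L2 unstable, panel = {L2}
})

test_that("burden is the exact fraction of affected panel loci", {
  panel <- build_panel(lapply(1:5, function(i) {
    make_profile(paste0("S", i), "x", paste0("L", 1:3))
  }), min_samples = 5)
  expect_equal(length(panel$loci), 3L)
  p0 <- make_profile("Z0", "x", character(0), tested = paste0("L", 1:3))
  expect_equal(msi_burden(p0, panel)$burden, 0)
  pall <- make_profile("Z1", "x", paste0("L", 1:3))
  expect_equal(msi_burden(pall, panel)$burden, 1)
  pone <- make_profile("Z2", "x", "L2", tested = paste0("L", 1:3))
  expect_equal(msi_burden(pone, panel)$burden, 1 / 3)
  empty <- structure(list(loci = character(0), support = integer(0),
                          min_samples = 5, excluded_histotypes = character(0)),
                     class = "recurrent_panel")
  expect_error(msi_burden(pone, empty), "empty")
})

test_that("classification splits at the mean burden of classified samples", {
  rec <- data.frame(
    sample = c("S1", "S2", "S3"), histotype = "x",
    n_recurrent_affected = c(10L, 2L, 3L), panel_size = 100L,
    burden = c(0.10, 0.02, 0.03), raw_event_count = c(10L, 2L, 3L),
    category = NA_character_, stringsAsFactors = FALSE
  )
  out <- classify_cohort(rec)
  expect_equal(out$threshold, 0.05)
  expect_equal(out$records$category, c("MSI-H", "MSI-L", "MSI-L"))
})

test_that("a burden exactly at the threshold is MSI-L (strictly-above rule)", {
  rec <- data.frame(
    sample = c("S1", "S2"), histotype = "x",
    n_recurrent_affected = c(2L, 2L), panel_size = 100L,
    burden = c(0.02, 0.02), raw_event_count = c(2L, 2L),
    category = NA_character_, stringsAsFactors = FALSE
  )
  out <- classify_cohort(rec)
  expect_equal(out$records$category, c("MSI-L", "MSI-L"))
})

test_that("raw events without recurrent loci mean EXCLUDED, never MSS", {
  rec <- data.frame(
    sample = c("S1", "S2", "S3"), histotype = "x",
    n_recurrent_affected = c(5L, 0L, 0L), panel_size = 100L,
    burden = c(0.05, 0, 0), raw_event_count = c(5L, 4L, 0L),
    category = NA_character_, stringsAsFactors = FALSE
  )
  out <- classify_cohort(rec)
  expect_equal(out$records$category, c("MSI-L", "EXCLUDED", "MSS"))
})

test_that("an all-stable cohort classifies as MSS without a threshold error", {
  rec <- data.frame(
    sample = paste0("S", 1:4), histotype = "x",
    n_recurrent_affected = 0L, panel_size = 10L, burden = 0,
    raw_event_count = 0L, category = NA_character_, stringsAsFactors = FALSE
  )
  out <- classify_cohort(rec)
  expect_true(all(out$records$category == "MSS"))
  expect_true(is.na(out$threshold))
})

test_that("categories partition every randomized cohort", {
  set.seed(202)
  for (i in 1:30) {
    n <- sample(5:60, 1)
    loci <- paste0("L", 1:20)
    profs <- lapply(seq_len(n), function(j) {
      raw <- sample(loci, rbinom(1, 20, runif(1, 0, 0.4)))
      make_profile(paste0("S", j), sample(c("a", "b"), 1), raw, tested = loci)
    })
    panel <- build_panel(profs, min_samples = 2)
    if (length(panel$loci) == 0L) next
    out <- classify_cohort(burden_table(profs, panel))
    tab <- table(factor(out$records$category,
                        levels = c("MSI-H", "MSI-L", "MSS", "EXCLUDED")))
    expect_equal(sum(tab), n)
    # invariant cross-checks
    expect_true(all((out$records$category == "MSS") ==
                      (out$records$raw_event_count == 0)))
    expect_true(all((out$records$category == "EXCLUDED") ==
                      (out$records$raw_event_count > 0 &
                         out$records$n_recurrent_affected == 0)))
  }
})

test_that("raising min_samples never enlarges the panel", {
  set.seed(203)
  loci <- paste0("L", 1:30)
  profs <- lapply(1:40, function(j) {
    make_profile(paste0("S", j), "x", sample(loci, rbinom(1, 30, 0.2)))
  })
  sizes <- vapply(1:8, function(k) length(build_panel(profs, k)$loci), integer(1))
  expect_true(all(diff(sizes) <= 0))
  # k = 1 panel equals the union of all raw event sets
  expect_equal(build_panel(profs, 1)$loci,
               sort(unique(unlist(lapply(profs, `[[`, "raw_unstable")))))
})

test_that("adding a panel locus to a sample never lowers burden or demotes it", {
  set.seed(204)
  profs <- lapply(1:10, function(j) {
    make_profile(paste0("S", j), "x", sample(paste0("L", 1:10), 5))
  })
  panel <- build_panel(profs, min_samples = 2)
  rec <- classify_cohort(burden_table(profs, panel))
  thr <- rec$threshold
  for (j in 1:5) {
    p <- profs[[j]]
    extra <- setdiff(panel$loci, p$raw_unstable)
    if (length(extra) == 0L) next
    p2 <- make_profile(p$sample, p$histotype, c(p$raw_unstable, extra[1]))
    b1 <- msi_burden(p, panel); b2 <- msi_burden(p2, panel)
    expect_gte(b2$burden, b1$burden)
    # with the threshold held fixed the category can only move toward MSI-H
    cat1 <- if (b1$burden > thr) "MSI-H" else "MSI-L"
    cat2 <- if (b2$burden > thr) "MSI-H" else "MSI-L"
    expect_false(cat1 == "MSI-H" && cat2 != "MSI-H")
  }
})

test_that("burden tables round-trip through the TSV writer", {
  rec <- data.frame(
    sample = c("S1", "S2"), histotype = c("x", "y"),
    n_recurrent_affected = c(5L, 0L), panel_size = 100L,
    burden = c(0.05, 0), raw_event_count = c(5L, 0L),
    category = c("MSI-L", "MSS"), stringsAsFactors = FALSE
  )
  path <- tmpfile()
  write_burden(rec, path)
  back <- read_burden(path)
  expect_equal(back$burden, rec$burden)
  expect_equal(back$category, rec$category)
  expect_equal(back$burden_pct, 100 * rec$burden)
})
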