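# Variant normalization, majority voting, PON filtering and VCF IO.

test_that("normalization trims suffix/prefix and keeps the indel anchor", {
  v <- normalize_variant("chr1", 100, "A", "G")
  expect_equal(v[c("pos", "ref", "alt")], list(pos = 100L, ref = "A", alt = "G"))

  v <- normalize_variant("chr1", 100, "AT", "GT")
  expect_equal(v[c("pos", "ref", "alt")], list(pos = 100L, ref = "A", alt = "G"))

  # multi-base padding on both sides of a SNV
  v <- normalize_variant("chr1", 100, "CCAG", "CCTG")
  expect_equal(v[c("pos", "ref", "alt")], list(pos = 102L, ref = "A", alt = "T"))

  expect_error(normalize_variant("chr1", 100, "AT", "AT"),
               class = "msiburden_null_variant")
})

test_that("indels left-align to the leftmost equivalent representation", {
  # deletion inside an A-run: ...C AAAA T...
  refseq <- c(chr1 = "GGCAAAATGG")
  v <- normalize_variant("chr1", 5, "AA", "A", reference = refseq)
  expect_equal(v$pos, 3L)
  expect_equal(v$ref, "CA")
  expect_equal(v$alt, "C")

  # idempotence
  v2 <- normalize_variant("chr1", v$pos, v$ref, v$alt, reference = refseq)
  expect_equal(v2[c("pos", "ref", "alt")], v[c("pos", "ref", "alt")])

  # random repeat-context indels agree with the exhaustive shift oracle
  set.seed(77)
  for (i in 1:40) {
    ctx <- paste0(random_dna(10), strrep(random_dna(sample(1:2, 1)), sample(3:8, 1)),
                  random_dna(10))
    n <- nchar(ctx)
    p <- sample(5:(n - 6), 1L)
    del_len <- sample(1:2, 1L)
    ref <- substr(ctx, p, p + del_len)
    alt <- substr(ctx, p, p)
    if (ref == alt) next
    v <- normalize_variant("c", p, ref, alt, reference = c(c = ctx))
    expect_equal(v$pos, oracle_leftmost_pos(ctx, p, ref, alt),
                 info = sprintf("ctx=%s p=%d ref=%s alt=%s", ctx, p, ref, alt))
    # equivalence: applying the normalized variant reproduces the edit
    apply_var <- function(pp, rr, aa) paste0(substr(ctx, 1, pp - 1), aa,
                                             substr(ctx, pp + nchar(rr), n))
    expect_equal(apply_var(v$pos, v$ref, v$alt), apply_var(p, ref, alt))
  }
})

test_that("majority vote keeps >= 2/3 variants and records full support", {
  a <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L), ref = "A",
                  alt = "G", stringsAsFactors = FALSE)
  b <- a[1:2, ]
  c <- a[1, , drop = FALSE]
  out <- consensus_vote(list(caller_A = a, caller_B = b, caller_C = c))
  expect_equal(out$pos, c(10L, 20L))                 # pos 30 seen once only
  expect_equal(out$callers, c("caller_A,caller_B,caller_C", "caller_A,caller_B"))
  expect_equal(out$n_callers, c(3L, 2L))
})

test_that("consensus equals brute-force key counting on random call-sets", {
  set.seed(99)
  for (i in 1:60) {
    cs <- list(caller_A = random_variants(sample(0:20, 1)),
               caller_B = random_variants(sample(0:20, 1)),
               caller_C = random_variants(sample(0:20, 1)))
    cs <- lapply(cs, function(df) df[!duplicated(paste(df$chrom, df$pos, df$ref, df$alt)), ])
    for (k in 1:3) {
      got <- consensus_vote(cs, min_callers = k)
      expect_equal(sort(got$key), oracle_consensus_keys(cs, k), info = paste("set", i, "k", k))
    }
    # k = 1 is the union; k = 3 the triple intersection; sizes are nested
    n1 <- nrow(consensus_vote(cs, 1)); n2 <- nrow(consensus_vote(cs, 2))
    n3 <- nrow(consensus_vote(cs, 3))
    expect_true(n3 <= n2 && n2 <= n1)
    expect_equal(n1, length(oracle_consensus_keys(cs, 1)))
  }
})

test_that("voting is invariant under permuting call-sets and rows", {
  set.seed(101)
  cs <- list(caller_A = random_variants(15), caller_B = random_variants(15),
             caller_C = random_variants(15))
  cs <- lapply(cs, function(df) df[!duplicated(paste(df$chrom, df$pos, df$ref, df$alt)), ])
  base <- consensus_vote(cs)
  perm <- list(caller_A = cs$caller_A[sample(nrow(cs$caller_A)), ],
               caller_B = cs$caller_B[sample(nrow(cs$caller_B)), ],
               caller_C = cs$caller_C[sample(nrow(cs$caller_C)), ])
  expect_equal(sort(consensus_vote(perm)$key), sort(base$key))
  swapped <- cs[c(2, 3, 1)]  # same caller names attached to same sets
  expect_equal(sort(consensus_vote(swapped)$key), sort(base$key))
})

test_that("duplicate records within one caller deduplicate with a warning", {
  a <- data.frame(chrom = "chr1", pos = c(10L, 10L), ref = "A", alt = "G",
                  stringsAsFactors = FALSE)
  expect_warning(
    out <- consensus_vote(list(caller_A = a, caller_B = a[1, ],
                               caller_C = a[0, ])),
    "duplicate"
  )
  expect_equal(nrow(out), 1L)
  expect_equal(out$n_callers, 2L)
})

test_that("PON filtering is exact-key set difference with an audit trail", {
  set.seed(111)
  v <- random_variants(10)
  v <- v[!duplicated(paste(v$chrom, v$pos, v$ref, v$alt)), ]
  v$key <- paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

  none <- apply_pon(v, panel_of_normals(character(0)))
  expect_equal(none$variants$key, v$key)
  expect_equal(nrow(none$removed), 0L)

  all_in <- apply_pon(v, panel_of_normals(v))
  expect_equal(nrow(all_in$variants), 0L)
  expect_true(all(all_in$removed$in_pon))

  pick <- v$key[sample(nrow(v), 3L)]
  some <- apply_pon(v, panel_of_normals(pick))
  expect_equal(sort(some$removed$key), sort(pick))
  expect_equal(sort(some$variants$key), sort(setdiff(v$key, pick)))
})

test_that("variant tables round-trip through the VCF writer and vcfR reader", {
  set.seed(121)
  v <- random_variants(12, max_pos = 500L)
  v <- v[!duplicated(paste(v$chrom, v$pos, v$ref, v$alt)), ]
  v$effect <- sample(c("nonsynonymous", "synonymous", "noncoding"),
                     nrow(v), replace = TRUE)
  path <- tmpfile(fileext = ".vcf")
  write_vcf(v, path)
  back <- read_caller_vcf(path)
  ord <- order(v$chrom, v$pos, v$ref, v$alt)
  expect_equal(back$chrom, v$chrom[ord])
  expect_equal(back$pos, v$pos[ord])
  expect_equal(back$ref, v$ref[ord])
  expect_equal(back$alt, v$alt[ord])
  expect_equal(back$effect, v$effect[ord])
})

test_that("multi-allelic VCF records split into one normalized row per allele", {
  path <- tmpfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=EFF,Number=1,Type=String,Description=\"effect\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\t.\tA\tG,T\t.\tPASS\tEFF=nonsynonymous,synonymous",
    "chr1\t200\t.\tCT\tC\t.\tPASS\tEFF=noncoding"
  ), path)
  v <- read_caller_vcf(path)
  expect_equal(nrow(v), 3L)
  expect_equal(v$alt[v$pos == 100], c("G", "T"))
  expect_equal(v$effect[v$pos == 100], c("nonsynonymous", "synonymous"))
  expect_equal(v$ref[v$pos == 200], "CT")
})
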