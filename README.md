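# msiburden

Cohort-level microsatellite-instability (MSI) analysis for paired
tumor–normal exome cohorts, written for comparative-oncology settings
(the defaults model a ten-histotype canine pan-cancer cohort) but
generic over any cohort with matched tumor/normal repeat-length data.

Microsatellites are 1–5 bp tandem repeats prone to replication
slippage; under mismatch-repair deficiency their lengths mutate
somatically. `msiburden` turns that signal into a per-sample score and
a cohort classification:

1. **Scan** a reference FASTA for microsatellite loci (maximal perfect
   tandem runs, primitive motifs, configurable minimum copy numbers).
2. **Call** each locus per sample: a chi-square homogeneity test of the
   tumor vs. matched-normal repeat-length read histograms (low-count
   bins pooled, coverage-gated), unstable iff p ≤ α.
3. **Merge** somatic SNV/indel call-sets from three callers by majority
   vote (≥ 2 of 3, on normalized left-aligned alleles) and remove
   Panel-of-Normals artifacts.
4. **TMB**: coding mutations per megabase (default 57 Mb exome target;
   mitochondrial/unplaced contigs excluded).
5. **Burden**: keep loci unstable in ≥ k samples (the recurrent panel,
   default k = 5), score each sample as

   `burden = |unstable loci ∩ panel| / |panel|`

   and classify: **MSS** (no events), **EXCLUDED** (only
   patient-specific events), **MSI-H** (burden strictly above the
   cohort mean of classifiable samples) or **MSI-L** (otherwise).
6. **Statistics**: pairwise Mann–Whitney comparisons of mutation counts
   and TMB across categories, Pearson correlation and OLS regression of
   TMB on burden (both r and R² reported), per-histotype summaries.

A seeded synthetic-cohort generator plants ground truth for every stage
(instability rates spanning orders of magnitude across histotypes, a
linear burden–TMB coupling, three imperfect callers with a contaminated
PON), so the whole pipeline is testable end to end.

## Worked example

Generate a desk-scale synthetic cohort (139 samples, 10 histotypes,
200 panel + 100 background loci) and run every stage on the written
files:

```r
library(msiburden)

cfg <- sim_config(seed = 7, scale = 0.2)
sim <- generate_synthetic_cohort(cfg, dir = "sim")

report <- run_pipeline(list(
  out_dir    = "sim/run",
  reference  = "sim/reference.fa",
  histograms = "sim/histograms.tsv",
  samples    = "sim/samples.tsv",
  callers    = c(caller_A = "sim/caller_A.tsv",
                 caller_B = "sim/caller_B.tsv",
                 caller_C = "sim/caller_C.tsv"),
  pon        = "sim/pon.tsv",
  min_samples = 2      # recurrence threshold at one-fifth cohort scale
))
#> [scan] 300 microsatellite loci
#> [call] 41700 sample-locus tests, 1048 unstable
#> [consensus] 7586 consensus variants (443 removed by PON)
#> [tmb] median TMB 0.544 mutations/Mb
#> [burden] panel 200 loci; threshold 0.0462; H/L/S/X = 21/91/25/2
#> [report] written to sim/run/report.json
```

The burden table ranks samples by their MSI score; B-cell lymphomas,
generated with the highest instability rate, dominate the MSI-H class:

```r
b <- read_burden("sim/run/burden.tsv")
head(b[order(-b$burden_pct),
       c("sample", "histotype", "burden_pct", "raw_event_count", "category")], 5)
#>    sample       histotype burden_pct raw_event_count category
#> 71   S071 b_cell_lymphoma       25.5              51    MSI-H
#> 58   S058 b_cell_lymphoma       25.0              50    MSI-H
#> 70   S070 b_cell_lymphoma       23.5              47    MSI-H
#> 73   S073 b_cell_lymphoma       23.5              47    MSI-H
#> 65   S065 b_cell_lymphoma       21.5              44    MSI-H
```

`burden_pct` is the percentage of the 200-locus recurrent panel that is
unstable in that sample; `raw_event_count` counts all unstable loci
including patient-specific ones; the classification threshold (4.6%
here — the mean burden of samples with at least one recurrent event) and
the category tally are in the report. The statistics report links the
score to mutational load:

```r
report$stats$burden_tmb[c("pearson_r", "r_squared", "slope", "p_value")]
#> burden~TMB: r = 0.876 (R^2 = 0.768), p = 1.16e-44, slope = 8.117
```

i.e. each percentage point of MSI burden adds ~0.08 mutations/Mb in
this cohort — the generator planted a slope of 8 per unit burden, which
the pipeline recovers. MSI-H samples carry a median TMB of ~1.9
mutations/Mb against ~0.5 for MSS, and the pairwise rank-sum tests in
`report$stats$tmb_wilcoxon` separate all three categories.

Each stage is also exposed individually (`scan_reference()`,
`call_cohort()`, `consensus_vote()`, `tmb_by_sample()`,
`build_panel()`, `classify_cohort()`, `cohort_stats_report()`), and a
command-line wrapper with per-stage subcommands ships at
`inst/cli/msiburden`:

```sh
msiburden scan --reference ref.fa --out sites.tsv
msiburden run-all --config run.yaml
```

## Layout

```
R/                  implementation (scan, instability, consensus, tmb,
                    burden, stats, simulate, pipeline, cli)
tests/testthat/     unit + property tests with independent oracles
scripts/acceptance.R   end-to-end reproduction script
vignettes/          methods vignette (model, assumptions, design choices)
inst/cli/msiburden  thin Rscript command-line wrapper
inst/extdata/       published cohort-composition fixture (TSV)
```
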