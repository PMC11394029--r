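Package: msiburden
Title: Microsatellite Instability Burden Scoring for Paired Tumor-Normal Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cohort-level microsatellite instability (MSI) analysis for
    paired tumor-normal exome cohorts. Discovers candidate microsatellite
    loci in a reference FASTA, tests per-locus tumor versus matched-normal
    repeat-length histograms for somatic instability, merges somatic
    call-sets from three variant callers by majority vote with
    Panel-of-Normals filtering, computes tumor mutational burden per
    megabase, derives a recurrence-filtered locus panel, scores each
    sample's MSI burden, classifies samples as MSI-H, MSI-L or MSS against
    the cohort mean, and runs the associated statistical battery (rank-sum
    comparisons, Pearson correlation, linear regression). A seeded
    synthetic-cohort generator with planted ground truth supports
    end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
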