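---
title: "Methods: cohort-level microsatellite-instability burden scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort-level microsatellite-instability burden scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msiburden)
```

## The problem

Microsatellites — tandem repeats of 1–5 bp motifs — are prone to
replication slippage; when mismatch repair is deficient, repeat-length
mutations accumulate and a tumor becomes microsatellite-unstable (MSI).
In paired tumor–normal exome cohorts, MSI can be read out per locus by
comparing the distribution of repeat lengths supported by tumor reads
against the matched normal. `msiburden` implements that readout at
cohort scale: locus discovery in a reference, per-locus instability
calls, a recurrence-filtered locus panel, a per-sample **MSI-burden
score** (the fraction of panel loci unstable in that sample), a
three-way MSI-H / MSI-L / MSS classification against the cohort mean,
and the statistics that connect the score to somatic mutation load and
tumor mutational burden (TMB). A seeded synthetic-cohort generator
provides planted ground truth for every stage.

## Locus discovery

`scan_sequence()` reports all maximal perfect tandem runs of primitive
1–5 bp motifs. Coordinates are 0-based half-open (BED convention), so
`end - start = unit_len * ref_repeats` holds exactly; conversion to
1-based happens only at VCF boundaries. Three rules make the output
deterministic and unambiguous:

* **Primitive units.** A run of `ATAT` units is reported once, as `AT`.
  Motifs are canonicalized to the lexicographically smallest rotation of
  their primitive form (`canonical_motif()`), so locus identity does not
  depend on reading frame.
* **Overlap resolution.** When candidate runs overlap (common in
  two-letter contexts such as `...AAAAATATATAT...`), the longer total
  run wins; ties go to the smaller unit length (favoring informative
  homopolymers), then to the smaller start.
* **N handling.** Runs never cross an `N`; a repeat count across an
  undetermined base would be undefined.

Default minimum copy numbers are 10 (homopolymers), 5 (dinucleotide)
and 4 (3–5 bp motifs) — the common scan settings of msisensor-style
tools; they are configurable per unit length. The scanner is validated
against a brute-force enumerator that tests every (start, unit-length)
pair positionally.

Only the reference strand is scanned, without reverse-complement
canonicalization: the downstream tumor/normal comparison operates on
repeat-length histograms, which are strand-symmetric.

## The instability test

For one locus in one sample, `test_locus()` compares the tumor and
normal repeat-length read histograms with a two-sided chi-square
homogeneity test over the union of observed repeat lengths. Two
numerical safeguards matter:

* **Pooling.** Bins whose expected count falls below 5 are merged into
  their numerically nearest neighboring repeat length (ties prefer the
  larger bin, then the left). If a single bin remains, the two tissues
  are indistinguishable at this coverage and p = 1. This keeps the
  chi-square approximation honest, at the price of making the test
  deliberately conservative on histograms that are tightly concentrated
  at one repeat length — a design feature: isolated stutter reads never
  drive a somatic call.
* **Coverage gate.** If either tissue has fewer than `min_cov` reads
  (default 20), the locus is not assessable and is reported stable with
  p = 1 and an explicit reason. Lowering `min_cov` can therefore only
  add calls, never remove them.

A locus is unstable iff p ≤ alpha (default 0.05), applied per locus
with no multiple-testing correction — the flat significance rule used
in cohort MSI scoring; Benjamini–Hochberg correction across loci within
a sample is available behind the `fdr` flag but off by default. The test
is symmetric in the two tissues: no somatic direction is inferred,
matching the presence/absence treatment of instability events
downstream. Calibration is verified on simulated null loci drawn from a
spread multinomial (expected bin counts ≥ 15 at coverage 100), where
the rejection rate must sit inside tight binomial bounds around alpha;
concentrated null histograms reject far *less* often than alpha because
of the pooling rule, which is the intended asymmetry.

Tumor-only mode is not implemented: a matched normal from the same
animal is a precondition of the design.

## Variant consensus, PON and TMB

Somatic call-sets from three callers are merged at the site/allele
level: a variant is trustworthy iff called by at least 2 of 3 callers.
Variant identity must be caller-independent, so every record is
normalized first — common suffix then prefix trimmed (keeping the
mandatory anchor base for indels) and indels left-aligned against the
reference to their leftmost equivalent representation; genotype and
quality fields play no role. Whether published pipelines vote on raw or
normalized representations is usually unstated; normalizing before
voting is this package's choice, since un-normalized voting silently
splits equivalent indels. Multi-allelic records are split before
normalization.

The Panel of Normals is an exact-key blacklist of variants observed in
the cohort's normal tissues; `apply_pon()` removes hits and keeps them
as a flagged audit table rather than discarding them silently. No
position-window fuzziness is applied — exact keys are deterministic and
testable, and left-alignment already collapses representational
variation.

TMB is coding mutations per megabase: variants with effect class
`nonsynonymous` or `synonymous` (coding indels carry the same labels),
excluding the mitochondrial contig and unplaced/unaligned contig names,
divided by the sequenced coding size — 57 Mb by default, the canine
exome target estimate, configurable per cohort. Counting synonymous
variants in the numerator mirrors the downstream category comparisons,
which tally both classes; a switch restricts to nonsynonymous-only.
Effect classes are read from an input column or a configurable VCF INFO
tag; functional annotation itself is out of scope.

## Panel, burden and classification

`build_panel()` keeps loci called unstable in at least `min_samples`
distinct samples (support counts samples, not events; default k = 5).
Histotypes whose event load would swamp the panel can be excluded from
support counting — in the motivating cohort that was B-cell lymphoma —
but excluded-histotype samples are still scored against the final
panel. The panel is anti-monotone in k by construction.

Each sample's burden is `|unstable ∩ panel| / |panel|`. Classification
(`classify_cohort()`) is four-way:

* **MSS** — no raw instability events at all;
* **EXCLUDED** — raw events but none on the recurrent panel
  (patient-specific instability only); these samples are kept in the
  output as a first-class category so the audit trail survives, but
  they take no part in the threshold;
* **MSI-H / MSI-L** — among the remaining ("classifiable") samples,
  burden strictly above the cohort-mean threshold is MSI-H, otherwise
  MSI-L. A burden exactly at the mean is MSI-L ("above" is strict).

The threshold population is a genuinely open design point: averaging
over all samples (zero-inflated) or only over classifiable ones gives
different thresholds. The default is the mean over classifiable
samples — consistent with applying categories after removing
patient-specific-only samples, and with a reported cohort-mean
threshold (2.4% in the motivating study) that is far above what
zero-inflated averaging over the full cohort would give.
`threshold_population = "all"` selects the other convention; neither
claims to reproduce the published threshold exactly, since the
underlying per-locus calls are not reproducible from the publication.
A cohort in which no sample has a recurrent event classifies everyone
MSS/EXCLUDED with an `NA` threshold rather than erroring.

## Statistics

Category comparisons of somatic mutation counts and TMB use the
unpaired two-sample Mann–Whitney rank-sum test ("Wilcoxon" in the
source literature; the compared categories are disjoint sample groups),
two-sided, exact when both groups have ≤ 25 observations and no ties,
normal approximation with tie and continuity correction otherwise —
i.e. the documented behavior of `stats::wilcox.test()`, validated here
against full enumeration for all group sizes with n₁ + n₂ ≤ 12. The
three pairwise tests are reported uncorrected, matching the flat
p ≤ 0.05 rule of the motivating analysis; Holm correction is a caller
option on the returned table. Quartile summaries use linear
interpolation between order statistics (quantile type 7), stated in the
report metadata.

The burden–TMB association reports the Pearson correlation with its
two-sided t-test p-value, the OLS regression of TMB on burden, and
*both* r and R²: published reports of the form "R = 0.03, p = 0.007"
are ambiguous between the two (at n ≈ 430, r = 0.03 would not be
significant at p = 0.007), and the report deliberately takes no
position. Zero variance in either variable yields a not-computable
result instead of an error.

## The synthetic cohort

`generate_synthetic_cohort()` stands in for the real whole-exome
cohort, which is out of scope. It emulates the statistical structure
the analysis assumes, with every default chosen up front as the study
condition:

* **Cohort template** (`default_histotypes()`): ten histotypes with
  sample counts 137, 136, 103, 98, 65, 64, 52, 28, 5, 4 at full scale
  and a 0.2× desk scale (139 samples) for routine runs. Per-locus
  instability rates span the reported orders of magnitude — 0.192 for
  B-cell lymphoma down to 0.0005 for T-cell lymphoma, with the other
  histotypes between 0.002 and 0.027 — so that per-histotype median
  burdens land in the published range (≈19% down to ≈0.05%).
* **Reference** : 200 shared "panel" loci plus 100 background loci
  planted at known coordinates on four chromosomes, with flanking
  sequence constructed (and verified by re-scanning) so the scanner
  recovers exactly the planted site list.
* **Histograms**: coverage Poisson(100) per tissue; reads concentrated
  at the true repeat count with a symmetric one-unit stutter kernel
  (probability 0.01 per side per read); unstable tumor loci are
  contracted by 3 repeat units (repeat loss dominates MSI biology).
* **Events**: panel loci become unstable with the histotype rate;
  background loci with a patient-specific rate of 0.001, producing the
  EXCLUDED category.
* **TMB coupling**: TMB = 0.42 + 8 × burden + N(0, 0.35), truncated at
  0. The base and slope reproduce the published medians (MSS ≈ 0.42,
  MSI-H ≈ 2 mutations/Mb); the implied population correlation is
  available in closed form (`coupling_target_r()`), and
  `coupling_noise_for_r()` inverts it when a specific target (e.g.
  r = 0.3) is wanted.
* **Callers**: three callers with sensitivities 0.95 / 0.90 / 0.85,
  independent per variant; per-caller false positives; systematic
  artifact sites seen by all callers, 80% of which are present in the
  Panel of Normals. With sensitivities (0.9, 0.9, 0.9) and no false
  calls, consensus recall has the closed form 3·0.9²·0.1 + 0.9³ =
  0.972, which the vote must reproduce empirically.

At the 0.2× scale the recurrence threshold is `min_samples = 2` rather
than the full-scale 5: the full-scale rule demands recurrence in ~0.7%
of 692 samples, and 5 of 139 would be disproportionately strict, while
1 of 139 would make every shared event "recurrent". Two samples is the
smallest k that still requires independent recurrence across animals;
the full-scale default of the pipeline remains 5.

**What the generator does *not* emulate** — and hence what passing
tests do not show about real data: read-level artifacts (alignment
error, PCR duplicates), heavy PCR stutter at long homopolymers (real
stutter can reach 5–15% per flanking length, far above the 0.01 default;
at such noise the per-locus false-positive rate approaches alpha and
burden estimates inflate accordingly, which is why the `fdr` flag
exists), interrupted/imperfect repeats, locus-specific coverage bias,
breed structure, and realistic mutational signatures. The generator
demonstrates estimator correctness under clean conditions, not
robustness to every failure mode of exome data.

## Problem sizes and determinism

Routine validation runs use the 0.2× cohort (139 samples, 300 loci,
~42,000 locus tests per run) over 10 seeds, 500 random sequences for
the scanner oracle, 10,000 simulated null loci for test calibration,
and n = 500 draws for the correlation-recovery check — sizes at which
every check completes in minutes on one core while keeping Monte-Carlo
error well below the asserted tolerances. All generators are seeded;
the pipeline itself contains no randomness, and rerunning any stage on
identical inputs produces byte-identical outputs (verified by checksum
in the run report).

## Known limitations

* Per-locus agreement with any specific external MSI caller is not a
  goal; the instability test is a documented, exactly-testable
  chi-square procedure, not a reimplementation of a particular tool.
* Repeats with unit length > 5 and interrupted repeats are out of
  scope.
* Repeat histograms are consumed as pre-tabulated TSV; extracting them
  from BAM pileups is a plausible adapter but not part of the package.
* The EXCLUDED/MSS boundary depends on the per-locus false-positive
  rate: on noisy real data a truly stable sample can acquire a stray
  call and move from MSS to EXCLUDED. The audit columns
  (`raw_event_count`, `n_recurrent_affected`) make this visible.
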