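---
title: "Multi-tier germline variant interpretation with mtier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-tier germline variant interpretation with mtier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtier)
```

`mtier` interprets germline variants called from a targeted cancer-gene
panel across a patient cohort. This vignette documents the model, the
statistical procedures, the synthetic data generator used for validation,
and the design decisions that are this package's own choices rather than
community standards.

## 1. Variant identity

Annotation sources spell the same indel differently. `normalize_variant()`
reduces each (chrom, pos, ref, alt) record to its minimal event: the shared
suffix is trimmed, then the shared prefix, allowing either allele to become
empty; the key is `chrom:pos:ref:alt` with `-` standing for an empty allele,
and a leading `chr` on the chromosome is dropped. The returned `ref`/`alt`
columns keep a VCF-valid (non-empty, anchored) spelling, while the key is
fully reduced, so `(100, CTT, CT)` and `(101, TT, T)` — two spellings of
deleting one T from a homopolymer — share the key `1:101:T:-`.

```{r}
normalize_variant("1", 100, "CTT", "CT")$key
normalize_variant("1", 101, "TT", "T")$key
```

This is context-free trimming only; left-alignment against a genome FASTA is
out of scope because the synthetic data never requires it. Multi-allelic VCF
rows are split into per-alternate dosage columns (`split_multiallelic()`),
with missing genotypes kept as `NA` and excluded from allele-number
denominators downstream.

## 2. Six-class significance calling

Evidence per variant is joined from five snapshots: ClinVar and HGMD
(germline assertions), COSMIC and TCGA (somatic observations), gnomAD
(population frequency only — presence in gnomAD is *not* an assertion).
Terms are recoded onto `{P, VUS, B, OTHER}`:

* ClinVar: pathogenic/likely-pathogenic spellings → `P`; benign spellings →
  `B`; uncertain significance and conflicting interpretations → `VUS`;
  `risk_factor`/`drug_response` → `OTHER`; unrecognized terms → no
  assertion, with a warning.
* HGMD: `DM`, `DM?`, `DFP` → `P`; `DP`, `FP` → `VUS`; retired (`R`) records
  are ignored.

The decision order is then:

1. No record in any assertion database → `NOVEL_VUS`.
2. Somatic record(s) only → `SOMATIC_VUS`.
3. Otherwise, over the germline assertion multiset: any explicit `VUS`, or
   both `P` and `B` present (a conflict) → `REPORTED_VUS`; all `P` (plus
   possibly `OTHER`) → `PATHOGENIC`; all `B` (plus possibly `OTHER`) →
   `BENIGN`; only `OTHER` → `OTHER`.

One deliberate choice: a variant whose only germline records are
uninformative (retired HGMD entries or unrecognized ClinVar terms), with no
somatic record, is treated as having *no assertion* and becomes
`NOVEL_VUS`. The severity order `PATHOGENIC > REPORTED_VUS > NOVEL_VUS >
SOMATIC_VUS > OTHER > BENIGN` (`collapse_severity()`) summarizes a variant
set — e.g. a gene's per-patient label — by its most severe member.

Consequence terms partition into coding (missense, in-frame
insertion/deletion, frameshift, splice donor/acceptor, start/stop changes)
and non-coding (synonymous, intronic, UTR, and notably `splice_region`,
which does not alter protein sequence directly). In-silico scores are
discretized at fixed thresholds (CADD ≥ 30, REVEL > 0.5, SIFT < 0.05,
FATHMM ≤ −1.5, LRT = "D", MetaLR > 0.5; absent → `NG`); they annotate but
never override the database-driven class.

## 3. Enrichment statistics

For a cohort of $N$ diploid patients with complete genotypes, the cohort
allele frequency of a variant with allele count $AC$ is $AC / 2N$. The
enrichment ratio divides it by the reference (gnomAD) frequency; a variant
absent from the reference has an undefined ratio and is flagged
`absent_in_reference` instead. Flags: `private` (exactly one carrier),
`polymorphic` (reference minor-allele frequency ≥ 5%, computed as
$\min(f, 1-f)$), `enriched_2x`/`enriched_10x` (ratio ≥ 2 / ≥ 10),
`depleted_2x` (ratio ≤ 0.5).

The one-sided test for over-representation conditions on both margins: with
$a$ of $n_1$ cohort chromosomes and $b$ of $n_2$ reference chromosomes
carrying the allele, the p-value is the hypergeometric upper tail
$P(X \ge a)$. It is computed from log-gamma pmf terms,

$$\log P(X = k) = \log\binom{K}{k} + \log\binom{N-K}{n_1-k} - \log\binom{N}{n_1},$$

exponentiated and summed, so that gnomAD-scale denominators
($n_2 \approx 2.45\times10^5$) are handled without overflow. The test suite
verifies exact agreement ($|\Delta p| < 10^{-12}$) with an independent
`choose()`-product enumeration over every 2×2 table with grand total ≤ 60,
and agreement with `stats::fisher.test` (to ~$10^{-10}$, the two
implementations differing only in summation order and rounding).

Reference allele counts are reconstructed from printed frequencies as
$\mathrm{round}(f \times AN)$ with a default $AN = 245{,}098$, the
denominator under which a frequency of $4.08\times10^{-6}$ is a singleton.
Raw p-values are reported to match the source analysis style; a
Benjamini-Hochberg column is appended as an extra.

## 4. Patient groups

Each variant receives provenance flags: `G` (any ClinVar/HGMD record), `S`
(any COSMIC/TCGA record), `G_C` (`G` with an attached phenotype curated to
CANCER or CANCER_RISK via the bundled YAML map), and `S_PDAC` (somatic
record with pancreas primary site). Groups are declared in
`inst/extdata/group_predicates.yaml` — 18 defaults — as combinations of a
pathogenicity requirement, a boolean provenance clause (e.g.
`G_C and not S`), a class restriction, a gene set
(`inst/extdata/gene_sets.yaml`; HDR is validated to be a subset of DDR),
and a minimum enrichment ratio. Polymorphic variants never trigger group
membership. A patient joins a group iff they carry at least one qualifying
variant; `assign_groups()` also returns the triggering (patient, group,
variant) table for auditability.

## 5. Outcome comparisons

`compare_clinical()` tests one group against the rest of the cohort:
continuous measures (age; CA19-9, restricted to producers) by Mann-Whitney;
categorical measures by chi-square, switching to Fisher's exact test when
any expected cell count falls below 5 (with simulated p-values for large
sparse tables); overall survival by Kaplan-Meier medians ("not reached"
when the curve stays above 0.5) and a 1-df log-rank test. Subgroup filters
(stage, surgery) restrict the rows before testing; degenerate splits return
no row rather than a spurious p-value. `run_table4()` evaluates the full
group × measure × filter grid, reporting raw p-values plus a BH-adjusted
column.

## 6. The synthetic generator

`sim_config()` defaults encode the emulated study conditions: 538 diploid
patients over a 50-gene panel; class counts at the real cohort's scale
(75 pathogenic, 793 reported VUS, 3,953 novel VUS, 34 somatic VUS, 5 other,
1,101 benign); a reference population of 245,098 chromosomes; planted
enrichment variants mirroring the published susceptibility loci; and
exponential survival with a 22.0 vs 9.8-month median contrast between
pathogenic-variant carriers and the rest (20% censoring). These defaults
are fixed study conditions, not tuning knobs; tests and the bundled demo
use smaller configurations purely for runtime, and those sizes are this
package's own choices.

The generator makes each class recoverable by construction: pathogenic
variants get concordant germline assertions, benign ones benign assertions,
reported VUS an explicit VUS/conflict/DP-FP record, somatic VUS only
COSMIC/TCGA records, novel VUS no assertion records (half are given a
gnomAD frequency, which must not change their class), and "other" variants
only risk-factor/drug-response annotations. Carriers are distributed
independently across patients; survival times are exponential
($\lambda = \ln 2 / \text{median}$), giving a closed-form oracle for
Kaplan-Meier recovery. Three sub-seeds (`seed`, `seed+1`, `seed+2`) drive
snapshots, genotypes, and clinical data, so every artifact is reproducible
from one integer.

Non-goals of the generator: realistic haplotype/LD structure, read-level
simulation, genotype missingness by default (the frequency arithmetic of
the emulated study implies complete genotyping), and the original
amplicon design.

## 7. Validation summary

The test suite (testthat, edition 3) combines worked-example reproduction
— enrichment ratios 91.56 / 28.60 / 5.73 / 1.95, cohort frequencies
9.29×10⁻⁴ / 1.86×10⁻³ / 3.72×10⁻³, Fisher p = 8.7×10⁻³ — with property
tests: key-normalization idempotence, classification purity and partition
conservation, exhaustive Fisher-oracle agreement, log-rank type-I error
calibration in [0.04, 0.06] over 5,000 null simulations, group-containment
invariants (every "X Pathogenic" ⊆ "X"; HDR ⊆ DDR; exclusive provenance
clauses disjoint) over 100 random cohorts, and byte-identical same-seed
pipeline reruns. `scripts/acceptance.R` recomputes these quantities against
the installed package from a single `--seed`.

## 8. Limitations

Classification is only as good as the snapshots: the package harmonizes
assertions, it does not curate them. The CTRC-style situation — a printed
cohort frequency inconsistent with its carrier count (possibly reflecting
homozygotes) — is resolved by computing ratios from printed frequencies
when exact counts are unavailable. The Fisher test treats reference counts
reconstructed from rounded frequencies as exact. Survival modeling is
exponential by design, adequate for calibration oracles but not a clinical
model.
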