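#' Cohort alternate-allele frequency
#'
#' @param cohort_ac alternate allele count(s) in the cohort.
#' @param n_patients number of (fully genotyped, diploid) patients.
#' @return cohort_ac / (2 * n_patients).
#' @export
cohort_af <- function(cohort_ac, n_patients) {
  if (length(n_patients) != 1L || n_patients <= 0) {
    stop("n_patients must be a single positive count")
  }
  if (any(cohort_ac < 0) || any(cohort_ac > 2 * n_patients)) {
    stop("cohort_ac must lie in [0, 2*n_patients]")
  }
  cohort_ac / (2 * n_patients)
}

#' Enrichment/depletion ratio of cohort vs reference allele frequency
#'
#' @param caf cohort allele frequency (>= 0).
#' @param ref_af reference-population allele frequency; NA when the variant
#'   is absent from the reference.
#' @return caf / ref_af when ref_af > 0; NA (absent in reference; the flag is
#'   reported separately) when ref_af is 0 or NA.
#' @export
af_ratio <- function(caf, ref_af) {
  ifelse(is.na(ref_af) | ref_af <= 0, NA_real_, caf / ref_af)
}

# log hypergeometric pmf: P(X = k) drawing n alleles from N with K successes
.lhyper <- function(k, K, N, n) {
  lgamma(K + 1) - lgamma(k + 1) - lgamma(K - k + 1) +
    lgamma(N - K + 1) - lgamma(n - k + 1) - lgamma(N - K - n + k + 1) -
    (lgamma(N + 1) - lgamma(n + 1) - lgamma(N - n + 1))
}

#' One-sided Fisher exact test for allele-count enrichment
#'
#' Exact hypergeometric upper-tail probability P(X >= cohort_ac) for the 2x2
#' allele-count table [[cohort_ac, cohort_an - cohort_ac],
#' [ref_ac, ref_an - ref_ac]], i.e. the one-sided test for greater occurrence
#' in the cohort. The tail is summed from a log-gamma pmf so it stays exact
#' to machine precision at reference-population allele numbers in the
#' hundreds of thousands. All arguments are vectorized.
#'
#' @param cohort_ac,cohort_an cohort alternate allele count and allele number.
#' @param ref_ac,ref_an reference alternate allele count and allele number.
#' @return p-value(s) in (0, 1].
#' @export
fisher_greater <- function(cohort_ac, cohort_an, ref_ac, ref_an) {
  m <- cbind(cohort_ac, cohort_an, ref_ac, ref_an)
  if (any(is.na(m))) stop("counts must be non-missing")
  if (any(m < 0) || any(cohort_ac > cohort_an) || any(ref_ac > ref_an)) {
    stop("counts must be non-negative with ac <= an")
  }
  if (any(cohort_an == 0) || any(ref_an == 0)) {
    stop("allele numbers must be positive")
  }
  vapply(seq_len(nrow(m)), function(i) {
    a <- m[i, 1]; an1 <- m[i, 2]; b <- m[i, 3]; an2 <- m[i, 4]
    N <- an1 + an2
    K <- a + b
    ks <- seq.int(a, min(an1, K))
    if (a == 0) return(1)
    min(1, sum(exp(.lhyper(ks, K, N, an1))))
  }, numeric(1))
}

#' Reconstruct reference allele counts from a printed frequency
#'
#' Rebuilds integer (AC, AN) pairs from a published allele frequency under an
#' assumed total allele number, as needed to turn printed population
#' frequencies back into countable tables.
#'
#' @param ref_af allele frequency in [0, 1].
#' @param assumed_an assumed reference allele number (>= 1).
#' @return data.frame with columns `ac` (= round(ref_af * assumed_an)) and
#'   `an`.
#' @export
reconstruct_ref_counts <- function(ref_af, assumed_an) {
  if (any(ref_af < 0) || any(ref_af > 1)) stop("ref_af must be in [0, 1]")
  if (any(assumed_an < 1)) stop("assumed_an must be >= 1")
  data.frame(ac = round(ref_af * assumed_an), an = assumed_an)
}

#' Flag a variant as private / polymorphic / enriched / depleted
#'
#' PRIVATE: carried by exactly one patient. POLYMORPHIC: reference minor
#' allele frequency >= 0.05 (boundary inclusive). ENRICHED_2X / ENRICHED_10X:
#' frequency ratio >= 2 / >= 10. DEPLETED_2X: ratio <= 0.5.
#' ABSENT_IN_REFERENCE: no reference frequency available.
#'
#' @param carriers number of patients carrying >= 1 alternate allele.
#' @param ref_maf reference minor allele frequency (NA if absent).
#' @param ratio frequency ratio (NA if absent in reference).
#' @return data.frame of logical flag columns private, polymorphic,
#'   enriched_2x, enriched_10x, depleted_2x, absent_in_reference.
#' @export
flag_variant <- function(carriers, ref_maf, ratio) {
  data.frame(
    private = carriers == 1,
    polymorphic = !is.na(ref_maf) & ref_maf >= 0.05,
    enriched_2x = !is.na(ratio) & ratio >= 2,
    enriched_10x = !is.na(ratio) & ratio >= 10,
    depleted_2x = !is.na(ratio) & ratio <= 0.5,
    absent_in_reference = is.na(ratio)
  )
}

#' Per-variant allele-enrichment table
#'
#' Computes cohort allele frequencies from the dosage matrix, joins reference
#' (gnomAD-style) frequencies, forms the enrichment/depletion ratio, runs the
#' one-sided Fisher exact test on allele counts, and attaches the
#' private/polymorphic/enrichment flags. Missing genotypes are excluded from
#' both the allele count and the allele number. An optional
#' Benjamini-Hochberg column (`fisher_p_bh`) is appended for convenience; the
#' primary report is the raw one-sided p-value.
#'
#' @param variants data.frame with a `key` column.
#' @param dosage variants x patients dosage matrix (rownames = keys).
#' @param gnomad gnomAD snapshot data.frame (key, AC, AN); may be empty.
#' @param default_ref_an allele number assumed for the Fisher test when a
#'   variant is absent from the reference snapshot.
#' @return data.frame, one row per variant: key, carriers, cohort_ac,
#'   cohort_an, cohort_af, ref_ac, ref_an, ref_af, ratio, fisher_p,
#'   fisher_p_bh and the flag columns.
#' @export
enrich_variants <- function(variants, dosage, gnomad,
                            default_ref_an = 245098) {
  dosage <- dosage[variants$key, , drop = FALSE]
  cohort_ac <- rowSums(dosage, na.rm = TRUE)
  cohort_an <- 2 * rowSums(!is.na(dosage))
  carriers <- rowSums(dosage >= 1, na.rm = TRUE)
  if (nrow(gnomad) > 0L) {
    idx <- match(variants$key, gnomad$key)
    ref_ac <- gnomad$AC[idx]
    ref_an <- gnomad$AN[idx]
  } else {
    ref_ac <- rep(NA_real_, nrow(variants))
    ref_an <- rep(NA_real_, nrow(variants))
  }
  ref_af <- ifelse(is.na(ref_ac), NA_real_, ref_ac / ref_an)
  caf <- cohort_ac / cohort_an
  ratio <- af_ratio(caf, ref_af)
  # minor-allele orientation for the polymorphic flag
  ref_maf <- ifelse(is.na(ref_af), NA_real_, pmin(ref_af, 1 - ref_af))
  fp <- fisher_greater(cohort_ac, cohort_an,
                       ifelse(is.na(ref_ac), 0, ref_ac),
                       ifelse(is.na(ref_an), default_ref_an, ref_an))
  out <- data.frame(
    key = variants$key,
    carriers = carriers,
    cohort_ac = cohort_ac,
    cohort_an = cohort_an,
    cohort_af = caf,
    ref_ac = ref_ac,
    ref_an = ref_an,
    ref_af = ref_af,
    ratio = ratio,
    fisher_p = fp,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, flag_variant(carriers, ref_maf, ratio))
  out$fisher_p_bh <- stats::p.adjust(out$fisher_p, method = "BH")
  out
}
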