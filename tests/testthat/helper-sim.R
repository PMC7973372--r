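# small simulation configs used across tests
small_config <- function(seed = 1L, n_patients = 60L,
                         counts = c(PATHOGENIC = 15, REPORTED_VUS = 15,
                                    NOVEL_VUS = 20, SOMATIC_VUS = 10,
                                    OTHER = 3, BENIGN = 12)) {
  sim_config(n_patients = n_patients, n_variants_per_class = counts,
             enrichment_spec = default_enrichment_spec()[1:2, ],
             seed = seed)
}

# evidence row constructor for classifier tests
make_evidence <- function(clinvar_sig = NA, clinvar_phenotype = NA,
                          hgmd_class = NA, hgmd_phenotype = NA,
                          gnomad_ac = NA, gnomad_an = NA,
                          cosmic = FALSE, cosmic_site = NA,
                          tcga = FALSE, tcga_site = NA, key = "1:100:A:G") {
  data.frame(key = key,
             clinvar_sig = as.character(clinvar_sig),
             clinvar_phenotype = as.character(clinvar_phenotype),
             hgmd_class = as.character(hgmd_class),
             hgmd_phenotype = as.character(hgmd_phenotype),
             gnomad_ac = as.numeric(gnomad_ac),
             gnomad_an = as.numeric(gnomad_an),
             cosmic = cosmic, cosmic_site = as.character(cosmic_site),
             tcga = tcga, tcga_site = as.character(tcga_site),
             stringsAsFactors = FALSE)
}

classify_one <- function(...) classify_variants(make_evidence(...))$class

# run the in-memory analysis stages on a simulated study
run_small_study <- function(seed = 1L, config = small_config(seed = seed)) {
  study <- simulate_study(config)
  snaps <- lapply(study$snapshots, function(s) {
    s$key <- normalize_variant(s$chrom, s$pos, s$ref, s$alt)$key
    s
  })
  cons <- study$consequences
  cons$key <- normalize_variant(cons$chrom, cons$pos, cons$ref, cons$alt)$key
  ev <- join_evidence(study$variants, snaps)
  calls <- call_variants(ev, cons)
  enr <- enrich_variants(study$variants, study$dosage, snaps$gnomad,
                         default_ref_an = config$reference_an)
  flags <- suppressWarnings(provenance_flags(ev, load_phenotype_map()))
  c(study, list(evidence = ev, calls = calls, enrichment = enr,
                flags = flags))
}

# brute-force hypergeometric upper-tail oracle via direct choose() products
fisher_oracle <- function(a, an1, b, an2) {
  N <- an1 + an2
  K <- a + b
  ks <- seq.int(a, min(an1, K))
  sum(choose(an1, ks) * choose(an2, K - ks)) / choose(N, K)
}
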