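#' Demo simulation configuration
#'
#' A small end-to-end configuration (200 patients, ~300 variants) used by the
#' bundled demo pipeline and the smoke tests.
#'
#' @param seed integer seed.
#' @return a [sim_config()].
#' @export
demo_config <- function(seed = 1L) {
  sim_config(
    n_patients = 200,
    n_variants_per_class = c(PATHOGENIC = 40, REPORTED_VUS = 60,
                             NOVEL_VUS = 120, SOMATIC_VUS = 25,
                             OTHER = 5, BENIGN = 50),
    seed = seed
  )
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Class-by-coding conservation matrix
#'
#' Cross-tabulates every classified variant by significance class and
#' coding/non-coding status; every variant falls in exactly one cell, so the
#' grand total equals the number of variants.
#'
#' @param calls call table from [call_variants()].
#' @return data.frame with one row per class plus a TOTAL row.
#' @export
class_coding_matrix <- function(calls) {
  tab <- table(factor(calls$class, levels = SIGNIFICANCE_CLASSES),
               factor(ifelse(calls$coding, "coding", "non_coding"),
                      levels = c("non_coding", "coding")))
  out <- data.frame(class = rownames(tab), non_coding = tab[, "non_coding"],
                    coding = tab[, "coding"],
                    total = rowSums(tab), row.names = NULL,
                    stringsAsFactors = FALSE)
  rbind(out, data.frame(class = "TOTAL", non_coding = sum(out$non_coding),
                        coding = sum(out$coding), total = sum(out$total)))
}

#' Run the full analysis pipeline
#'
#' Stages: simulate (when `config` is a [sim_config()]) -> write inputs ->
#' read/normalize/join -> classify -> enrich -> summarize -> groups ->
#' outcomes -> report. Every stage's output is written under `out_dir` so
#' stages are independently re-runnable; the run is fully determined by the
#' configuration seed.
#'
#' @param config a [sim_config()]; its `seed` drives all randomness.
#' @param out_dir output directory (created if needed).
#' @param alpha significance threshold for the filtered outcome view.
#' @return invisibly, a list with the in-memory stage results and a `files`
#'   vector of everything written.
#' @export
run_pipeline <- function(config = demo_config(), out_dir, alpha = 0.05) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- file.path(out_dir, "inputs")
  dir.create(inp, showWarnings = FALSE)

  # stage 1: simulate and write the inputs
  study <- simulate_study(config)
  files <- character(0)
  files <- c(files, write_vcf(study$variants, study$dosage,
                              file.path(inp, "cohort.vcf")))
  for (nm in names(study$snapshots)) {
    files <- c(files, .write_tsv(study$snapshots[[nm]],
                                 file.path(inp, paste0(nm, ".tsv"))))
  }
  files <- c(files, .write_tsv(study$consequences,
                               file.path(inp, "consequences.tsv")))
  utils::write.csv(study$clinical, file.path(inp, "clinical.csv"),
                   row.names = FALSE)
  files <- c(files, file.path(inp, "clinical.csv"))
  files <- c(files, .write_tsv(study$truth, file.path(inp, "truth.tsv")))

  # stage 2: read back through the file interface and join
  cohort <- read_cohort_vcf(file.path(inp, "cohort.vcf"))
  snapshots <- list(
    clinvar = read_snapshot(file.path(inp, "clinvar.tsv"), "CLINVAR"),
    hgmd = read_snapshot(file.path(inp, "hgmd.tsv"), "HGMD"),
    gnomad = read_snapshot(file.path(inp, "gnomad.tsv"), "GNOMAD"),
    cosmic = read_snapshot(file.path(inp, "cosmic.tsv"), "COSMIC"),
    tcga = read_snapshot(file.path(inp, "tcga.tsv"), "TCGA")
  )
  consequences <- read_consequences(file.path(inp, "consequences.tsv"))
  clinical <- read_clinical(file.path(inp, "clinical.csv"))
  evidence <- join_evidence(cohort$variants, snapshots)

  # stage 3: classify
  calls <- call_variants(evidence, consequences)
  files <- c(files, .write_tsv(calls, file.path(out_dir, "calls.tsv")))

  # stage 4: enrichment
  enrich <- enrich_variants(cohort$variants, cohort$dosage, snapshots$gnomad,
                            default_ref_an = config$reference_an)
  files <- c(files, .write_tsv(enrich, file.path(out_dir, "enrichment.tsv")))

  # stage 5: summarization
  summ <- burden_and_incidence(calls, cohort$dosage)
  spectrum <- incidence_spectrum(calls, cohort$dosage)
  files <- c(files,
             .write_tsv(summ$patients, file.path(out_dir, "patients.tsv")),
             .write_tsv(summ$genes, file.path(out_dir, "genes.tsv")),
             .write_tsv(summ$cooccurrence,
                        file.path(out_dir, "cooccurrence.tsv")),
             .write_tsv(spectrum, file.path(out_dir, "incidence_spectrum.tsv")))

  # stage 6: groups
  gene_sets <- load_gene_sets()
  predicates <- load_group_predicates()
  phen_map <- load_phenotype_map()
  flags <- suppressWarnings(provenance_flags(evidence, phen_map))
  qual <- variant_group_matrix(calls, flags, enrich, predicates, gene_sets)
  assign <- assign_groups(qual, cohort$dosage)
  memb_df <- data.frame(patient_id = rownames(assign$membership),
                        assign$membership, check.names = FALSE)
  files <- c(files,
             .write_tsv(memb_df, file.path(out_dir, "membership.tsv")),
             .write_tsv(assign$triggers, file.path(out_dir, "triggers.tsv")))

  # stage 7: outcomes
  outcomes <- run_table4(assign$membership, clinical, alpha = alpha)
  files <- c(files,
             .write_tsv(outcomes$full, file.path(out_dir, "comparisons.tsv")),
             .write_tsv(outcomes$significant,
                        file.path(out_dir, "comparisons_significant.tsv")))

  # stage 8: report
  matrix_tab <- class_coding_matrix(calls)
  files <- c(files, .write_tsv(matrix_tab,
                               file.path(out_dir, "class_coding_matrix.tsv")))
  ns_cohort <- ns_ratio(calls, level = "cohort")
  ns_pat <- ns_ratio(calls, cohort$dosage, level = "per_patient")
  report <- list(
    n_patients = ncol(cohort$dosage),
    n_variants = nrow(cohort$variants),
    class_counts = as.list(table(factor(calls$class,
                                        levels = SIGNIFICANCE_CLASSES))),
    ns_ratio_cohort = ns_cohort,
    ns_ratio_per_patient_mean = ns_pat$mean,
    ns_ratio_per_patient_sd = ns_pat$sd,
    median_burden = stats::median(summ$patients$burden),
    n_enriched_2x = sum(enrich$enriched_2x),
    n_enriched_10x = sum(enrich$enriched_10x),
    n_private = sum(enrich$private),
    group_sizes = as.list(colSums(assign$membership)),
    n_significant_comparisons = nrow(outcomes$significant)
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, file.path(out_dir, "report.json"))

  invisible(list(calls = calls, enrichment = enrich, summary = summ,
                 spectrum = spectrum, membership = assign$membership,
                 triggers = assign$triggers, outcomes = outcomes,
                 report = report, truth = study$truth, clinical = clinical,
                 dosage = cohort$dosage, evidence = evidence, files = files))
}
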