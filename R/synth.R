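#' Default gene panel
#'
#' A 50-gene cancer-predisposition panel spanning DNA damage response,
#' homology-directed repair, cell-cycle checkpoints, chronic-pancreatitis
#' genes, and cell adhesion/migration; user-replaceable.
#'
#' @return character vector of gene symbols.
#' @export
default_panel <- function() {
  c("APC", "ATM", "ATR", "BARD1", "BRCA1", "BRCA2", "BRIP1", "BUB1B", "CDK4",
    "CDKN2A", "CFTR", "CHEK2", "CPA1", "CTRC", "ERCC4", "FANCA", "FANCC",
    "FANCD2", "FANCG", "MEN1", "MLH1", "MRE11A", "MSH2", "MSH6", "MUTYH",
    "NBN", "NF1", "PALB2", "PALLD", "PDGFA", "PDGFRA", "PMS2", "POLD1",
    "POLE", "PTEN", "RAD50", "RAD51", "RAD51C", "RAD51D", "SDHA", "SDHB",
    "SDHC", "SDHD", "SMARCA4", "STK11", "TP53", "TSC2", "WRN", "XRCC2",
    "KDR")
}

#' Default enrichment plantings
#'
#' Variants planted with a known reference allele frequency and cohort
#' carrier count, so that frequency-ratio and Fisher-test recovery can be
#' checked against analytic values. The defaults mirror the worked
#' pancreatic-cancer/pancreatitis susceptibility examples: singleton cohort
#' carriers over very rare reference alleles, plus one recurrent variant.
#'
#' @return data.frame with columns gene, ref_af, carriers.
#' @export
default_enrichment_spec <- function() {
  data.frame(
    gene = c("BRCA1", "BRCA2", "PALB2", "TP53", "CFTR", "CTRC", "CPA1"),
    ref_af = c(1.62e-4, 4.08e-6, 3.25e-5, 2.03e-5, 1.84e-4, 9.76e-3, 4.35e-4),
    carriers = c(1, 1, 1, 2, 1, 17, 4),
    stringsAsFactors = FALSE
  )
}

#' Build and validate a simulation configuration
#'
#' The defaults are the emulated study conditions: a 538-patient diploid
#' cohort over a 50-gene panel, class counts at the scale of the real
#' cohort's classification, a gnomAD-scale reference population
#' (AN = 245,098), enrichment plantings mirroring the worked susceptibility
#' variants, and exponential survival with a 22.0 vs 9.8 month contrast
#' between pathogenic-variant carriers and the rest.
#'
#' @param n_patients cohort size (>= 2).
#' @param panel_genes gene symbols.
#' @param n_variants_per_class named counts for the six classes.
#' @param enrichment_spec data.frame(gene, ref_af, carriers).
#' @param reference_an reference-population chromosome count
#'   (>= 2 * n_patients).
#' @param survival_spec data.frame(group, median_months, censor_frac); groups
#'   must include "pathogenic" and "rest".
#' @param seed integer seed driving all randomness.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_patients = 538,
                       panel_genes = default_panel(),
                       n_variants_per_class = c(PATHOGENIC = 75,
                                                REPORTED_VUS = 793,
                                                NOVEL_VUS = 3953,
                                                SOMATIC_VUS = 34,
                                                OTHER = 5,
                                                BENIGN = 1101),
                       enrichment_spec = default_enrichment_spec(),
                       reference_an = 245098,
                       survival_spec = data.frame(
                         group = c("pathogenic", "rest"),
                         median_months = c(22.0, 9.8),
                         censor_frac = c(0.2, 0.2)),
                       seed = 1L) {
  if (n_patients < 2) stop("n_patients must be >= 2")
  if (!all(names(n_variants_per_class) %in% SIGNIFICANCE_CLASSES)) {
    stop("unknown class in n_variants_per_class")
  }
  counts <- stats::setNames(rep(0L, length(SIGNIFICANCE_CLASSES)),
                            SIGNIFICANCE_CLASSES)
  counts[names(n_variants_per_class)] <- as.integer(n_variants_per_class)
  if (any(counts < 0)) stop("class counts must be >= 0")
  if (reference_an < 2 * n_patients) {
    stop("reference_an must be >= 2 * n_patients")
  }
  if (nrow(enrichment_spec) > 0) {
    if (any(enrichment_spec$ref_af <= 0) || any(enrichment_spec$carriers < 1)) {
      stop("enrichment_spec requires ref_af > 0 and carriers >= 1")
    }
    if (any(enrichment_spec$carriers > n_patients)) {
      stop("planted carriers exceed n_patients")
    }
  }
  if (any(survival_spec$censor_frac < 0) || any(survival_spec$censor_frac >= 1)) {
    stop("censoring fraction must be in [0, 1)")
  }
  if (any(survival_spec$median_months <= 0)) {
    stop("median survival must be positive")
  }
  structure(list(n_patients = as.integer(n_patients),
                 panel_genes = panel_genes,
                 n_variants_per_class = counts,
                 enrichment_spec = enrichment_spec,
                 reference_an = as.integer(reference_an),
                 survival_spec = survival_spec,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.coding_menu <- list(
  coding = c("missense_variant", "frameshift_variant", "stop_gained",
             "splice_donor_variant", "splice_acceptor_variant",
             "inframe_deletion", "inframe_insertion", "start_lost",
             "stop_lost"),
  noncoding = c("intron_variant", "synonymous_variant",
                "splice_region_variant", "5_prime_UTR_variant",
                "3_prime_UTR_variant", "upstream_gene_variant",
                "downstream_gene_variant")
)

.cancer_phenotypes <- c("Breast cancer", "Ovarian cancer",
                        "Colorectal cancer", "Pancreatic adenocarcinoma")
.risk_phenotypes <- c("Pancreatic cancer susceptibility",
                      "Hereditary cancer-predisposing syndrome",
                      "Lynch syndrome", "Ataxia telangiectasia")
.other_phenotypes <- c("Cystic fibrosis", "Pancreatitis",
                       "Hereditary pancreatitis", "Cardiovascular phenotype")

.primary_sites <- c("pancreas", "breast", "large_intestine", "lung",
                    "haematopoietic_and_lymphoid", "endometrium", "stomach")

#' Simulate the five annotation-database snapshots and the truth table
#'
#' Generates a panel's worth of variants with known significance classes and
#' consistent database records: pathogenic variants carry concordant
#' assertions in at least one germline snapshot; benign variants carry benign
#' assertions; reported VUS carry an explicit VUS assertion, a germline
#' conflict, or an HGMD DP/FP record; somatic VUS appear only in
#' COSMIC/TCGA; novel VUS appear in no assertion database (half are given a
#' gnomAD frequency, which must not affect classification); "other" variants
#' carry only risk-factor/drug-response annotations. Enrichment plantings
#' become pathogenic variants with reference allele count
#' round(ref_af * reference_an).
#'
#' @param config a [sim_config()].
#' @return list with `snapshots` (named list: clinvar, hgmd, gnomad, cosmic,
#'   tcga), `truth` (per-variant data.frame: key, chrom, pos, ref, alt, gene,
#'   class, consequence, coding, carriers, hom_carriers, cohort_ac, ref_ac,
#'   ref_an), and `consequences` (the consequence/score table).
#' @export
simulate_reference_snapshots <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  counts <- config$n_variants_per_class
  esp <- config$enrichment_spec
  n_extra <- nrow(esp)
  n <- sum(counts) + n_extra
  if (n == 0L) stop("configuration generates no variants")
  classes <- c(rep(names(counts), counts), rep("PATHOGENIC", n_extra))
  planted <- c(rep(FALSE, sum(counts)), rep(TRUE, n_extra))
  genes <- character(n)
  genes[!planted] <- sample(config$panel_genes, sum(counts), replace = TRUE)
  genes[planted] <- esp$gene
  # one locus per gene: deterministic chromosome and base position
  gidx <- match(genes, config$panel_genes)
  chrom <- as.character((gidx - 1L) %% 22L + 1L)
  # globally unique offsets within disjoint 1 Mb per-gene windows
  pos <- gidx * 1000000L + sample.int(900000L, n)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  # consequences: class-dependent coding mix
  p_coding <- c(PATHOGENIC = 0.8, REPORTED_VUS = 0.67, NOVEL_VUS = 0.06,
                SOMATIC_VUS = 0.56, OTHER = 0.2, BENIGN = 0.14)
  coding <- stats::runif(n) < p_coding[classes]
  coding[planted] <- TRUE
  consequence <- ifelse(
    coding,
    sample(.coding_menu$coding, n, replace = TRUE),
    sample(.coding_menu$noncoding, n, replace = TRUE))
  key <- normalize_variant(chrom, pos, ref, alt)$key

  # carrier counts: planted variants use the spec; others are mostly private
  carriers <- integer(n)
  carriers[planted] <- esp$carriers
  k <- sum(!planted)
  carriers[!planted] <- pmin(1L + stats::rpois(k, 0.8) +
                               ifelse(stats::runif(k) < 0.05,
                                      stats::rpois(k, 15), 0L),
                             config$n_patients)
  # common (polymorphic-in-reference) benign variants are common here too
  common_benign <- classes == "BENIGN" & stats::runif(n) < 0.5
  carriers[common_benign] <- pmin(
    carriers[common_benign] + stats::rbinom(sum(common_benign),
                                            config$n_patients, 0.25),
    config$n_patients)
  hom <- integer(n)
  eligible <- !planted & carriers > 0
  hom[eligible] <- stats::rbinom(sum(eligible), carriers[eligible], 0.03)
  cohort_ac <- carriers + hom
  if (any(cohort_ac > 2 * config$n_patients)) {
    stop("planted allele count exceeds 2 * n_patients")
  }

  # reference allele frequencies by class
  ref_ac <- rep(NA_real_, n)
  an <- config$reference_an
  draw_af <- function(sel, lo, hi) {
    ref_ac[sel] <<- pmax(1, round(exp(stats::runif(sum(sel), log(lo), log(hi))) * an))
  }
  draw_af(classes == "BENIGN" & !planted & common_benign, 0.05, 0.5)
  draw_af(classes == "BENIGN" & !planted & !common_benign, 1e-4, 0.04)
  sel <- classes == "REPORTED_VUS" & stats::runif(n) < 0.9
  draw_af(sel, 1e-5, 1e-2)
  sel <- classes == "PATHOGENIC" & !planted & stats::runif(n) < 0.7
  draw_af(sel, 1e-6, 1e-3)
  sel <- classes == "SOMATIC_VUS" & stats::runif(n) < 0.3
  draw_af(sel, 1e-6, 1e-4)
  sel <- classes == "OTHER" & stats::runif(n) < 0.8
  draw_af(sel, 1e-4, 0.04)
  sel <- classes == "NOVEL_VUS" & stats::runif(n) < 0.5
  draw_af(sel, 1e-6, 1e-4)
  ref_ac[planted] <- round(esp$ref_af * an)

  # germline assertion patterns
  clinvar_sig <- rep(NA_character_, n)
  clinvar_phen <- rep(NA_character_, n)
  hgmd_class <- rep(NA_character_, n)
  hgmd_phen <- rep(NA_character_, n)
  in_cosmic <- rep(FALSE, n)
  in_tcga <- rep(FALSE, n)
  phen_pool <- function(m) sample(c(.cancer_phenotypes, .risk_phenotypes,
                                    .other_phenotypes), m, replace = TRUE)
  for (i in seq_len(n)) {
    cl <- classes[i]
    if (cl == "PATHOGENIC") {
      mode <- if (planted[i]) "both" else
        sample(c("clinvar", "hgmd", "both"), 1)
      if (mode %in% c("clinvar", "both")) {
        clinvar_sig[i] <- sample(c("Pathogenic", "Likely_pathogenic",
                                   "Pathogenic/Likely_pathogenic"), 1)
        clinvar_phen[i] <- phen_pool(1)
      }
      if (mode %in% c("hgmd", "both")) {
        hgmd_class[i] <- sample(c("DM", "DM?", "DFP"), 1)
        hgmd_phen[i] <- phen_pool(1)
      }
      if (stats::runif(1) < 0.3) in_cosmic[i] <- TRUE
    } else if (cl == "BENIGN") {
      clinvar_sig[i] <- sample(c("Benign", "Likely_benign",
                                 "Benign/Likely_benign"), 1)
      clinvar_phen[i] <- phen_pool(1)
    } else if (cl == "REPORTED_VUS") {
      mode <- sample(c("vus", "conflicting_term", "pb_conflict", "hgmd_poly"), 1)
      if (mode == "vus") {
        clinvar_sig[i] <- "Uncertain_significance"
        clinvar_phen[i] <- phen_pool(1)
      } else if (mode == "conflicting_term") {
        clinvar_sig[i] <- "Conflicting_interpretations_of_pathogenicity"
        clinvar_phen[i] <- phen_pool(1)
      } else if (mode == "pb_conflict") {
        clinvar_sig[i] <- sample(c("Benign", "Likely_benign"), 1)
        clinvar_phen[i] <- phen_pool(1)
        hgmd_class[i] <- "DM"
        hgmd_phen[i] <- phen_pool(1)
      } else {
        hgmd_class[i] <- sample(c("DP", "FP"), 1)
        hgmd_phen[i] <- phen_pool(1)
      }
      if (stats::runif(1) < 0.25) in_cosmic[i] <- TRUE
      if (stats::runif(1) < 0.1) in_tcga[i] <- TRUE
    } else if (cl == "SOMATIC_VUS") {
      pick <- sample(c("cosmic", "tcga", "both"), 1)
      in_cosmic[i] <- pick != "tcga"
      in_tcga[i] <- pick != "cosmic"
    } else if (cl == "OTHER") {
      clinvar_sig[i] <- sample(c("risk_factor", "drug_response"), 1)
      clinvar_phen[i] <- sample(.other_phenotypes, 1)
    }
  }

  base_cols <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                          stringsAsFactors = FALSE)
  snap <- function(sel, extra) {
    out <- cbind(base_cols[sel, , drop = FALSE], extra)
    rownames(out) <- NULL
    out
  }
  gn <- !is.na(ref_ac)
  snapshots <- list(
    clinvar = snap(!is.na(clinvar_sig),
                   data.frame(clinical_significance = clinvar_sig[!is.na(clinvar_sig)],
                              phenotype = clinvar_phen[!is.na(clinvar_sig)],
                              stringsAsFactors = FALSE)),
    hgmd = snap(!is.na(hgmd_class),
                data.frame(variant_class = hgmd_class[!is.na(hgmd_class)],
                           phenotype = hgmd_phen[!is.na(hgmd_class)],
                           stringsAsFactors = FALSE)),
    gnomad = snap(gn, data.frame(AC = ref_ac[gn], AN = an)),
    cosmic = snap(in_cosmic,
                  data.frame(primary_site = sample(.primary_sites,
                                                   sum(in_cosmic),
                                                   replace = TRUE),
                             sample_count = 1L + stats::rpois(sum(in_cosmic), 4),
                             stringsAsFactors = FALSE)),
    tcga = snap(in_tcga,
                data.frame(primary_site = sample(.primary_sites, sum(in_tcga),
                                                 replace = TRUE),
                           sample_count = 1L + stats::rpois(sum(in_tcga), 2),
                           stringsAsFactors = FALSE))
  )

  # raw predictor scores: generated for coding SNVs, absent elsewhere
  sc_na <- rep(NA_real_, n)
  has_score <- coding & consequence == "missense_variant"
  m <- sum(has_score)
  scores <- data.frame(cadd = sc_na, revel = sc_na, sift = sc_na,
                       fathmm = sc_na, lrt = rep(NA_character_, n),
                       metalr = sc_na, stringsAsFactors = FALSE)
  scores$cadd[has_score] <- round(stats::runif(m, 0, 45), 1)
  scores$revel[has_score] <- round(stats::runif(m), 3)
  scores$sift[has_score] <- round(stats::runif(m), 3)
  scores$fathmm[has_score] <- round(stats::runif(m, -5, 5), 2)
  scores$lrt[has_score] <- sample(c("D", "N", "U"), m, replace = TRUE)
  scores$metalr[has_score] <- round(stats::runif(m), 3)

  truth <- data.frame(
    key = key, chrom = chrom, pos = pos, ref = ref, alt = alt, gene = genes,
    class = classes, consequence = consequence, coding = coding,
    carriers = carriers, hom_carriers = hom, cohort_ac = cohort_ac,
    ref_ac = ifelse(is.na(ref_ac), 0, ref_ac),
    ref_an = ifelse(is.na(ref_ac), NA_integer_, an),
    planted = planted,
    stringsAsFactors = FALSE
  )
  consequences <- cbind(base_cols,
                        data.frame(gene = genes, consequence = consequence,
                                   stringsAsFactors = FALSE),
                        scores)
  list(snapshots = snapshots, truth = truth, consequences = consequences)
}

#' Simulate the multi-sample cohort VCF genotypes
#'
#' Distributes each variant's planted carriers (heterozygous, plus the
#' truth-table's homozygous upgrades) independently across patients (no
#' linkage), so that per-variant alternate-allele column sums equal the
#' planted cohort allele counts exactly. Variants with zero planted alleles
#' are omitted.
#'
#' @param config a [sim_config()].
#' @param truth truth table from [simulate_reference_snapshots()].
#' @return list with `variants` (chrom, pos, ref, alt, key; position-sorted)
#'   and `dosage` (variants x patients integer matrix).
#' @export
simulate_cohort_vcf <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  np <- config$n_patients
  if (any(truth$cohort_ac > 2L * np)) {
    stop("planted allele count exceeds 2 * n_patients")
  }
  keep <- truth$cohort_ac > 0L
  tt <- truth[keep, , drop = FALSE]
  pats <- sprintf("P%04d", seq_len(np))
  dosage <- matrix(0L, nrow(tt), np, dimnames = list(tt$key, pats))
  for (i in seq_len(nrow(tt))) {
    who <- sample.int(np, tt$carriers[i])
    dosage[i, who] <- 1L
    if (tt$hom_carriers[i] > 0L) {
      dosage[i, who[seq_len(tt$hom_carriers[i])]] <- 2L
    }
  }
  ord <- order(as.integer(tt$chrom), tt$pos)
  variants <- tt[ord, c("chrom", "pos", "ref", "alt", "key")]
  rownames(variants) <- NULL
  list(variants = variants, dosage = dosage[ord, , drop = FALSE])
}

#' Write a cohort VCF v4.2
#'
#' @param variants data.frame (chrom, pos, ref, alt), position-sorted.
#' @param dosage variants x patients dosage matrix.
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, dosage, path) {
  stopifnot(nrow(variants) == nrow(dosage))
  gt <- matrix(c("0/0", "0/1", "1/1")[dosage + 1L],
               nrow = nrow(dosage), ncol = ncol(dosage))
  gt[is.na(dosage)] <- "./."
  contigs <- unique(variants$chrom)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=mtier-synthetic-cohort",
    paste0("##contig=<ID=", contigs, ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(dosage)), collapse = "\t")
  )
  body <- paste(variants$chrom, variants$pos, ".", variants$ref, variants$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Simulate the clinical table
#'
#' Survival times are exponential with the group medians from the
#' configuration (rate = ln 2 / median, so the analytic median is
#' recoverable); a `censor_frac` fraction of each group is censored at a
#' uniform fraction of its event time. Stage is multinomial
#' (resectable/borderline/locally advanced/metastatic at 31/33/20/16%),
#' surgery depends on stage, CA19-9 is log-normal among the ~69% of
#' producers.
#'
#' @param config a [sim_config()].
#' @param groups named character vector: patient id -> survival group label
#'   (must match `config$survival_spec$group`).
#' @return clinical data.frame: patient_id, age, sex, race, stage, surgery,
#'   ca19_9_producer, ca19_9, os_months, vital_status, survival_group.
#' @export
simulate_clinical <- function(config, groups) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  spec <- config$survival_spec
  if (!all(groups %in% spec$group)) {
    stop("unknown survival group label(s): ",
         paste(setdiff(unique(groups), spec$group), collapse = ", "))
  }
  np <- length(groups)
  idx <- match(groups, spec$group)
  rate <- log(2) / spec$median_months[idx]
  t_event <- stats::rexp(np, rate)
  censored <- stats::runif(np) < spec$censor_frac[idx]
  os <- ifelse(censored, t_event * stats::runif(np), t_event)
  stage <- sample(c("resectable", "borderline", "locally advanced",
                    "metastatic"), np, replace = TRUE,
                  prob = c(0.31, 0.33, 0.20, 0.16))
  surgery <- stats::runif(np) < c("resectable" = 0.85, "borderline" = 0.6,
                                  "locally advanced" = 0.3,
                                  "metastatic" = 0.02)[stage]
  producer <- stats::runif(np) < 0.69
  ca19_9 <- ifelse(producer,
                   round(stats::rlnorm(np, log(321), 1.1), 1), NA_real_)
  data.frame(
    patient_id = names(groups),
    age = pmin(pmax(round(stats::rnorm(np, 65, 9)), 30), 92),
    sex = sample(c("F", "M"), np, replace = TRUE, prob = c(0.47, 0.53)),
    race = sample(c("white", "black", "hispanic", "asian", "other"), np,
                  replace = TRUE, prob = c(0.89, 0.065, 0.02, 0.015, 0.01)),
    stage = stage,
    surgery = surgery,
    ca19_9_producer = producer,
    ca19_9 = ca19_9,
    os_months = round(os, 2),
    vital_status = as.integer(!censored),
    survival_group = unname(groups),
    stringsAsFactors = FALSE
  )
}

#' Simulate a complete study
#'
#' Runs the three generators in sequence: snapshots + truth, cohort
#' genotypes, and clinical outcomes. The survival group of each patient is
#' "pathogenic" if they carry at least one planted-pathogenic variant, else
#' "rest" (matching the default `survival_spec`); custom specs can relabel
#' via the returned truth.
#'
#' @param config a [sim_config()].
#' @return list: config, snapshots, truth, variants, dosage, consequences,
#'   clinical, patient_groups.
#' @export
simulate_study <- function(config = sim_config()) {
  snap <- simulate_reference_snapshots(config)
  vcf <- simulate_cohort_vcf(config, snap$truth)
  path_keys <- snap$truth$key[snap$truth$class == "PATHOGENIC"]
  carried_path <- colSums(vcf$dosage[rownames(vcf$dosage) %in% path_keys, ,
                                     drop = FALSE] >= 1) > 0
  groups <- stats::setNames(ifelse(carried_path, "pathogenic", "rest"),
                            colnames(vcf$dosage))
  clinical <- simulate_clinical(config, groups)
  list(config = config, snapshots = snap$snapshots, truth = snap$truth,
       variants = vcf$variants, dosage = vcf$dosage,
       consequences = snap$consequences, clinical = clinical,
       patient_groups = groups)
}
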