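#' Six clinical-significance classes
#'
#' Severity order (most to least severe) as used when collapsing multiple
#' variants in the same gene for the same patient.
#' @export
SIGNIFICANCE_CLASSES <- c("PATHOGENIC", "REPORTED_VUS", "NOVEL_VUS",
                          "SOMATIC_VUS", "OTHER", "BENIGN")

#' Recode a ClinVar aggregate significance term
#'
#' Maps ClinVar aggregate clinical-significance strings onto the harmonized
#' germline scale: P (pathogenic / likely pathogenic, including combined
#' terms), B (benign / likely benign), VUS (uncertain significance or
#' conflicting interpretations), OTHER (risk factor or drug response as the
#' sole annotation), NONE (unrecognized, with a warning).
#'
#' @param term character vector of ClinVar significance strings.
#' @return character vector over {"P","B","VUS","OTHER","NONE"}.
#' @export
recode_clinvar <- function(term) {
  out <- rep(NA_character_, length(term))
  t <- tolower(gsub("[ /,]+", "_", trimws(term)))
  p <- c("pathogenic", "likely_pathogenic", "pathogenic_likely_pathogenic")
  b <- c("benign", "likely_benign", "benign_likely_benign")
  vus <- c("uncertain_significance",
           "conflicting_interpretations_of_pathogenicity",
           "conflicting_interpretations")
  oth <- c("risk_factor", "drug_response", "risk_factor_drug_response",
           "drug_response_risk_factor")
  out[t %in% p] <- "P"
  out[t %in% b] <- "B"
  out[t %in% vus] <- "VUS"
  out[t %in% oth] <- "OTHER"
  unknown <- is.na(out) & !is.na(term)
  if (any(unknown)) {
    warning("unrecognized ClinVar term(s) recoded to NONE: ",
            paste(unique(term[unknown]), collapse = ", "))
    out[unknown] <- "NONE"
  }
  out[is.na(term)] <- NA_character_
  out
}

#' Recode an HGMD variant class
#'
#' DM, DM? and DFP are treated as pathogenic assertions; DP and FP as
#' variants of uncertain significance; retired records (R) are ignored.
#'
#' @param code character vector over {"DM","DM?","DFP","DP","FP","R"}.
#' @return character vector over {"P","VUS","IGNORED"}.
#' @export
recode_hgmd <- function(code) {
  map <- c("DM" = "P", "DM?" = "P", "DFP" = "P",
           "DP" = "VUS", "FP" = "VUS", "R" = "IGNORED")
  bad <- !is.na(code) & !(code %in% names(map))
  if (any(bad)) {
    stop("unknown HGMD code(s): ", paste(unique(code[bad]), collapse = ", "))
  }
  out <- unname(map[code])
  out[is.na(code)] <- NA_character_
  out
}

#' Classify variants into the six clinical-significance classes
#'
#' Applies the harmonized decision rule to each row of an evidence table
#' (from [join_evidence()]):
#' \enumerate{
#'   \item no record in any of ClinVar, HGMD, COSMIC, TCGA (gnomAD presence
#'     alone is frequency evidence, not an assertion) -> NOVEL_VUS;
#'   \item records only in the somatic resources -> SOMATIC_VUS;
#'   \item germline assertions present: any explicit VUS assertion, or
#'     co-occurrence of P and B assertions, -> REPORTED_VUS; all-P (possibly
#'     with OTHER) -> PATHOGENIC; all-B (possibly with OTHER) -> BENIGN;
#'     only OTHER -> OTHER.
#' }
#' A germline record whose assertions all recode to IGNORED (HGMD retired)
#' or NONE (unrecognized), with no somatic record, yields NOVEL_VUS.
#'
#' @param evidence data.frame from [join_evidence()].
#' @return data.frame with columns `key`, `class` (one of
#'   [SIGNIFICANCE_CLASSES]), and `rationale` (machine-readable trace of the
#'   rule that fired).
#' @export
classify_variants <- function(evidence) {
  n <- nrow(evidence)
  cv <- recode_clinvar(evidence$clinvar_sig)
  hg <- recode_hgmd(evidence$hgmd_class)
  cls <- character(n)
  why <- character(n)
  for (i in seq_len(n)) {
    has_clinvar <- !is.na(evidence$clinvar_sig[i])
    has_hgmd <- !is.na(evidence$hgmd_class[i])
    somatic <- isTRUE(evidence$cosmic[i]) || isTRUE(evidence$tcga[i])
    germ <- c(cv[i], hg[i])
    germ <- germ[!is.na(germ) & !(germ %in% c("IGNORED", "NONE"))]
    if (!has_clinvar && !has_hgmd && !somatic) {
      cls[i] <- "NOVEL_VUS"; why[i] <- "no_assertion_record"
    } else if (length(germ) == 0L && somatic) {
      cls[i] <- "SOMATIC_VUS"; why[i] <- "somatic_only"
    } else if (length(germ) == 0L) {
      cls[i] <- "NOVEL_VUS"; why[i] <- "germline_records_uninformative"
    } else if (any(germ == "VUS")) {
      cls[i] <- "REPORTED_VUS"; why[i] <- "explicit_vus_assertion"
    } else if (any(germ == "P") && any(germ == "B")) {
      cls[i] <- "REPORTED_VUS"; why[i] <- "conflicting_p_and_b"
    } else if (any(germ == "P")) {
      cls[i] <- "PATHOGENIC"; why[i] <- "consistent_pathogenic"
    } else if (any(germ == "B")) {
      cls[i] <- "BENIGN"; why[i] <- "consistent_benign"
    } else {
      cls[i] <- "OTHER"; why[i] <- "risk_or_drug_response_only"
    }
  }
  data.frame(key = evidence$key, class = cls, rationale = why,
             stringsAsFactors = FALSE)
}

# consequence terms counted as protein-coding
.coding_terms <- c(
  "missense_variant", "inframe_insertion", "inframe_deletion",
  "disruptive_inframe_insertion", "disruptive_inframe_deletion",
  "frameshift_variant", "splice_donor_variant", "splice_acceptor_variant",
  "start_lost", "initiator_codon_variant", "stop_gained", "stop_lost"
)

.noncoding_terms <- c(
  "synonymous_variant", "stop_retained_variant", "intron_variant",
  "splice_region_variant", "5_prime_UTR_variant", "3_prime_UTR_variant",
  "upstream_gene_variant", "downstream_gene_variant", "intergenic_variant",
  "non_coding_transcript_exon_variant"
)

#' Partition consequence terms into coding and non-coding
#'
#' Protein-coding consequences are amino-acid substitutions, in-frame
#' insertions/deletions, frameshifts, splice donor/acceptor alterations, and
#' start/stop codon alterations. Everything else (synonymous, intronic,
#' splice region, UTR, up/downstream) is non-coding; unknown terms are
#' non-coding with a warning.
#'
#' @param term character vector of Sequence Ontology-style consequence terms.
#' @return logical vector: TRUE for coding.
#' @export
is_coding_consequence <- function(term) {
  t <- trimws(term)
  unknown <- !is.na(t) & !(t %in% c(.coding_terms, .noncoding_terms))
  if (any(unknown)) {
    warning("unknown consequence term(s) treated as non-coding: ",
            paste(unique(t[unknown]), collapse = ", "))
  }
  out <- t %in% .coding_terms
  out[is.na(t)] <- FALSE
  out
}

#' Discretize sequence-based predictor scores
#'
#' Converts raw per-tool scores to DELETERIOUS / TOLERATED / NG
#' (not generated). Thresholds: CADD >= 30 and REVEL > 0.5 (study-specific
#' cutoffs); SIFT < 0.05, FATHMM <= -1.5, MetaLR > 0.5 (the tools' published
#' defaults); LRT uses its categorical label "D". Absent scores are NG.
#'
#' @param scores data.frame with numeric columns cadd, revel, sift, fathmm,
#'   metalr and character column lrt (labels "D"/"N"/"U"); NA where a tool
#'   produced no score.
#' @return data.frame of the same height with columns cadd_call, revel_call,
#'   sift_call, fathmm_call, lrt_call, metalr_call over
#'   {"DELETERIOUS","TOLERATED","NG"}.
#' @export
discretize_scores <- function(scores) {
  num <- function(x, nm) {
    if (is.character(x)) {
      bad <- !is.na(x) & nzchar(x) & is.na(suppressWarnings(as.numeric(x)))
      if (any(bad)) stop("non-numeric ", nm, " score: ",
                         paste(unique(x[bad]), collapse = ", "))
      x <- suppressWarnings(as.numeric(x))
    }
    x
  }
  call_num <- function(x, deleterious) {
    out <- ifelse(is.na(x), "NG", ifelse(deleterious, "DELETERIOUS", "TOLERATED"))
    out
  }
  cadd <- num(scores$cadd, "CADD")
  revel <- num(scores$revel, "REVEL")
  sift <- num(scores$sift, "SIFT")
  fathmm <- num(scores$fathmm, "FATHMM")
  metalr <- num(scores$metalr, "MetaLR")
  lrt <- as.character(scores$lrt)
  lrt[!is.na(lrt) & !nzchar(lrt)] <- NA_character_
  data.frame(
    cadd_call = call_num(cadd, cadd >= 30),
    revel_call = call_num(revel, revel > 0.5),
    sift_call = call_num(sift, sift < 0.05),
    fathmm_call = call_num(fathmm, fathmm <= -1.5),
    lrt_call = ifelse(is.na(lrt), "NG",
                      ifelse(lrt == "D", "DELETERIOUS", "TOLERATED")),
    metalr_call = call_num(metalr, metalr > 0.5),
    stringsAsFactors = FALSE
  )
}

#' Build the full per-variant call table
#'
#' Joins classification, coding partition, and score discretization into the
#' call table consumed by the summarization and grouping stages.
#'
#' @param evidence evidence table from [join_evidence()].
#' @param consequences consequence/score table from [read_consequences()].
#' @return data.frame: key, gene, consequence, class, coding, rationale, and
#'   the six discretized score columns.
#' @export
call_variants <- function(evidence, consequences) {
  calls <- classify_variants(evidence)
  idx <- match(calls$key, consequences$key)
  calls$gene <- consequences$gene[idx]
  calls$consequence <- consequences$consequence[idx]
  calls$coding <- is_coding_consequence(calls$consequence)
  sc <- consequences[idx, c("cadd", "revel", "sift", "fathmm", "lrt", "metalr")]
  cbind(calls[, c("key", "gene", "consequence", "class", "coding", "rationale")],
        discretize_scores(sc))
}
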