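#' Collapse multiple significance classes to the most severe
#'
#' When a patient carries several variants in the same gene, the gene is
#' summarized by the most severe class, in the order PATHOGENIC >
#' REPORTED_VUS > NOVEL_VUS > SOMATIC_VUS > OTHER > BENIGN.
#'
#' @param classes non-empty character vector of significance classes.
#' @return a single class.
#' @export
collapse_severity <- function(classes) {
  classes <- classes[!is.na(classes)]
  if (length(classes) == 0L) stop("cannot collapse an empty set of classes")
  bad <- !(classes %in% SIGNIFICANCE_CLASSES)
  if (any(bad)) stop("unknown class: ", paste(unique(classes[bad]), collapse = ", "))
  SIGNIFICANCE_CLASSES[min(match(classes, SIGNIFICANCE_CLASSES))]
}

#' Non-synonymous to synonymous ratio
#'
#' ns = protein-altering variants under the coding definition (missense,
#' in-frame indels, frameshifts, splice donor/acceptor, start/stop changes);
#' s = synonymous variants. At the cohort level the ratio is over unique
#' variants; at the patient level over each patient's carried variants,
#' reported as mean and sd across patients.
#'
#' @param calls call table (needs `key`, `consequence` columns).
#' @param dosage optional dosage matrix for the per-patient level.
#' @param level "cohort" or "per_patient".
#' @return for "cohort": a single ratio (NA when no synonymous variants); for
#'   "per_patient": list(mean, sd, ratios) over patients with >= 1 synonymous
#'   variant.
#' @export
ns_ratio <- function(calls, dosage = NULL, level = c("cohort", "per_patient")) {
  level <- match.arg(level)
  ns <- is_coding_consequence(calls$consequence)
  syn <- calls$consequence %in% c("synonymous_variant", "stop_retained_variant")
  if (level == "cohort") {
    if (sum(syn) == 0L) return(NA_real_)
    return(sum(ns) / sum(syn))
  }
  stopifnot(!is.null(dosage))
  dosage <- dosage[calls$key, , drop = FALSE]
  carried <- !is.na(dosage) & dosage >= 1
  per_ns <- colSums(carried[ns, , drop = FALSE])
  per_syn <- colSums(carried[syn, , drop = FALSE])
  ratios <- ifelse(per_syn == 0, NA_real_, per_ns / per_syn)
  list(mean = mean(ratios, na.rm = TRUE),
       sd = stats::sd(ratios, na.rm = TRUE),
       ratios = ratios)
}

#' Per-patient burden profiles and per-gene summaries
#'
#' A patient "carries" a variant iff dosage >= 1 (homozygous carriage counts
#' once). Burden is the number of carried variants; per-gene incidence
#' counts patients with >= 1 carried variant in the gene, broken down by the
#' severity-collapsed class of the patient-gene pair; the co-occurrence
#' histogram counts patients by number of distinct carried variants per gene.
#'
#' @param calls call table (key, gene, class, coding).
#' @param dosage dosage matrix (rownames = keys, colnames = patient ids).
#' @return list with `patients` (data.frame: patient_id, burden,
#'   coding_burden, one count column per class), `genes` (data.frame: gene,
#'   unique-variant count per class, incidence per collapsed class, total
#'   incidence), and `cooccurrence` (data.frame: gene, k, n_patients).
#' @export
burden_and_incidence <- function(calls, dosage) {
  dosage <- dosage[calls$key, , drop = FALSE]
  carried <- !is.na(dosage) & dosage >= 1
  pats <- colnames(dosage)
  cls_levels <- SIGNIFICANCE_CLASSES
  per_class <- sapply(cls_levels, function(cl) {
    colSums(carried[calls$class == cl, , drop = FALSE])
  })
  if (is.null(dim(per_class))) per_class <- t(per_class)
  patients <- data.frame(
    patient_id = pats,
    burden = colSums(carried),
    coding_burden = colSums(carried[calls$coding, , drop = FALSE]),
    stringsAsFactors = FALSE
  )
  patients <- cbind(patients, as.data.frame(per_class))
  genes <- sort(unique(calls$gene))
  gene_rows <- list()
  cooc <- list()
  for (g in genes) {
    sel <- calls$gene == g
    uv <- table(factor(calls$class[sel], levels = cls_levels))
    sub <- carried[sel, , drop = FALSE]
    kper <- colSums(sub)
    affected <- kper > 0
    collapsed <- vapply(pats[affected], function(p) {
      collapse_severity(calls$class[sel][sub[, p]])
    }, character(1))
    inc <- table(factor(collapsed, levels = cls_levels))
    gene_rows[[g]] <- data.frame(
      gene = g,
      t(as.matrix(uv)),
      incidence = sum(affected),
      t(as.matrix(stats::setNames(as.integer(inc),
                                  paste0("inc_", cls_levels)))),
      stringsAsFactors = FALSE, check.names = FALSE
    )
    kt <- table(kper[kper > 0])
    if (length(kt)) {
      cooc[[g]] <- data.frame(gene = g, k = as.integer(names(kt)),
                              n_patients = as.integer(kt),
                              stringsAsFactors = FALSE)
    }
  }
  list(
    patients = patients,
    genes = do.call(rbind, c(gene_rows, list(make.row.names = FALSE))),
    cooccurrence = do.call(rbind, c(cooc, list(make.row.names = FALSE)))
  )
}

#' Incidence spectrum: private, recurrent, and frequent variants
#'
#' @param calls call table (key, coding).
#' @param dosage dosage matrix.
#' @return data.frame with rows for "all" and "coding" variants: counts and
#'   fractions of private (exactly one carrier), recurrent (>= 2 carriers),
#'   and frequent (>= 5 carriers) variants.
#' @export
incidence_spectrum <- function(calls, dosage) {
  dosage <- dosage[calls$key, , drop = FALSE]
  carriers <- rowSums(!is.na(dosage) & dosage >= 1)
  one <- function(sel, label) {
    cc <- carriers[sel]
    n <- length(cc)
    data.frame(
      set = label,
      n_variants = n,
      private = sum(cc == 1),
      recurrent_2plus = sum(cc >= 2),
      frequent_5plus = sum(cc >= 5),
      private_frac = if (n) sum(cc == 1) / n else NA_real_,
      frequent_frac = if (n) sum(cc >= 5) / n else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  rbind(one(rep(TRUE, nrow(calls)), "all"), one(calls$coding, "coding"))
}
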