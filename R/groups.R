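#' Load gene-set configuration
#'
#' Gene sets are configuration, not code: the defaults ship as YAML
#' (DDR, HDR, CELL_CYCLE, GCP, ATM, BRCA1_2) and can be replaced by the user.
#' HDR must be a subset of DDR.
#'
#' @param path YAML file; default is the bundled configuration.
#' @return named list of character vectors of gene symbols.
#' @export
load_gene_sets <- function(path = system.file("extdata", "gene_sets.yaml",
                                              package = "mtier")) {
  gs <- yaml::read_yaml(path)
  gs <- lapply(gs, as.character)
  if (!is.null(gs$HDR) && !is.null(gs$DDR) && !all(gs$HDR %in% gs$DDR)) {
    stop("gene-set configuration invalid: HDR must be a subset of DDR")
  }
  gs
}

#' Load the phenotype-to-category map
#'
#' Emulates manual phenotype curation: maps phenotype strings to CANCER,
#' CANCER_RISK, or OTHER.
#'
#' @param path YAML file; default is the bundled map.
#' @return named character vector (phenotype -> category).
#' @export
load_phenotype_map <- function(path = system.file("extdata",
                                                  "phenotype_map.yaml",
                                                  package = "mtier")) {
  unlist(yaml::read_yaml(path))
}

#' Load group-predicate configuration
#'
#' Each predicate defines one genomics-based patient group by: whether the
#' triggering variant must be PATHOGENIC, a provenance clause over the flags
#' G (germline record), S (somatic record), G_C (germline record with a
#' cancer or cancer-risk phenotype) and S_PDAC (somatic record with pancreas
#' primary site), an optional class restriction, an optional gene-set
#' restriction, and an optional minimum enrichment ratio. The 18 bundled
#' defaults mirror the study's group table.
#'
#' @param path YAML file; default is the bundled 18-group configuration.
#' @return list of predicate lists (id, name, requires_pathogenic,
#'   provenance, classes, gene_set, min_ratio).
#' @export
load_group_predicates <- function(path = system.file("extdata",
                                                     "group_predicates.yaml",
                                                     package = "mtier")) {
  yaml::read_yaml(path)
}

#' Provenance flags for each variant
#'
#' G: any ClinVar or HGMD record. S: any COSMIC or TCGA record. G_C: G with
#' any attached phenotype mapped to CANCER or CANCER_RISK. S_PDAC: a somatic
#' record whose primary site is pancreas. Phenotypes missing from the map
#' are treated as OTHER with a warning.
#'
#' @param evidence evidence table from [join_evidence()].
#' @param phenotype_map named character vector from [load_phenotype_map()].
#' @return data.frame with logical columns G, S, G_C, S_PDAC (one row per
#'   variant, keyed like `evidence`).
#' @export
provenance_flags <- function(evidence, phenotype_map) {
  g <- !is.na(evidence$clinvar_sig) | !is.na(evidence$hgmd_class)
  s <- evidence$cosmic | evidence$tcga
  phen_cat <- function(ph) {
    if (is.na(ph) || !nzchar(ph)) return(NA_character_)
    if (!(ph %in% names(phenotype_map))) {
      warning("unmapped phenotype treated as OTHER: ", ph)
      return("OTHER")
    }
    phenotype_map[[ph]]
  }
  cancer_phen <- vapply(seq_len(nrow(evidence)), function(i) {
    cats <- c(phen_cat(evidence$clinvar_phenotype[i]),
              phen_cat(evidence$hgmd_phenotype[i]))
    any(cats %in% c("CANCER", "CANCER_RISK"))
  }, logical(1))
  pancreas <- function(site) {
    !is.na(site) & tolower(site) == "pancreas"
  }
  data.frame(
    key = evidence$key,
    G = g,
    S = s,
    G_C = g & cancer_phen,
    S_PDAC = (evidence$cosmic & pancreas(evidence$cosmic_site)) |
             (evidence$tcga & pancreas(evidence$tcga_site)),
    stringsAsFactors = FALSE
  )
}

# evaluate a provenance clause string ("G_C and not S") for flag rows
.eval_provenance <- function(clause, flags) {
  if (is.null(clause) || !nzchar(clause)) return(rep(TRUE, nrow(flags)))
  expr <- gsub("\\bnot\\b", "!", clause)
  expr <- gsub("\\band\\b", "&", expr)
  expr <- gsub("\\bor\\b", "|", expr)
  allowed <- c("G", "S", "G_C", "S_PDAC")
  toks <- unique(regmatches(expr, gregexpr("[A-Za-z_]+", expr))[[1]])
  if (length(setdiff(toks, allowed))) {
    stop("provenance clause uses unknown flag(s): ",
         paste(setdiff(toks, allowed), collapse = ", "))
  }
  env <- list2env(as.list(flags[, allowed]))
  eval(parse(text = expr), envir = env)
}

#' Per-variant group qualification matrix
#'
#' Determines, for every variant and every group predicate, whether the
#' variant qualifies (triggers) the group. Polymorphic variants (reference
#' MAF >= 5%) never trigger membership.
#'
#' @param calls call table (key, gene, class).
#' @param flags provenance flags from [provenance_flags()].
#' @param enrich enrichment table from [enrich_variants()].
#' @param predicates list from [load_group_predicates()].
#' @param gene_sets list from [load_gene_sets()].
#' @return logical matrix, variants x groups (rownames = keys, colnames =
#'   group ids).
#' @export
variant_group_matrix <- function(calls, flags, enrich, predicates, gene_sets) {
  fl <- flags[match(calls$key, flags$key), ]
  en <- enrich[match(calls$key, enrich$key), ]
  qual <- matrix(FALSE, nrow(calls), length(predicates),
                 dimnames = list(calls$key,
                                 vapply(predicates, `[[`, character(1), "id")))
  for (j in seq_along(predicates)) {
    p <- predicates[[j]]
    ok <- !en$polymorphic
    if (isTRUE(p$requires_pathogenic)) ok <- ok & calls$class == "PATHOGENIC"
    if (!is.null(p$classes)) ok <- ok & calls$class %in% unlist(p$classes)
    ok <- ok & .eval_provenance(p$provenance, fl)
    if (!is.null(p$gene_set)) {
      if (!(p$gene_set %in% names(gene_sets))) {
        stop("predicate '", p$id, "' references undefined gene set: ", p$gene_set)
      }
      ok <- ok & calls$gene %in% gene_sets[[p$gene_set]]
    }
    if (!is.null(p$min_ratio)) {
      ok <- ok & !is.na(en$ratio) & en$ratio >= p$min_ratio
    }
    qual[, j] <- ok
  }
  qual
}

#' Assign patients to genomic groups
#'
#' A patient belongs to a group iff at least one of their carried variants
#' (dosage >= 1) qualifies under the group's predicate.
#'
#' @param qual variant x group qualification matrix from
#'   [variant_group_matrix()].
#' @param dosage dosage matrix (rownames = keys, colnames = patient ids).
#' @return list with `membership` (logical matrix, patients x groups) and
#'   `triggers` (data.frame: patient_id, group, key of each triggering
#'   variant).
#' @export
assign_groups <- function(qual, dosage) {
  dosage <- dosage[rownames(qual), , drop = FALSE]
  carried <- !is.na(dosage) & dosage >= 1
  membership <- t(carried) %*% qual > 0
  trig <- which(qual, arr.ind = TRUE)
  triggers <- if (length(trig)) {
    do.call(rbind, lapply(seq_len(nrow(trig)), function(r) {
      i <- trig[r, 1]; j <- trig[r, 2]
      pats <- colnames(dosage)[carried[i, ]]
      if (!length(pats)) return(NULL)
      data.frame(patient_id = pats, group = colnames(qual)[j],
                 key = rownames(qual)[i], stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(patient_id = character(0), group = character(0),
               key = character(0), stringsAsFactors = FALSE)
  }
  list(membership = membership, triggers = triggers)
}

#' Membership in the enrichment-defined group
#'
#' @param enrich enrichment table from [enrich_variants()].
#' @param dosage dosage matrix.
#' @param threshold minimum frequency ratio (default 10).
#' @return named logical vector over patients: carries >= 1 variant with
#'   ratio >= threshold.
#' @export
enrichment_group <- function(enrich, dosage, threshold = 10) {
  sel <- !is.na(enrich$ratio) & enrich$ratio >= threshold
  keys <- enrich$key[sel]
  carried <- !is.na(dosage[keys, , drop = FALSE]) &
    dosage[keys, , drop = FALSE] >= 1
  colSums(carried) > 0
}
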