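test_that("bundled configuration files load and validate", {
  gs <- load_gene_sets()
  expect_true(all(gs$HDR %in% gs$DDR))
  expect_equal(gs$ATM, "ATM")
  expect_setequal(gs$BRCA1_2, c("BRCA1", "BRCA2"))
  bad <- tempfile(fileext = ".yaml")
  writeLines(c("DDR: [BRCA1]", "HDR: [BRCA1, ATM]"), bad)
  expect_error(load_gene_sets(bad), "subset")

  pm <- load_phenotype_map()
  expect_true(all(pm %in% c("CANCER", "CANCER_RISK", "OTHER")))

  preds <- load_group_predicates()
  expect_length(preds, 18L)
  ids <- vapply(preds, `[[`, character(1), "id")
  expect_false(anyDuplicated(ids) > 0)
})

test_that("provenance flags reflect record sources and phenotype curation", {
  pm <- load_phenotype_map()
  ev <- rbind(
    make_evidence(clinvar_sig = "Pathogenic",
                  clinvar_phenotype = "Breast cancer", key = "1:1:A:G"),
    make_evidence(hgmd_class = "DM", hgmd_phenotype = "Cystic fibrosis",
                  key = "1:2:A:G"),
    make_evidence(cosmic = TRUE, cosmic_site = "pancreas", key = "1:3:A:G"),
    make_evidence(tcga = TRUE, tcga_site = "breast", key = "1:4:A:G"),
    make_evidence(key = "1:5:A:G")
  )
  fl <- provenance_flags(ev, pm)
  expect_equal(fl$G, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(fl$S, c(FALSE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(fl$G_C, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(fl$S_PDAC, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  # risk phenotypes also count as cancer-relevant
  ev_risk <- make_evidence(clinvar_sig = "Uncertain_significance",
                           clinvar_phenotype = "Lynch syndrome")
  expect_true(provenance_flags(ev_risk, pm)$G_C)
  # unmapped phenotype: warn, treat as OTHER
  ev_un <- make_evidence(clinvar_sig = "Pathogenic",
                         clinvar_phenotype = "Mystery syndrome")
  expect_warning(fl_un <- provenance_flags(ev_un, pm), "unmapped")
  expect_true(fl_un$G)
  expect_false(fl_un$G_C)
})

test_that("provenance clauses evaluate boolean logic and reject unknown flags", {
  fl <- data.frame(G = c(TRUE, TRUE, FALSE, FALSE),
                   S = c(TRUE, FALSE, TRUE, FALSE),
                   G_C = c(TRUE, TRUE, FALSE, FALSE),
                   S_PDAC = c(FALSE, FALSE, TRUE, FALSE))
  eval_pv <- mtier:::.eval_provenance
  expect_equal(eval_pv("G or S", fl), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(eval_pv("G_C and not S", fl), c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(eval_pv("S and not G_C", fl), c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(eval_pv("", fl), rep(TRUE, 4))
  expect_error(eval_pv("G or EVIL", fl), "unknown flag")
})

test_that("group predicates qualify variants as specified", {
  calls <- data.frame(
    key = paste0("1:", 1:4, ":A:G"),
    gene = c("BRCA2", "ATM", "CFTR", "TP53"),
    class = c("PATHOGENIC", "REPORTED_VUS", "PATHOGENIC", "SOMATIC_VUS"),
    stringsAsFactors = FALSE
  )
  flags <- data.frame(
    key = calls$key,
    G = c(TRUE, TRUE, TRUE, FALSE),
    S = c(FALSE, FALSE, FALSE, TRUE),
    G_C = c(TRUE, TRUE, FALSE, FALSE),
    S_PDAC = c(FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  enrich <- data.frame(
    key = calls$key,
    ratio = c(15, 3, NA, 1),
    polymorphic = c(FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  qual <- variant_group_matrix(calls, flags, enrich,
                               load_group_predicates(), load_gene_sets())
  # variant 1: germline pathogenic cancer BRCA2, 15x enriched
  expect_true(all(qual["1:1:A:G", c("pathogenic", "enriched_10x",
                                    "genetic_cancer",
                                    "genetic_cancer_pathogenic",
                                    "brca1_2", "brca1_2_pathogenic",
                                    "hdr", "hdr_pathogenic",
                                    "germline_cancer_risk")]))
  expect_false(any(qual["1:1:A:G", c("cancer_vus", "somatic_cancer",
                                     "pdac_cancer", "atm")]))
  # variant 2: germline cancer VUS in ATM
  expect_true(all(qual["1:2:A:G", c("cancer_vus", "genetic_cancer",
                                    "atm", "hdr",
                                    "germline_cancer_risk")]))
  expect_false(any(qual["1:2:A:G", c("pathogenic", "atm_pathogenic",
                                     "enriched_10x")]))
  # variant 3: polymorphic variants never trigger any group
  expect_false(any(qual["1:3:A:G", ]))
  # variant 4: somatic pancreas VUS
  expect_true(all(qual["1:4:A:G", c("cancer_vus", "somatic_cancer",
                                    "pdac_cancer")]))
  expect_false(any(qual["1:4:A:G", c("pathogenic", "genetic_cancer",
                                     "germline_cancer_risk")]))
})

test_that("patients join a group iff they carry a qualifying variant", {
  qual <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2,
                 dimnames = list(c("k1", "k2"), c("ga", "gb")))
  dosage <- rbind(k1 = c(1L, 0L, NA), k2 = c(0L, 2L, 0L))
  colnames(dosage) <- c("P1", "P2", "P3")
  out <- assign_groups(qual, dosage)
  expect_equal(out$membership["P1", ], c(ga = TRUE, gb = FALSE))
  expect_equal(out$membership["P2", ], c(ga = FALSE, gb = TRUE))
  expect_false(any(out$membership["P3", ]))
  expect_equal(out$triggers$patient_id, c("P1", "P2"))
  expect_equal(out$triggers$key, c("k1", "k2"))
})

test_that("the enrichment group applies the ratio threshold at the boundary", {
  enrich <- data.frame(key = c("k1", "k2", "k3"),
                       ratio = c(10, 9.999, NA),
                       stringsAsFactors = FALSE)
  dosage <- rbind(k1 = c(1L, 0L), k2 = c(0L, 1L), k3 = c(1L, 1L))
  colnames(dosage) <- c("P1", "P2")
  g <- enrichment_group(enrich, dosage, threshold = 10)
  expect_equal(g, c(P1 = TRUE, P2 = FALSE))
})

test_that("group memberships satisfy logical containments on random cohorts", {
  preds <- load_group_predicates()
  gsets <- load_gene_sets()
  # an explicit DDR group to check the HDR-within-DDR containment
  preds <- c(preds, list(list(id = "ddr", name = "DDR",
                              provenance = "G or S", gene_set = "DDR")))
  for (seed in c(101L, 202L, 303L)) {
    st <- run_small_study(seed)
    qual <- variant_group_matrix(st$calls, st$flags, st$enrichment,
                                 preds, gsets)
    memb <- assign_groups(qual, st$dosage)$membership
    within <- function(a, b) expect_true(all(memb[, b][memb[, a]]))
    # pathogenic-restricted groups sit inside their unrestricted versions
    for (g in c("cancer_either", "genetic_cancer", "somatic_cancer",
                "genetic_somatic_cancer", "atm", "brca1_2", "hdr")) {
      restricted <- paste0(g, "_pathogenic")
      base <- if (g == "cancer_either") "pathogenic" else g
      within(restricted, base)
    }
    # provenance implications
    within("genetic_cancer", "germline_cancer_risk")
    within("genetic_somatic_cancer", "germline_cancer_risk")
    within("cancer_either_pathogenic", "pathogenic")
    # gene-set nesting: ATM and BRCA1/2 are HDR genes; HDR genes are DDR genes
    within("atm", "hdr")
    within("brca1_2", "hdr")
    within("hdr", "ddr")
    # the enrichment-defined group agrees with the predicate route, except
    # that the predicate additionally suppresses polymorphic variants
    eg <- enrichment_group(st$enrichment, st$dosage, threshold = 10)
    pred_memb <- memb[names(eg), "enriched_10x"]
    expect_true(all(eg[pred_memb]))
    if (!any(st$enrichment$polymorphic)) {
      expect_equal(unname(pred_memb), unname(eg))
    }
  }
})
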