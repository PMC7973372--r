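# Default genomics-based patient groups (18). Each group is triggered by any
# carried, non-polymorphic variant satisfying the predicate. Provenance flags:
# G = germline record (ClinVar/HGMD); S = somatic record (COSMIC/TCGA);
# G_C = germline record with a cancer or cancer-risk phenotype;
# S_PDAC = somatic record with pancreas primary site.
- id: pathogenic
  name: Pathogenic
  requires_pathogenic: true
  provenance: G or S
- id: enriched_10x
  name: Population Enriched 10x
  min_ratio: 10
- id: cancer_vus
  name: Cancer VUS
  provenance: G_C or S
  classes: [REPORTED_VUS, SOMATIC_VUS]
- id: cancer_either_pathogenic
  name: Cancer Either Pathogenic
  requires_pathogenic: true
  provenance: G_C or S
- id: genetic_cancer
  name: Genetic Cancer
  provenance: G_C and not S
- id: genetic_cancer_pathogenic
  name: Genetic Cancer Pathogenic
  requires_pathogenic: true
  provenance: G_C and not S
- id: somatic_cancer
  name: Somatic Cancer
  provenance: S and not G_C
- id: somatic_cancer_pathogenic
  name: Somatic Cancer Pathogenic
  requires_pathogenic: true
  provenance: S and not G_C
- id: genetic_somatic_cancer
  name: Genetic, Somatic Cancer
  provenance: G_C and S
- id: genetic_somatic_cancer_pathogenic
  name: Genetic, Somatic Cancer Pathogenic
  requires_pathogenic: true
  provenance: G_C and S
- id: pdac_cancer
  name: PDAC Cancer
  provenance: S_PDAC
- id: atm
  name: ATM
  provenance: G or S
  gene_set: ATM
- id: atm_pathogenic
  name: ATM Pathogenic
  requires_pathogenic: true
  provenance: G or S
  gene_set: ATM
- id: brca1_2
  name: BRCA1/BRCA2
  provenance: G or S
  gene_set: BRCA1_2
- id: brca1_2_pathogenic
  name: BRCA1/BRCA2 Pathogenic
  requires_pathogenic: true
  provenance: G or S
  gene_set: BRCA1_2
- id: hdr
  name: HDR
  provenance: G or S
  gene_set: HDR
- id: hdr_pathogenic
  name: HDR Pathogenic
  requires_pathogenic: true
  provenance: G or S
  gene_set: HDR
- id: germline_cancer_risk
  name: Germline Cancer Risk
  provenance: G_C
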