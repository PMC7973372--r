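#' Normalize a variant to its canonical key
#'
#' Reduces a VCF-style (contig, pos, ref, alt) record to a minimal canonical
#' identity so that cohort records and database records join correctly
#' regardless of how the caller padded or anchored the alleles. The shared
#' suffix is trimmed first, then the shared prefix (advancing `pos`), down to
#' the minimal differing event. The `key` encodes that event
#' ("chrom:pos:ref:alt", with "-" for an empty indel side), so the two
#' anchorings of the same deletion -- e.g. (100, "CTT", "CT") and
#' (101, "TT", "T") -- receive identical keys without needing genome context.
#' The returned `ref`/`alt` columns keep a VCF-valid representation (at least
#' one base each). Chromosome names are unified by stripping a leading "chr".
#' All arguments are vectorized.
#'
#' @param contig chromosome name(s), with or without a "chr" prefix.
#' @param pos 1-based position(s).
#' @param ref,alt allele strings (A/C/G/T only).
#' @return a data.frame with columns `chrom`, `pos`, `ref`, `alt` (trimmed,
#'   VCF-style), and `key` (the canonical minimal-event identity string).
#' @export
normalize_variant <- function(contig, pos, ref, alt) {
  n <- max(length(contig), length(pos), length(ref), length(alt))
  contig <- rep_len(as.character(contig), n)
  pos <- rep_len(as.integer(pos), n)
  ref <- rep_len(toupper(as.character(ref)), n)
  alt <- rep_len(toupper(as.character(alt)), n)
  if (any(is.na(pos)) || any(pos < 1L)) {
    stop("positions must be integers >= 1")
  }
  if (any(!nzchar(ref) | is.na(ref)) || any(!nzchar(alt) | is.na(alt))) {
    stop("ref and alt alleles must be non-empty")
  }
  if (any(grepl("[^ACGT]", ref)) || any(grepl("[^ACGT]", alt))) {
    stop("alleles must contain only A/C/G/T characters")
  }
  if (any(ref == alt)) {
    stop("non-variant record: ref equals alt")
  }
  chrom <- sub("^chr", "", contig)
  key <- character(n)
  for (i in seq_len(n)) {
    r <- strsplit(ref[i], "", fixed = TRUE)[[1]]
    a <- strsplit(alt[i], "", fixed = TRUE)[[1]]
    p <- pos[i]
    # minimal event: full suffix trim, then full prefix trim (may empty a side)
    while (length(r) > 0L && length(a) > 0L && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]
      a <- a[-length(a)]
    }
    while (length(r) > 0L && length(a) > 0L && r[1L] == a[1L]) {
      r <- r[-1L]
      a <- a[-1L]
      p <- p + 1L
    }
    key[i] <- paste(chrom[i], p,
                    if (length(r)) paste(r, collapse = "") else "-",
                    if (length(a)) paste(a, collapse = "") else "-",
                    sep = ":")
    # VCF-valid trimmed representation: same trims but keep >= 1 base each
    r <- strsplit(ref[i], "", fixed = TRUE)[[1]]
    a <- strsplit(alt[i], "", fixed = TRUE)[[1]]
    while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]
      a <- a[-length(a)]
    }
    while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
      r <- r[-1L]
      a <- a[-1L]
      pos[i] <- pos[i] + 1L
    }
    ref[i] <- paste(r, collapse = "")
    alt[i] <- paste(a, collapse = "")
  }
  data.frame(
    chrom = chrom, pos = pos, ref = ref, alt = alt, key = key,
    stringsAsFactors = FALSE
  )
}

#' Split a multi-allelic genotype record into per-alternate dosages
#'
#' @param gt character vector of VCF GT strings (e.g. "0/1", "1|2", "./."),
#'   one per sample.
#' @param n_alt number of alternate alleles at the site.
#' @return integer matrix (samples x alternates) of alternate-allele dosages;
#'   `NA` for missing genotypes.
#' @export
split_multiallelic <- function(gt, n_alt) {
  stopifnot(n_alt >= 1L)
  alleles <- strsplit(gt, "[/|]")
  out <- matrix(0L, nrow = length(gt), ncol = n_alt)
  for (i in seq_along(alleles)) {
    a <- alleles[[i]]
    if (any(a == "." | a == "")) {
      out[i, ] <- NA_integer_
    } else {
      ai <- as.integer(a)
      for (j in seq_len(n_alt)) out[i, j] <- sum(ai == j)
    }
  }
  out
}

#' Read a multi-sample cohort VCF
#'
#' Reads GT genotypes, splits multi-allelic records into one entry per
#' alternate allele, and normalizes every variant to its canonical key.
#'
#' @param path path to a VCF (v4.x) file, plain text or bgzipped.
#' @return list with `variants` (data.frame: chrom, pos, ref, alt, key) and
#'   `dosage` (integer matrix, variants x patients, rownames = keys).
#' @export
read_cohort_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT genotype field")
  keys <- character(0)
  rows <- list()
  dos <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    d <- split_multiallelic(gt[i, ], length(alts))
    for (j in seq_along(alts)) {
      nv <- normalize_variant(fix[i, "CHROM"], as.integer(fix[i, "POS"]),
                              fix[i, "REF"], alts[j])
      rows[[length(rows) + 1L]] <- nv
      dos[[length(dos) + 1L]] <- d[, j]
    }
  }
  variants <- do.call(rbind, rows)
  dosage <- do.call(rbind, dos)
  rownames(dosage) <- variants$key
  colnames(dosage) <- colnames(gt)
  if (anyDuplicated(variants$key)) {
    stop("duplicate variant keys in cohort VCF after normalization")
  }
  list(variants = variants, dosage = dosage)
}

#' Read an annotation snapshot table
#'
#' Snapshot TSVs carry the key columns (chrom, pos, ref, alt) plus
#' source-specific payload columns (see the synthetic generator for the
#' schemas). Keys are normalized on read and must be unique per source.
#'
#' @param path path to a TSV file with a header.
#' @param source one of "CLINVAR", "HGMD", "GNOMAD", "COSMIC", "TCGA".
#' @return data.frame with a normalized `key` column prepended.
#' @export
read_snapshot <- function(path, source = c("CLINVAR", "HGMD", "GNOMAD",
                                           "COSMIC", "TCGA")) {
  source <- match.arg(source)
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("chrom", "pos", "ref", "alt")
  if (!all(required %in% names(x))) {
    stop("snapshot is missing key columns: ",
         paste(setdiff(required, names(x)), collapse = ", "))
  }
  if (nrow(x) == 0L) {
    x$key <- character(0)
    return(x[, c("key", setdiff(names(x), "key"))])
  }
  nv <- normalize_variant(x$chrom, x$pos, x$ref, x$alt)
  x$key <- nv$key
  if (source == "GNOMAD") {
    if (any(x$AC < 0) || any(x$AC > x$AN)) stop("gnomAD snapshot violates 0 <= AC <= AN")
  }
  if (anyDuplicated(x$key)) {
    stop(sprintf("duplicate keys in %s snapshot; pre-deduplicate", source))
  }
  x[, c("key", setdiff(names(x), "key"))]
}

#' Read the per-variant consequence/score table
#'
#' Stands in for annotator output: gene symbol, Sequence Ontology consequence
#' term, and raw scores from six sequence-based tools (absent scores empty or
#' NA).
#'
#' @param path path to a TSV with columns chrom, pos, ref, alt, gene,
#'   consequence, cadd, revel, sift, fathmm, lrt, metalr.
#' @return data.frame keyed by the normalized variant key.
#' @export
read_consequences <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  nv <- normalize_variant(x$chrom, x$pos, x$ref, x$alt)
  x$key <- nv$key
  if (anyDuplicated(x$key)) stop("duplicate keys in consequence table")
  x[, c("key", setdiff(names(x), "key"))]
}

#' Read the clinical table
#'
#' @param path CSV with columns patient_id, age, sex, race, stage, surgery,
#'   ca19_9_producer, ca19_9, os_months, vital_status.
#' @return data.frame of clinical records.
#' @export
read_clinical <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (any(x$os_months < 0, na.rm = TRUE)) stop("negative survival time")
  if (!all(x$vital_status %in% c(0, 1))) stop("vital_status must be 0/1")
  x
}

#' Join cohort variants to the five annotation snapshots
#'
#' Each cohort variant receives at most one record per source; unmatched
#' sources are recorded as absent (NA payloads, FALSE presence flags). The
#' join is by normalized variant key, so row order of the snapshots is
#' irrelevant.
#'
#' @param variants data.frame with a `key` column (from [read_cohort_vcf()]).
#' @param snapshots named list with elements clinvar, hgmd, gnomad, cosmic,
#'   tcga (data.frames from [read_snapshot()]; any may be an empty
#'   data.frame).
#' @return an evidence data.frame, one row per cohort variant: key plus
#'   clinvar_sig, clinvar_phenotype, hgmd_class, hgmd_phenotype, gnomad_ac,
#'   gnomad_an, cosmic, cosmic_site, tcga, tcga_site.
#' @export
join_evidence <- function(variants, snapshots) {
  needed <- c("clinvar", "hgmd", "gnomad", "cosmic", "tcga")
  if (!all(needed %in% names(snapshots))) {
    stop("snapshots must be a named list with elements: ",
         paste(needed, collapse = ", "))
  }
  for (nm in needed) {
    snap <- snapshots[[nm]]
    if (nrow(snap) > 0L && anyDuplicated(snap$key)) {
      stop(sprintf("duplicate keys in %s snapshot", nm))
    }
  }
  pick <- function(snap, col) {
    if (nrow(snap) == 0L) return(rep(NA, nrow(variants)))
    snap[[col]][match(variants$key, snap$key)]
  }
  ev <- data.frame(
    key = variants$key,
    clinvar_sig = as.character(pick(snapshots$clinvar, "clinical_significance")),
    clinvar_phenotype = as.character(pick(snapshots$clinvar, "phenotype")),
    hgmd_class = as.character(pick(snapshots$hgmd, "variant_class")),
    hgmd_phenotype = as.character(pick(snapshots$hgmd, "phenotype")),
    gnomad_ac = as.numeric(pick(snapshots$gnomad, "AC")),
    gnomad_an = as.numeric(pick(snapshots$gnomad, "AN")),
    cosmic_site = as.character(pick(snapshots$cosmic, "primary_site")),
    tcga_site = as.character(pick(snapshots$tcga, "primary_site")),
    stringsAsFactors = FALSE
  )
  ev$cosmic <- if (nrow(snapshots$cosmic)) variants$key %in% snapshots$cosmic$key else rep(FALSE, nrow(variants))
  ev$tcga <- if (nrow(snapshots$tcga)) variants$key %in% snapshots$tcga$key else rep(FALSE, nrow(variants))
  ev
}
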