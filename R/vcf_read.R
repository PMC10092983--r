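# VCF readers for the annotation dialects the filter chains consume.
# Parsing is delegated to vcfR; these functions only map the caller-
# specific FORMAT/INFO fields onto the flat variant-record table.

.read_vcfr <- function(path) {
  if (!file.exists(path)) stop("no such VCF: ", path, call. = FALSE)
  suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
}

.gt_alt_field <- function(vcf, key, sample, idx = 2L) {
  m <- vcfR::extract.gt(vcf, element = key)
  if (is.null(m) || !(sample %in% colnames(m)))
    return(rep(NA_integer_, nrow(vcf@fix)))
  vapply(m[, sample], function(x) {
    if (is.na(x)) return(NA_integer_)
    parts <- strsplit(x, ",", fixed = TRUE)[[1]]
    if (length(parts) < idx) return(NA_integer_)
    as.integer(parts[idx])
  }, 1L, USE.NAMES = FALSE)
}

#' Read a somatic SNV/indel VCF into a variant-record table
#'
#' Expects Mutect2-style annotations: FILTER, per-sample `AD` allele
#' depths, and INFO keys `MAX_AF`, `CADD_PHRED`, `IMPACT` (and optionally
#' `GENE`). The tumor alternate allele count is taken from the tumor
#' sample's `AD` field.
#'
#' @param path VCF file (v4.2, uncompressed or bgzipped).
#' @param tumor_sample,normal_sample Genotype column names
#'   (default `"TUMOR"`, `"NORMAL"`).
#' @return Variant-record data.frame (kind `snv_indel`); zero rows for a
#'   record-less VCF.
#' @export
read_somatic_snv_vcf <- function(path, tumor_sample = "TUMOR",
                                 normal_sample = "NORMAL") {
  vcf <- .read_vcfr(path)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L)
    return(variant_records(data.frame(kind = character(0),
                                      chrom = character(0),
                                      pos = integer(0))))
  df <- data.frame(
    kind = "snv_indel",
    id = fix$ID,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    filter_status = fix$FILTER,
    stringsAsFactors = FALSE)
  df$alt_count <- .gt_alt_field(vcf, "AD", tumor_sample)
  df$max_af <- suppressWarnings(
    as.numeric(vcfR::extract.info(vcf, "MAX_AF")))
  df$cadd_phred <- suppressWarnings(
    as.numeric(vcfR::extract.info(vcf, "CADD_PHRED")))
  df$impact <- vcfR::extract.info(vcf, "IMPACT")
  df$gene <- vcfR::extract.info(vcf, "GENE")
  variant_records(df)
}

#' Read a somatic SV VCF into a variant-record table
#'
#' Expects Manta-style annotations: per-sample `PR` (spanning-pair) and
#' `SR` (split-read) ref,alt support and INFO keys `SOMATICSCORE`,
#' `SVTYPE`, `END`. The matched-normal support is the sum of the normal
#' sample's alternate PR and SR reads.
#'
#' @inheritParams read_somatic_snv_vcf
#' @return Variant-record data.frame (kind `sv`).
#' @export
read_somatic_sv_vcf <- function(path, tumor_sample = "TUMOR",
                                normal_sample = "NORMAL") {
  vcf <- .read_vcfr(path)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L)
    return(variant_records(data.frame(kind = character(0),
                                      chrom = character(0),
                                      pos = integer(0))))
  pr_n <- .gt_alt_field(vcf, "PR", normal_sample)
  sr_n <- .gt_alt_field(vcf, "SR", normal_sample)
  df <- data.frame(
    kind = "sv",
    id = fix$ID,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    svtype = vcfR::extract.info(vcf, "SVTYPE"),
    end = suppressWarnings(as.integer(vcfR::extract.info(vcf, "END"))),
    filter_status = fix$FILTER,
    stringsAsFactors = FALSE)
  df$pr_tumor <- .gt_alt_field(vcf, "PR", tumor_sample)
  df$sr_tumor <- .gt_alt_field(vcf, "SR", tumor_sample)
  df$normal_support <- ifelse(is.na(pr_n) & is.na(sr_n), NA_integer_,
                              ifelse(is.na(pr_n), 0L, pr_n) +
                                ifelse(is.na(sr_n), 0L, sr_n))
  df$somaticscore <- suppressWarnings(
    as.integer(vcfR::extract.info(vcf, "SOMATICSCORE")))
  df$gene <- vcfR::extract.info(vcf, "GENE")
  variant_records(df)
}
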