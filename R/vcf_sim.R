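# Synthetic somatic VCF pairs with known truth labels.
#
# The generator writes one SNV/indel VCF (Mutect2-style annotations:
# FILTER, FORMAT/AD, INFO MAX_AF / CADD_PHRED / IMPACT) and one SV VCF
# (Manta-style: FORMAT/PR, FORMAT/SR, INFO SOMATICSCORE / SVTYPE / END),
# each with TUMOR and NORMAL sample columns. A chosen fraction of records
# is constructed to satisfy every retention criterion; each failing record
# violates exactly one randomly chosen criterion. The generator's
# bookkeeping (the truth table) is the oracle for the filter chain.

.vcf_geno_cols <- c("TUMOR", "NORMAL")

.write_vcf_text <- function(path, meta, records) {
  header <- c("##fileformat=VCFv4.2",
              "##source=ddmrd synthetic somatic variant generator",
              meta,
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "INFO", "FORMAT", .vcf_geno_cols),
                    collapse = "\t"))
  writeLines(c(header, records), path)
  invisible(path)
}

.fmt_info <- function(...) {
  kv <- list(...)
  kv <- kv[!vapply(kv, function(x) is.null(x) || is.na(x), TRUE)]
  if (!length(kv)) return(".")
  paste(sprintf("%s=%s", names(kv), vapply(kv, as.character, "")),
        collapse = ";")
}

#' Generate a synthetic somatic SNV + SV VCF pair with truth labels
#'
#' @param n_snv,n_sv Record counts (>= 0).
#' @param fraction_passing Proportion of records built to satisfy all
#'   retention criteria; the rest each violate exactly one criterion.
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @param gene_lists Gene lists used to draw plausible gene symbols
#'   (default the bundled lists).
#' @return List with `snv_vcf`, `sv_vcf` (file paths) and `truth`: a list
#'   of two data.frames keyed by record `id`, carrying every generated
#'   annotation and the logical column `passes`.
#' @examples
#' \donttest{
#' sim <- simulate_somatic_vcf_pair(20, 10, 0.3, seed = 1,
#'                                  dir = tempdir())
#' table(sim$truth$snv$passes)
#' }
#' @export
simulate_somatic_vcf_pair <- function(n_snv, n_sv, fraction_passing,
                                      seed, dir = tempdir(),
                                      gene_lists = read_gene_lists()) {
  stopifnot(n_snv >= 0, n_sv >= 0,
            fraction_passing >= 0, fraction_passing <= 1)
  if (missing(seed)) stop("`seed` must be supplied", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  snv_path <- file.path(dir, "synthetic_somatic_snv.vcf")
  sv_path  <- file.path(dir, "synthetic_somatic_sv.vcf")
  genes <- c(gene_lists$mb_recurrent, gene_lists$cancer_census,
             sprintf("GENE%03d", 1:40))

  out <- withr::with_seed(seed, {
    list(snv = .gen_snv(n_snv, fraction_passing, genes),
         sv  = .gen_sv(n_sv, fraction_passing, genes))
  })

  snv_meta <- c(
    '##INFO=<ID=MAX_AF,Number=1,Type=Float,Description="Maximum population allele frequency across gnomAD-style panels">',
    '##INFO=<ID=CADD_PHRED,Number=1,Type=Float,Description="CADD PHRED-scaled deleteriousness score">',
    '##INFO=<ID=IMPACT,Number=1,Type=String,Description="Predicted functional impact class">',
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths for the ref and alt alleles">',
    '##FILTER=<ID=germline_risk,Description="Possible germline variant">',
    '##FILTER=<ID=panel_of_normals,Description="Seen in panel of normals">')
  sv_meta <- c(
    '##INFO=<ID=SOMATICSCORE,Number=1,Type=Integer,Description="Somatic variant quality score">',
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Type of structural variant">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End position of the variant">',
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##ALT=<ID=DEL,Description="Deletion">',
    '##ALT=<ID=DUP,Description="Duplication">',
    '##ALT=<ID=INV,Description="Inversion">',
    '##FORMAT=<ID=PR,Number=.,Type=Integer,Description="Spanning paired-read support for the ref and alt alleles">',
    '##FORMAT=<ID=SR,Number=.,Type=Integer,Description="Split-read support for the ref and alt alleles">',
    '##FILTER=<ID=MinSomaticScore,Description="Somatic score below threshold">')

  .write_vcf_text(snv_path, snv_meta, out$snv$lines)
  .write_vcf_text(sv_path, sv_meta, out$sv$lines)
  list(snv_vcf = snv_path, sv_vcf = sv_path,
       truth = list(snv = out$snv$truth, sv = out$sv$truth))
}

.n_passing <- function(n, fraction) {
  np <- round(n * fraction)
  passes <- rep(FALSE, n)
  if (np > 0) passes[sample.int(n, np)] <- TRUE
  passes
}

.gen_snv <- function(n, fraction_passing, genes) {
  if (n == 0L)
    return(list(lines = character(0),
                truth = data.frame(id = character(0), passes = logical(0))))
  passes <- .n_passing(n, fraction_passing)
  bases <- c("A", "C", "G", "T")
  truth <- data.frame(
    id = sprintf("snv_%04d", seq_len(n)),
    chrom = paste0("chr", sample(1:22, n, replace = TRUE)),
    pos = sample.int(2e8, n), stringsAsFactors = FALSE)
  truth$ref <- sample(bases, n, replace = TRUE)
  truth$alt <- vapply(truth$ref, function(r)
    sample(setdiff(bases, r), 1L), "")
  truth$gene <- sample(genes, n, replace = TRUE)
  truth$filter_status <- "PASS"
  truth$ref_count <- sample(20:100, n, replace = TRUE)
  truth$alt_count <- sample(5:60, n, replace = TRUE)
  truth$max_af <- ifelse(stats::runif(n) < 0.5, NA,
                         stats::runif(n, 0, 0.001))
  truth$cadd_phred <- ifelse(stats::runif(n) < 0.3, NA,
                             stats::runif(n, 20, 40))
  truth$impact <- sample(c("HIGH", "MODERATE"), n, replace = TRUE)

  fail_mode <- sample(5L, n, replace = TRUE)
  for (i in which(!passes)) {
    switch(fail_mode[i],
      truth$filter_status[i] <- sample(c("germline_risk",
                                         "panel_of_normals"), 1L),
      truth$alt_count[i] <- sample(0:4, 1L),
      truth$max_af[i] <- stats::runif(1L, 0.0015, 0.05),
      truth$cadd_phred[i] <- stats::runif(1L, 0, 19.5),
      truth$impact[i] <- sample(c("LOW", "MODIFIER"), 1L))
  }
  truth$passes <- passes

  lines <- vapply(seq_len(n), function(i) {
    r <- truth[i, ]
    paste(c(r$chrom, r$pos, r$id, r$ref, r$alt, ".", r$filter_status,
            .fmt_info(MAX_AF = if (is.na(r$max_af)) NA else
                        sprintf("%.6f", r$max_af),
                      CADD_PHRED = if (is.na(r$cadd_phred)) NA else
                        sprintf("%.2f", r$cadd_phred),
                      IMPACT = r$impact, GENE = r$gene),
            "AD",
            sprintf("%d,%d", r$ref_count, r$alt_count),
            sprintf("%d,0", sample(20:100, 1L))),
          collapse = "\t")
  }, "")
  # round MAX_AF/CADD in truth to what the VCF text carries
  truth$max_af <- ifelse(is.na(truth$max_af), NA,
                         round(truth$max_af, 6))
  truth$cadd_phred <- ifelse(is.na(truth$cadd_phred), NA,
                             round(truth$cadd_phred, 2))
  list(lines = lines, truth = truth)
}

.gen_sv <- function(n, fraction_passing, genes) {
  if (n == 0L)
    return(list(lines = character(0),
                truth = data.frame(id = character(0), passes = logical(0))))
  passes <- .n_passing(n, fraction_passing)
  truth <- data.frame(
    id = sprintf("sv_%04d", seq_len(n)),
    chrom = paste0("chr", sample(1:22, n, replace = TRUE)),
    pos = sample.int(2e8, n), stringsAsFactors = FALSE)
  truth$svtype <- sample(c("DEL", "DUP", "INV"), n, replace = TRUE)
  truth$end <- truth$pos + sample(1000:5e6, n, replace = TRUE)
  truth$gene <- sample(genes, n, replace = TRUE)
  truth$filter_status <- "PASS"
  truth$pr_tumor <- sample(5:60, n, replace = TRUE)
  truth$sr_tumor <- sample(5:60, n, replace = TRUE)
  truth$normal_support <- sample(0:1, n, replace = TRUE)
  truth$somaticscore <- sample(50:250, n, replace = TRUE)

  fail_mode <- sample(5L, n, replace = TRUE)
  for (i in which(!passes)) {
    switch(fail_mode[i],
      truth$filter_status[i] <- "MinSomaticScore",
      truth$pr_tumor[i] <- sample(0:4, 1L),
      truth$sr_tumor[i] <- sample(0:4, 1L),
      truth$normal_support[i] <- sample(2:10, 1L),
      truth$somaticscore[i] <- sample(0:49, 1L))
  }
  truth$passes <- passes

  lines <- vapply(seq_len(n), function(i) {
    r <- truth[i, ]
    # split the normal support between PR and SR
    nr_pr <- sample(0:r$normal_support, 1L)
    nr_sr <- r$normal_support - nr_pr
    paste(c(r$chrom, r$pos, r$id, "N", sprintf("<%s>", r$svtype), ".",
            r$filter_status,
            .fmt_info(SOMATICSCORE = r$somaticscore, SVTYPE = r$svtype,
                      END = r$end, GENE = r$gene),
            "PR:SR",
            sprintf("%d,%d:%d,%d", sample(20:100, 1L), r$pr_tumor,
                    sample(20:100, 1L), r$sr_tumor),
            sprintf("%d,%d:%d,%d", sample(20:100, 1L), nr_pr,
                    sample(20:100, 1L), nr_sr)),
          collapse = "\t")
  }, "")
  list(lines = lines, truth = truth)
}
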