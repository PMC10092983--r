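# Somatic filter chains, gene-list prioritization, timepoint
# intersection, and the VCF round trip against generator truth.

test_that("SNV filter honours every boundary of the retention rule", {
  keep <- function(r) nrow(filter_somatic_snv(r)) == 1L
  expect_true(keep(snv_rec(alt_count = 5, cadd_phred = 25,
                           impact = "MODERATE")))
  expect_false(keep(snv_rec(alt_count = 4)))
  expect_true(keep(snv_rec(max_af = 0.001)))   # inclusive boundary
  expect_false(keep(snv_rec(max_af = 0.01)))
  expect_true(keep(snv_rec(max_af = NA)))      # absence tolerated
  expect_true(keep(snv_rec(cadd_phred = 20)))
  expect_false(keep(snv_rec(cadd_phred = 19.9)))
  expect_true(keep(snv_rec(cadd_phred = NA)))  # absence tolerated
  expect_true(keep(snv_rec(impact = "HIGH")))
  expect_false(keep(snv_rec(impact = "LOW")))
  expect_false(keep(snv_rec(filter_status = "germline_risk")))
  # missing impact annotation rejects with a reason, never crashes
  out <- filter_somatic_snv(snv_rec(impact = NA))
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "rejected")$reason, "unannotated")
})

test_that("SV filter honours every boundary of the retention rule", {
  keep <- function(r) nrow(filter_somatic_sv(r)) == 1L
  expect_true(keep(sv_rec(pr_tumor = 5, sr_tumor = 5,
                          normal_support = 1, somaticscore = 50)))
  expect_false(keep(sv_rec(pr_tumor = 4)))
  expect_false(keep(sv_rec(sr_tumor = 4)))
  expect_false(keep(sv_rec(normal_support = 2)))
  expect_false(keep(sv_rec(somaticscore = 49)))
  expect_false(keep(sv_rec(filter_status = "MinSomaticScore")))
  out <- filter_somatic_sv(sv_rec(pr_tumor = NA))
  expect_equal(attr(out, "rejected")$reason, "unannotated")
})

test_that("filters are idempotent, subsetting and threshold-monotone", {
  sim <- simulate_somatic_vcf_pair(100, 50, 0.4, seed = 77,
                                   dir = withr::local_tempdir())
  snv <- read_somatic_snv_vcf(sim$snv_vcf)
  out1 <- filter_somatic_snv(snv)
  out2 <- filter_somatic_snv(out1)
  expect_equal(out2$id, out1$id)          # idempotent
  expect_true(all(out1$id %in% snv$id))   # subset
  # tightening any threshold never adds a record
  tight <- selection_criteria(snv = list(min_alt_count = 10,
                                         max_af = 0.0005, min_cadd = 25,
                                         impacts = "HIGH",
                                         require_pass = TRUE))
  expect_true(all(filter_somatic_snv(snv, tight)$id %in% out1$id))
  sv <- read_somatic_sv_vcf(sim$sv_vcf)
  out_sv <- filter_somatic_sv(sv)
  tight_sv <- selection_criteria(sv = list(min_pr = 10, min_sr = 10,
                                           max_normal_support = 0,
                                           min_somaticscore = 100,
                                           require_pass = TRUE))
  expect_true(all(filter_somatic_sv(sv, tight_sv)$id %in% out_sv$id))
})

test_that("filter output equals the generator truth table exactly", {
  sim <- simulate_somatic_vcf_pair(100, 50, 0.3, seed = 123,
                                   dir = withr::local_tempdir())
  snv <- filter_somatic_snv(read_somatic_snv_vcf(sim$snv_vcf))
  sv <- filter_somatic_sv(read_somatic_sv_vcf(sim$sv_vcf))
  expect_setequal(snv$id, sim$truth$snv$id[sim$truth$snv$passes])
  expect_setequal(sv$id, sim$truth$sv$id[sim$truth$sv$passes])
})

test_that("empty and fully-passing VCFs behave as constructed", {
  d <- withr::local_tempdir()
  sim0 <- simulate_somatic_vcf_pair(0, 0, 0.5, seed = 5, dir = d)
  expect_equal(nrow(read_somatic_snv_vcf(sim0$snv_vcf)), 0L)
  expect_equal(nrow(read_somatic_sv_vcf(sim0$sv_vcf)), 0L)
  sim1 <- simulate_somatic_vcf_pair(30, 20, 1, seed = 6, dir = d)
  expect_equal(nrow(filter_somatic_snv(
    read_somatic_snv_vcf(sim1$snv_vcf))), 30L)
  expect_equal(nrow(filter_somatic_sv(
    read_somatic_sv_vcf(sim1$sv_vcf))), 20L)
})

test_that("prioritization ranks by gene-list tier, then read support", {
  gl <- list(mb_recurrent = c("CTNNB1", "PRDM6"),
             cancer_census = c("PTEN", "KRAS"))
  recs <- rbind(
    variant_records(snv_rec(gene = "PTEN", alt_count = 10, pos = 1L)),
    variant_records(sv_rec(gene = "GENE009", pr_tumor = 40,
                           sr_tumor = 45, pos = 2L)),
    variant_records(snv_rec(gene = "GENE008", alt_count = 12, pos = 3L)),
    variant_records(snv_rec(gene = "GENE007", alt_count = 7, pos = 4L)),
    variant_records(snv_rec(gene = "CTNNB1", alt_count = 6, pos = 5L)))
  ranked <- prioritize_targets(recs, gl)
  # MB-recurrent beats census beats others, whatever the support
  expect_equal(ranked$gene[1], "CTNNB1")
  expect_equal(ranked$gene[2], "PTEN")
  # same tier: read support descending (SV support is min(PR, SR) = 40)
  expect_equal(ranked$gene[3:5], c("GENE009", "GENE008", "GENE007"))
  # mixed panel: best SNV and best SV both selected
  sel <- ranked[ranked$selected, ]
  expect_true(any(sel$kind == "snv_indel") && any(sel$kind == "sv"))
})

test_that("a single surviving target raises the under-target flag", {
  one <- prioritize_targets(variant_records(snv_rec()), min_targets = 2)
  expect_true(attr(one, "under_target"))
  expect_equal(sum(one$selected), 1L)
  expect_warning(prioritize_targets(
    variant_records(snv_rec())[0, ], min_targets = 2), "empty panel")
})

test_that("timepoint intersection matches SNVs exactly and SVs by window", {
  p <- rbind(variant_records(snv_rec(pos = 100L)),
             variant_records(snv_rec(pos = 200L, alt = "G")),
             variant_records(sv_rec(pos = 5000L, end = 9000L)),
             variant_records(sv_rec(pos = 70000L, end = 90000L,
                                    chrom = "chr9")))
  r <- rbind(variant_records(snv_rec(pos = 100L)),
             variant_records(sv_rec(pos = 5003L, end = 8998L)))
  shared <- intersect_timepoints(p, r)
  expect_equal(nrow(shared), 2L)
  expect_setequal(shared$pos, c(100L, 5000L))
  # a breakpoint 11 bp away misses the default +/- 10 bp window
  r_far <- variant_records(sv_rec(pos = 5011L, end = 9000L))
  expect_equal(nrow(intersect_timepoints(
    variant_records(sv_rec(pos = 5000L)), r_far)), 0L)
})

test_that("bundled gene lists load and feed prioritization", {
  gl <- read_gene_lists()
  expect_true("CTNNB1" %in% gl$mb_recurrent)
  expect_true(length(gl$cancer_census) > 10)
  expect_false(any(startsWith(unlist(gl), "#")))
})
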