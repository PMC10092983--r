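Package: ddmrd
Title: Tumor-Informed Measurable Residual Disease Detection by Droplet
    Digital PCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for tumor-informed measurable residual
    disease (MRD) analysis of liquid biopsies by droplet digital PCR
    (ddPCR). Selects patient-specific assay targets from somatic SNV/indel
    and structural-variant call sets via explicit post-calling filter
    chains and gene-list prioritization; derives amplitude gates from
    control wells and classifies droplets in amplitude-multiplexed
    two-channel data; quantifies template concentrations by Poisson
    partition statistics with exact 95% confidence intervals, merges
    replicate wells, and converts results to copies, haploid genomic
    equivalents, and DNA mass per mL of biofluid; estimates per-assay
    false-positive rates from negative-control plates and applies
    positive/trace-positive/negative decision rules, including limit-of-
    detection assessment on dilution series. Ships a synthetic-data module
    that emulates Poisson partitioning, Gaussian amplitude clusters, rain,
    false-positive events, negative-control plates, dilution series, and
    annotated somatic VCFs so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
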