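# Shared fixtures: amplitude models, hand-built wells and classified-well
# skeletons used across the module tests.

VD <- 0.85 / 1000  # droplet volume, µL

fix_amp_model <- function(n_targets = 1L, rain = 0, fp = 0) {
  means <- seq(4000, by = 2500, length.out = n_targets)
  amplitude_model(
    target_bands = data.frame(target_id = paste0("T", seq_len(n_targets)),
                              mean_fam = means, sd_fam = 150),
    rain_fraction = rain, fp_rate = fp)
}

# a droplet well built directly from normal clusters (no simulator)
fix_well <- function(n_neg, band_counts = integer(0), band_means = numeric(0),
                     role = "sample", well_id = "A01", sample_id = "s",
                     hex_ref_frac = 0.1, seed = 1) {
  withr::with_seed(seed, {
    fam <- c(stats::rnorm(n_neg, 1000, 100),
             unlist(mapply(function(k, mu) stats::rnorm(k, mu, 150),
                           band_counts, band_means, SIMPLIFY = FALSE)))
    n <- length(fam)
    hex <- ifelse(stats::runif(n) < hex_ref_frac,
                  stats::rnorm(n, 4500, 150), stats::rnorm(n, 900, 90))
    droplet_well(well_id, sample_id, role,
                 data.frame(fam = fam, hex = hex))
  })
}

# classified-well skeleton with prescribed counts, bypassing amplitudes
fix_classified <- function(k, n, target = "T1", hex_positive = 0,
                           well_id = "A01", sample_id = "s",
                           role = "sample", replicate_group = sample_id,
                           biofluid_volume_ml = NA_real_) {
  structure(list(
    well_id = well_id, sample_id = sample_id, role = role,
    replicate_group = replicate_group,
    biofluid_volume_ml = biofluid_volume_ml,
    counts = data.frame(target_id = target, target_only = as.integer(k),
                        target_and_reference = 0L,
                        stringsAsFactors = FALSE),
    empty = as.integer(n - k - hex_positive),
    reference_only = as.integer(hex_positive),
    unassigned = 0L, hex_positive = as.integer(hex_positive),
    total_droplets = as.integer(n), gates = NULL
  ), class = "classified_well")
}

# single-row variant records with overridable annotation fields
snv_rec <- function(...) {
  defaults <- list(kind = "snv_indel", chrom = "chr1", pos = 1000L,
                   ref = "A", alt = "T", filter_status = "PASS",
                   alt_count = 10L, max_af = NA, cadd_phred = NA,
                   impact = "MODERATE", gene = "GENE001")
  args <- utils::modifyList(defaults, list(...))
  as.data.frame(args, stringsAsFactors = FALSE)
}

sv_rec <- function(...) {
  defaults <- list(kind = "sv", chrom = "chr2", pos = 5000L,
                   end = 9000L, svtype = "DEL", filter_status = "PASS",
                   pr_tumor = 10L, sr_tumor = 10L, normal_support = 0L,
                   somaticscore = 80L, gene = "GENE002")
  args <- utils::modifyList(defaults, list(...))
  as.data.frame(args, stringsAsFactors = FALSE)
}

fix_gates <- function(n_targets = 1L) {
  means <- seq(4000, by = 2500, length.out = n_targets)
  gate_set(2000, 2700,
           data.frame(target_id = paste0("T", seq_len(n_targets)),
                      fam_low = means - 800, fam_high = means + 800))
}
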