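# Synthetic droplet-level ddPCR data.
#
# The generator reproduces the statistical structure the analysis assumes:
# Poisson partitioning of template molecules into droplets (each droplet is
# positive for a template with probability 1 - exp(-c * V_d)), Gaussian
# amplitude clusters per FAM band with optional rain, a HEX reference band,
# and Poisson-distributed false-positive droplets per well. It makes no
# attempt to model thermal cycling, probe chemistry or droplet generation
# failure modes.

# deterministic per-well stream derived from one plate seed
.derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(i)) %% 2147483647)
}

#' Simulate one ddPCR well
#'
#' Each droplet is positive for each template independently with
#' probability `p = 1 - exp(-c * V_d)` where `c` is the template
#' concentration in copies/µL of reaction and `V_d` the droplet volume in
#' µL. Droplets positive for a target draw their FAM amplitude from that
#' target's band (droplets hit by more than one target template are
#' assigned to the highest band); reference-positive droplets draw HEX from
#' the reference band; all other amplitudes come from the negative
#' clusters. A `Poisson(fp_rate)` number of template-negative droplets is
#' relabelled into a random target band (false positives), and a
#' `rain_fraction` share of target-positive droplets gets a FAM amplitude
#' uniform between the negative-cluster mean and its band mean.
#'
#' @param target_concentrations Named numeric vector, copies/µL of reaction
#'   per target; names must match the amplitude model's target bands. All
#'   values must be >= 0.
#' @param reference_concentration Reference template concentration,
#'   copies/µL of reaction, >= 0.
#' @param amplitude_model An [amplitude_model()].
#' @param well_spec A [well_spec()].
#' @param seed Integer seed; the same seed reproduces the identical well.
#' @param well_id,sample_id,role,replicate_group,biofluid_volume_ml
#'   Manifest metadata passed to [droplet_well()].
#' @return A [droplet_well()].
#' @examples
#' am <- amplitude_model()
#' w  <- simulate_well(c(T1 = 2), 100, am, well_spec(), seed = 1)
#' nrow(w$droplets)
#' @export
simulate_well <- function(target_concentrations,
                          reference_concentration,
                          amplitude_model,
                          well_spec = ddmrd::well_spec(),
                          seed,
                          well_id = "A01",
                          sample_id = "sim",
                          role = "sample",
                          replicate_group = sample_id,
                          biofluid_volume_ml = NA_real_) {
  stopifnot(inherits(amplitude_model, "amplitude_model"),
            inherits(well_spec, "well_spec"))
  if (missing(seed)) stop("`seed` must be supplied", call. = FALSE)
  bands <- amplitude_model$target_bands
  if (is.null(names(target_concentrations)) && length(target_concentrations))
    stop("`target_concentrations` must be named by target_id", call. = FALSE)
  if (!all(names(target_concentrations) %in% bands$target_id))
    stop("unknown target id in `target_concentrations`", call. = FALSE)
  if (any(target_concentrations < 0) || reference_concentration < 0)
    stop("concentrations must be >= 0", call. = FALSE)

  n  <- well_spec$n_droplets
  vd <- .vd_ul(well_spec$droplet_volume_nl)
  am <- amplitude_model

  droplets <- withr::with_seed(seed, {
    fam <- stats::rnorm(n, am$negative_mean_fam, am$negative_sd_fam)
    hex <- stats::rnorm(n, am$negative_mean_hex, am$negative_sd_hex)

    # which band occupies each droplet: 0 = none, else row index into bands
    # (highest band wins when several templates share a droplet)
    band_of <- integer(n)
    for (i in seq_len(nrow(bands))) {
      cc <- target_concentrations[bands$target_id[i]]
      cc <- if (is.na(cc)) 0 else unname(cc)
      if (cc > 0) {
        hit <- stats::runif(n) < (1 - exp(-cc * vd))
        band_of[hit] <- i
      }
    }

    # false positives among template-negative droplets
    nfp <- stats::rpois(1L, am$fp_rate)
    if (nfp > 0L) {
      free <- which(band_of == 0L)
      nfp  <- min(nfp, length(free))
      pick <- if (length(free) == 1L) free else sample(free, nfp)
      band_of[pick] <- sample.int(nrow(bands), nfp, replace = TRUE)
    }

    pos <- which(band_of > 0L)
    if (length(pos)) {
      mu <- bands$mean_fam[band_of[pos]]
      sd <- bands$sd_fam[band_of[pos]]
      fam[pos] <- stats::rnorm(length(pos), mu, sd)
      if (am$rain_fraction > 0) {
        is_rain <- stats::runif(length(pos)) < am$rain_fraction
        if (any(is_rain))
          fam[pos[is_rain]] <- stats::runif(sum(is_rain),
                                            am$negative_mean_fam,
                                            mu[is_rain])
      }
    }

    if (reference_concentration > 0) {
      ref_hit <- stats::runif(n) < (1 - exp(-reference_concentration * vd))
      nref <- sum(ref_hit)
      if (nref)
        hex[ref_hit] <- stats::rnorm(nref, am$reference_mean_hex,
                                     am$reference_sd_hex)
    }
    data.frame(fam = fam, hex = hex)
  })

  droplet_well(well_id, sample_id, role, droplets,
               replicate_group = replicate_group,
               biofluid_volume_ml = biofluid_volume_ml)
}

#' Simulate a limit-of-detection dilution series
#'
#' Ten-fold dilutions of tumor (positive-control) genomic DNA in normal
#' genomic DNA at a constant total input per well. At each step the tumor
#' target copies loaded are `total_mass_ng * dilution * 1000 / pg_per_hge`
#' and the reference assay sees the full input mass (tumor plus normal
#' background), so the reference concentration is constant across steps.
#'
#' @param dilutions Strictly decreasing tumor mass fractions in `(0, 1]`
#'   (default `10^-(1:4)`).
#' @param total_mass_ng Total gDNA input per well in ng (default 10).
#' @param assay Target id of the assay under test (must be a band in
#'   `amplitude_model`).
#' @param amplitude_model,well_spec,seed As in [simulate_well()].
#' @param wells_per_step Replicate wells per dilution step (default 1).
#' @param pg_per_hge Mass of one haploid genome equivalent (default 3.3 pg).
#' @return A list of [droplet_well()]s with attribute `"truth"`: a
#'   data.frame with one row per well giving `dilution`, `tumor_mass_pg`,
#'   `tumor_hge` and the loaded concentrations.
#' @examples
#' am <- amplitude_model()
#' ser <- simulate_dilution_series(assay = "T1", amplitude_model = am,
#'                                 seed = 7)
#' attr(ser, "truth")
#' @export
simulate_dilution_series <- function(dilutions = 10^-(1:4),
                                     total_mass_ng = 10,
                                     assay,
                                     amplitude_model,
                                     well_spec = ddmrd::well_spec(),
                                     seed,
                                     wells_per_step = 1L,
                                     pg_per_hge = ddmrd_constants$pg_per_hge) {
  if (any(dilutions <= 0) || any(dilutions > 1))
    stop("dilutions must lie in (0, 1]", call. = FALSE)
  if (any(diff(dilutions) >= 0))
    stop("dilutions must be strictly decreasing", call. = FALSE)
  .assert_scalar_num(total_mass_ng, "total_mass_ng", lower = 0, strict = TRUE)
  if (missing(seed)) stop("`seed` must be supplied", call. = FALSE)

  ref_copies <- total_mass_ng * 1000 / pg_per_hge
  ref_conc   <- ref_copies / well_spec$reaction_volume_ul

  wells <- list()
  truth <- NULL
  k <- 0L
  for (s in seq_along(dilutions)) {
    mass_pg <- total_mass_ng * dilutions[s] * 1000
    hge     <- mass_pg / pg_per_hge
    conc    <- hge / well_spec$reaction_volume_ul
    for (r in seq_len(wells_per_step)) {
      k <- k + 1L
      wid <- sprintf("D%02d_%d", s, r)
      wells[[k]] <- simulate_well(
        stats::setNames(conc, assay), ref_conc, amplitude_model, well_spec,
        seed = .derive_seed(seed, k), well_id = wid,
        sample_id = sprintf("dil_%g", dilutions[s]), role = "PC_gDNA",
        replicate_group = sprintf("dil_%g", dilutions[s]))
      truth <- rbind(truth, data.frame(
        well_id = wid, dilution = dilutions[s], tumor_mass_pg = mass_pg,
        tumor_hge = hge, tumor_copies_per_ul = conc,
        reference_copies_per_ul = ref_conc))
    }
  }
  attr(wells, "truth") <- truth
  wells
}

#' Simulate a negative-control cfDNA plate
#'
#' Wells carry reference template but zero true target template;
#' target-band droplets appear only as false positives, `Poisson(fp_rate)`
#' per well. Used to estimate per-assay false-positive rates.
#'
#' @param n_wells Number of NC wells (default 12, one standard plate
#'   complement).
#' @param fp_rate Expected false-positive droplets per well, >= 0.
#' @param amplitude_model,well_spec,seed As in [simulate_well()].
#' @param reference_concentration Reference template copies/µL of reaction
#'   in the NC cfDNA (default 50).
#' @return A list of [droplet_well()]s with role `"NC_cfDNA"`.
#' @export
simulate_nc_plate <- function(n_wells = ddmrd_constants$nc_plate_wells,
                              fp_rate,
                              amplitude_model,
                              well_spec = ddmrd::well_spec(),
                              seed,
                              reference_concentration = 50) {
  if (n_wells < 1L) stop("`n_wells` must be >= 1", call. = FALSE)
  .assert_scalar_num(fp_rate, "fp_rate", lower = 0)
  if (missing(seed)) stop("`seed` must be supplied", call. = FALSE)
  am <- amplitude_model
  am$fp_rate <- fp_rate
  zero <- stats::setNames(numeric(nrow(am$target_bands)),
                          am$target_bands$target_id)
  lapply(seq_len(n_wells), function(i) {
    simulate_well(zero, reference_concentration, am, well_spec,
                  seed = .derive_seed(seed, i),
                  well_id = sprintf("N%02d", i),
                  sample_id = "NC_cfDNA", role = "NC_cfDNA",
                  replicate_group = "NC_cfDNA")
  })
}
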