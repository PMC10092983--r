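#' Amplitude model for simulated two-channel droplet data
#'
#' Describes the fluorescence geometry of a simulated amplitude-multiplexed
#' ddPCR assay: a negative cluster in each channel, one FAM positive band
#' per target (amplitude multiplexing separates targets by FAM level), and
#' one HEX positive band for the reference assay. Real instruments report
#' arbitrary fluorescence units and the cluster positions are assay- and
#' run-specific; the defaults here are synthetic conventions chosen so that
#' neighbouring clusters are separated by at least 5 standard deviations
#' and are therefore cleanly resolvable by rectangular gates.
#'
#' @param target_bands data.frame with columns `target_id` (character),
#'   `mean_fam`, `sd_fam`: one FAM positive band per multiplexed target.
#' @param negative_mean_fam,negative_sd_fam Negative-cluster FAM amplitude
#'   mean and SD (a.u.).
#' @param negative_mean_hex,negative_sd_hex Negative-cluster HEX amplitude
#'   mean and SD (a.u.).
#' @param reference_mean_hex,reference_sd_hex HEX positive band of the
#'   reference assay (a.u.).
#' @param rain_fraction Proportion of template-positive droplets whose FAM
#'   amplitude is drawn uniformly between the negative-cluster mean and
#'   their band mean ("rain"), in `[0, 1]`.
#' @param fp_rate Expected number of false-positive droplets per well
#'   (droplets relabelled into a random target band with no template),
#'   must be >= 0.
#'
#' @return An object of class `amplitude_model`.
#' @examples
#' am <- amplitude_model()
#' am$target_bands
#' @export
amplitude_model <- function(target_bands = data.frame(
                              target_id = "T1",
                              mean_fam  = 6000,
                              sd_fam    = 150,
                              stringsAsFactors = FALSE),
                            negative_mean_fam = 1000,
                            negative_sd_fam   = 100,
                            negative_mean_hex = 900,
                            negative_sd_hex   = 90,
                            reference_mean_hex = 4500,
                            reference_sd_hex   = 150,
                            rain_fraction = 0.01,
                            fp_rate       = 0) {
  stopifnot(is.data.frame(target_bands),
            all(c("target_id", "mean_fam", "sd_fam") %in% names(target_bands)))
  if (anyDuplicated(target_bands$target_id))
    stop("target band ids must be unique", call. = FALSE)
  .assert_scalar_num(rain_fraction, "rain_fraction", lower = 0)
  if (rain_fraction > 1) stop("`rain_fraction` must be <= 1", call. = FALSE)
  .assert_scalar_num(fp_rate, "fp_rate", lower = 0)

  ord <- order(target_bands$mean_fam)
  target_bands <- target_bands[ord, , drop = FALSE]
  rownames(target_bands) <- NULL

  # resolvability: every band >= 5 SD above the negative cluster, and
  # neighbouring bands >= 5 SD apart (larger SD of the pair)
  gap_neg <- target_bands$mean_fam - negative_mean_fam
  if (any(gap_neg < 5 * pmax(negative_sd_fam, target_bands$sd_fam)))
    stop("every target band must exceed the negative FAM cluster by >= 5 SD",
         call. = FALSE)
  if (nrow(target_bands) > 1L) {
    d  <- diff(target_bands$mean_fam)
    sd <- pmax(target_bands$sd_fam[-1L],
               target_bands$sd_fam[-nrow(target_bands)])
    if (any(d < 5 * sd))
      stop("target bands must be pairwise separated by >= 5 SD", call. = FALSE)
  }
  if (reference_mean_hex - negative_mean_hex <
      5 * max(negative_sd_hex, reference_sd_hex))
    stop("reference HEX band must exceed the negative HEX cluster by >= 5 SD",
         call. = FALSE)

  structure(list(
    target_bands       = target_bands,
    negative_mean_fam  = negative_mean_fam,
    negative_sd_fam    = negative_sd_fam,
    negative_mean_hex  = negative_mean_hex,
    negative_sd_hex    = negative_sd_hex,
    reference_mean_hex = reference_mean_hex,
    reference_sd_hex   = reference_sd_hex,
    rain_fraction      = rain_fraction,
    fp_rate            = fp_rate
  ), class = "amplitude_model")
}

#' Physical specification of one simulated ddPCR well
#'
#' @param n_droplets Accepted droplets per well (default 16000).
#' @param droplet_volume_nl Droplet volume in nL (default 0.85, the QX200
#'   nominal partition volume).
#' @param reaction_volume_ul Reaction volume in µL (default 22).
#' @param eluate_loaded_ul Template eluate loaded per well in µL
#'   (default 11).
#' @return An object of class `well_spec`.
#' @examples
#' well_spec()
#' @export
well_spec <- function(n_droplets = ddmrd_constants$n_droplets,
                      droplet_volume_nl = ddmrd_constants$droplet_volume_nl,
                      reaction_volume_ul = ddmrd_constants$reaction_volume_ul,
                      eluate_loaded_ul = ddmrd_constants$eluate_loaded_ul) {
  .assert_scalar_num(n_droplets, "n_droplets", lower = 0, strict = TRUE)
  .assert_scalar_num(droplet_volume_nl, "droplet_volume_nl",
                     lower = 0, strict = TRUE)
  .assert_scalar_num(reaction_volume_ul, "reaction_volume_ul",
                     lower = 0, strict = TRUE)
  if (n_droplets * droplet_volume_nl > reaction_volume_ul * 1000)
    stop("total droplet volume exceeds the reaction volume", call. = FALSE)
  structure(list(
    n_droplets         = as.integer(n_droplets),
    droplet_volume_nl  = droplet_volume_nl,
    reaction_volume_ul = reaction_volume_ul,
    eluate_loaded_ul   = eluate_loaded_ul
  ), class = "well_spec")
}

#' @export
print.amplitude_model <- function(x, ...) {
  cat("<amplitude_model>\n")
  cat(sprintf("  negative cluster FAM %g (sd %g), HEX %g (sd %g)\n",
              x$negative_mean_fam, x$negative_sd_fam,
              x$negative_mean_hex, x$negative_sd_hex))
  cat(sprintf("  reference HEX band %g (sd %g)\n",
              x$reference_mean_hex, x$reference_sd_hex))
  cat(sprintf("  %d target FAM band(s): %s\n", nrow(x$target_bands),
              paste(sprintf("%s@%g", x$target_bands$target_id,
                            x$target_bands$mean_fam), collapse = ", ")))
  cat(sprintf("  rain_fraction %g, fp_rate %g events/well\n",
              x$rain_fraction, x$fp_rate))
  invisible(x)
}

#' @export
print.well_spec <- function(x, ...) {
  cat(sprintf(
    "<well_spec> %d droplets x %g nL in %g uL reaction (%g uL eluate)\n",
    x$n_droplets, x$droplet_volume_nl, x$reaction_volume_ul,
    x$eluate_loaded_ul))
  invisible(x)
}
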