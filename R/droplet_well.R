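#' Construct a droplet well
#'
#' One ddPCR well: per-droplet two-channel fluorescence amplitudes plus the
#' manifest metadata (sample identity, control role, replicate grouping,
#' biofluid volume) the downstream stages need.
#'
#' @param well_id Plate coordinate, e.g. `"A01"`.
#' @param sample_id Sample identifier.
#' @param role One of `"sample"`, `"NC_gDNA"`, `"PC_gDNA"`, `"NTC"`,
#'   `"NC_cfDNA"`.
#' @param droplets data.frame with numeric columns `fam` and `hex`, one row
#'   per accepted droplet; amplitudes must be finite.
#' @param replicate_group Replicate group label; wells sharing a label are
#'   merged at quantification.
#' @param biofluid_volume_ml Volume of the liquid biopsy (mL) behind this
#'   sample, or `NA` when unknown (per-mL outputs are then suppressed).
#' @return An object of class `droplet_well`.
#' @export
droplet_well <- function(well_id, sample_id, role, droplets,
                         replicate_group = sample_id,
                         biofluid_volume_ml = NA_real_) {
  role <- match.arg(role, c("sample", "NC_gDNA", "PC_gDNA", "NTC", "NC_cfDNA"))
  stopifnot(is.data.frame(droplets),
            all(c("fam", "hex") %in% names(droplets)))
  if (nrow(droplets) == 0L)
    stop("droplet table is empty; a well must contain droplets", call. = FALSE)
  if (!all(is.finite(droplets$fam)) || !all(is.finite(droplets$hex)))
    stop("droplet amplitudes must be finite", call. = FALSE)
  structure(list(
    well_id            = as.character(well_id),
    sample_id          = as.character(sample_id),
    role               = role,
    droplets           = droplets[, c("fam", "hex")],
    replicate_group    = as.character(replicate_group),
    biofluid_volume_ml = as.numeric(biofluid_volume_ml)
  ), class = "droplet_well")
}

#' @export
print.droplet_well <- function(x, ...) {
  cat(sprintf("<droplet_well> %s (%s, role %s): %d droplets\n",
              x$well_id, x$sample_id, x$role, nrow(x$droplets)))
  invisible(x)
}
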