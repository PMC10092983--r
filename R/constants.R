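#' Package constants for ddPCR quantification
#'
#' Named defaults used throughout the pipeline. All are overridable through
#' function arguments; they are collected here so that a run is auditable
#' from one place.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{pg_per_hge}{Mass of one haploid human genome equivalent, 3.3 pg.
#'     This single constant drives every hGE/mass conversion.}
#'   \item{droplet_volume_nl}{Nominal accepted-droplet volume of the QX200
#'     system, 0.85 nL.}
#'   \item{n_droplets}{Default accepted droplets per well, 16000.}
#'   \item{reaction_volume_ul}{ddPCR reaction volume, 22 µL.}
#'   \item{eluate_loaded_ul}{cfDNA eluate loaded per well, 11 µL.}
#'   \item{input_fraction}{Fraction of the extraction eluate analysed across
#'     the triplicate wells, 33/40 (33 of 40 µL).}
#'   \item{min_positive_droplets}{Minimum merged FAM-positive droplets for a
#'     positive or trace-positive MRD call, 3.}
#'   \item{nc_plate_wells}{Negative-control cfDNA wells per plate used for
#'     false-positive-rate estimation, 12.}
#' }
#' @export
ddmrd_constants <- list(
  pg_per_hge            = 3.3,
  droplet_volume_nl     = 0.85,
  n_droplets            = 16000L,
  reaction_volume_ul    = 22,
  eluate_loaded_ul      = 11,
  input_fraction        = 33 / 40,
  min_positive_droplets = 3L,
  nc_plate_wells        = 12L
)

# internal: droplet volume in µL from nL
.vd_ul <- function(droplet_volume_nl) droplet_volume_nl / 1000

.assert_scalar_num <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (strict && x <= lower)
    stop(sprintf("`%s` must be > %s", name, lower), call. = FALSE)
  if (!strict && x < lower)
    stop(sprintf("`%s` must be >= %s", name, lower), call. = FALSE)
  invisible(x)
}
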