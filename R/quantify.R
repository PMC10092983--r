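# Poisson quantification of partition counts.
#
# With n droplets of volume V_d (µL) and k positives, the mean occupancy is
# lambda = -ln(1 - k/n) and the concentration lambda / V_d copies/µL of
# reaction. The 95% "Poisson" interval is the exact Clopper-Pearson
# binomial interval on p = k/n pushed through p -> -ln(1 - p) / V_d; the
# monotone transform preserves coverage and behaves correctly at the small
# counts (k in 0..5) that decide MRD calls. Merged replicates additionally
# carry a "total" error interval: the wider of the pooled Poisson interval
# and a t interval over per-well concentrations, which picks up inter-well
# (pipetting, droplet-count) variation the partition model ignores.

.clopper_pearson <- function(k, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lo <- if (k == 0) 0 else stats::qbeta(a, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
  c(lo, hi)
}

#' Estimate a concentration from droplet counts
#'
#' @param k FAM- (or HEX-) positive droplet count, `0 <= k <= n`.
#' @param n Total accepted droplets, > 0.
#' @param droplet_volume_ul Droplet volume in µL (default 0.85 nL).
#' @param conf Confidence level (default 0.95).
#' @return An object of class `concentration_estimate` with fields
#'   `k_positive`, `n_total`, `lambda`, `copies_per_ul`, `ci_low`,
#'   `ci_high` (copies/µL), `ci_kind`, `wells_merged`, `saturated`.
#'   A saturated well (`k == n`) is flagged and carries no finite point
#'   estimate.
#' @examples
#' estimate_concentration(100, 10000)
#' @export
estimate_concentration <- function(k, n,
                                   droplet_volume_ul =
                                     .vd_ul(ddmrd_constants$droplet_volume_nl),
                                   conf = 0.95) {
  if (n <= 0) stop("`n` must be > 0", call. = FALSE)
  if (k < 0 || k > n) stop("need 0 <= k <= n", call. = FALSE)
  vd <- droplet_volume_ul
  ci_p <- .clopper_pearson(k, n, conf)
  if (k == n) {
    est <- list(k_positive = k, n_total = n, lambda = NA_real_,
                copies_per_ul = NA_real_,
                ci_low = -log(1 - ci_p[1]) / vd, ci_high = Inf,
                ci_kind = "poisson", wells_merged = 1L, saturated = TRUE,
                droplet_volume_ul = vd)
    return(structure(est, class = "concentration_estimate"))
  }
  lambda <- -log(1 - k / n) + 0  # + 0 normalizes IEEE -0 when k = 0
  structure(list(
    k_positive = as.integer(k), n_total = as.integer(n),
    lambda = lambda, copies_per_ul = lambda / vd,
    ci_low  = -log(1 - ci_p[1]) / vd + 0,
    ci_high = -log(1 - ci_p[2]) / vd,
    ci_kind = "poisson", wells_merged = 1L, saturated = FALSE,
    droplet_volume_ul = vd
  ), class = "concentration_estimate")
}

#' Merge replicate wells into one concentration estimate
#'
#' Droplet counts are pooled (`k = sum k_i`, `n = sum n_i`) and the point
#' estimate is the pooled Poisson estimate. With two or more wells, the
#' reported interval is the wider of (a) the pooled Poisson interval and
#' (b) `mean +/- t * SD / sqrt(m)` over per-well concentrations; `ci_kind`
#' records which won ("poisson" or "total").
#'
#' @param wells List of `classified_well`s sharing one gate set.
#' @param target Target id whose FAM counts are merged, or `NULL` to merge
#'   the reference (HEX-positive) counts.
#' @param conf Confidence level (default 0.95).
#' @param droplet_volume_ul Droplet volume in µL (default 0.85 nL).
#' @return A `concentration_estimate` with `wells_merged` set.
#' @export
merge_replicates <- function(wells, target = NULL, conf = 0.95,
                             droplet_volume_ul =
                               .vd_ul(ddmrd_constants$droplet_volume_nl)) {
  if (!length(wells)) stop("need at least one well", call. = FALSE)
  gates <- lapply(wells, function(w) w$gates)
  if (length(wells) > 1L &&
      !all(vapply(gates[-1L], identical, TRUE, y = gates[[1L]])))
    stop("wells were classified with different gate sets", call. = FALSE)
  vd <- droplet_volume_ul

  ks <- vapply(wells, function(w) {
    if (is.null(target)) reference_hex_count(w)
    else target_fam_count(w, target)
  }, 0)
  ns <- vapply(wells, `[[`, 0L, "total_droplets")

  pooled <- estimate_concentration(sum(ks), sum(ns),
                                   droplet_volume_ul = vd, conf = conf)
  pooled$wells_merged <- length(wells)
  m <- length(wells)
  if (m >= 2L && !pooled$saturated) {
    per_well <- -log(1 - ks / ns) / vd
    if (all(is.finite(per_well))) {
      se <- stats::sd(per_well) / sqrt(m)
      tq <- stats::qt(1 - (1 - conf) / 2, df = m - 1L)
      t_lo <- max(0, mean(per_well) - tq * se)
      t_hi <- mean(per_well) + tq * se
      if ((t_hi - t_lo) > (pooled$ci_high - pooled$ci_low)) {
        pooled$ci_low  <- t_lo
        pooled$ci_high <- t_hi
        pooled$ci_kind <- "total"
      }
    }
  }
  pooled
}

#' Convert a merged reaction concentration to copies per mL of biofluid
#'
#' Copies detected across the merged wells (`copies/µL x reaction volume x
#' wells`) are scaled up by the analysed input fraction (33 of 40 µL of
#' eluate by default) and divided by the initial biofluid volume. The CI
#' endpoints are transformed identically.
#'
#' @param merged A `concentration_estimate` from [merge_replicates()].
#' @param biofluid_volume_ml Initial liquid-biopsy volume in mL; `NA`
#'   yields `NA` results with `volume_missing = TRUE`.
#' @param reaction_volume_ul Reaction volume per well (default 22 µL).
#' @param wells Number of merged wells (defaults to `merged$wells_merged`).
#' @param input_fraction Fraction of the eluate analysed (default 33/40).
#' @return List with `copies_per_ml`, `ci_low`, `ci_high`,
#'   `copies_detected` and `volume_missing`.
#' @examples
#' est <- estimate_concentration(100, 10000)
#' copies_per_ml_biofluid(est, biofluid_volume_ml = 2, wells = 3)
#' @export
copies_per_ml_biofluid <- function(merged, biofluid_volume_ml,
                                   reaction_volume_ul =
                                     ddmrd_constants$reaction_volume_ul,
                                   wells = merged$wells_merged,
                                   input_fraction =
                                     ddmrd_constants$input_fraction) {
  if (is.na(biofluid_volume_ml))
    return(list(copies_per_ml = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_, copies_detected = NA_real_,
                volume_missing = TRUE))
  if (biofluid_volume_ml <= 0)
    stop("`biofluid_volume_ml` must be > 0", call. = FALSE)
  f <- reaction_volume_ul * wells / input_fraction / biofluid_volume_ml
  list(copies_per_ml   = merged$copies_per_ul * f,
       ci_low          = merged$ci_low * f,
       ci_high         = merged$ci_high * f,
       copies_detected = merged$copies_per_ul * reaction_volume_ul * wells,
       volume_missing  = FALSE)
}

#' Total cfDNA content of a sample in haploid genome equivalents per mL
#'
#' Reference-gene mode counts HEX (reference) signals: one reference locus
#' per haploid genome, so hGE/mL equals reference copies/mL. SNV mode sums
#' wild-type (HEX) and mutant (FAM) copies of the SNV locus.
#'
#' @param wells Classified replicate wells of one sample.
#' @param mode `"reference"` or `"snv"`.
#' @param snv_target Target id of the SNV assay (SNV mode only).
#' @param biofluid_volume_ml Biofluid volume in mL.
#' @param ... Passed to [copies_per_ml_biofluid()].
#' @param pg_per_hge Mass per haploid genome equivalent (default 3.3 pg).
#' @return List with `hge_per_ml`, `mass_pg_per_ml` and `mode`.
#' @export
total_cfdna <- function(wells, mode = c("reference", "snv"),
                        snv_target = NULL, biofluid_volume_ml, ...,
                        pg_per_hge = ddmrd_constants$pg_per_hge) {
  mode <- match.arg(mode)
  if (mode == "reference") {
    per_ml <- copies_per_ml_biofluid(merge_replicates(wells, target = NULL),
                                     biofluid_volume_ml, ...)
    hge <- per_ml$copies_per_ml
  } else {
    if (is.null(snv_target))
      stop("SNV mode needs `snv_target`", call. = FALSE)
    wt  <- copies_per_ml_biofluid(merge_replicates(wells, target = NULL),
                                  biofluid_volume_ml, ...)
    mut <- copies_per_ml_biofluid(merge_replicates(wells, target = snv_target),
                                  biofluid_volume_ml, ...)
    hge <- wt$copies_per_ml + mut$copies_per_ml
  }
  list(hge_per_ml = hge, mass_pg_per_ml = hge * pg_per_hge, mode = mode)
}

#' Convert between haploid genome equivalents and DNA mass
#'
#' Uses 3.3 pg per haploid human genome equivalent. The conversion is exact
#' and self-inverse; rounding is applied only by the display helpers
#' [display_hge()] and [display_mass_pg()].
#'
#' @param value Non-negative quantity to convert.
#' @param direction `"hge_to_mass_pg"` or `"mass_pg_to_hge"`.
#' @param pg_per_hge Mass per haploid genome equivalent (default 3.3 pg).
#' @return Converted value at full precision.
#' @examples
#' hge_mass_convert(100, "mass_pg_to_hge")   # 30.3 hGE
#' hge_mass_convert(8573, "hge_to_mass_pg")  # 28290.9 pg = 28.3 ng
#' @export
hge_mass_convert <- function(value,
                             direction = c("hge_to_mass_pg",
                                           "mass_pg_to_hge"),
                             pg_per_hge = ddmrd_constants$pg_per_hge) {
  direction <- match.arg(direction)
  if (any(value < 0)) stop("`value` must be >= 0", call. = FALSE)
  switch(direction,
         hge_to_mass_pg = value * pg_per_hge,
         mass_pg_to_hge = value / pg_per_hge)
}

#' Display rounding for haploid genome equivalents
#'
#' hGE counts are reported as integers.
#'
#' @param hge Numeric hGE value(s).
#' @return Rounded integer value(s).
#' @examples
#' display_hge(hge_mass_convert(100, "mass_pg_to_hge"))  # 30
#' @export
display_hge <- function(hge) round(hge)

#' Display rounding for DNA mass
#'
#' Masses below 1000 pg are printed as integer pg; larger masses as ng to
#' one decimal.
#'
#' @param mass_pg Mass in pg.
#' @return Character string such as `"66 pg"` or `"28.3 ng"`.
#' @examples
#' display_mass_pg(hge_mass_convert(8573, "hge_to_mass_pg"))  # "28.3 ng"
#' @export
display_mass_pg <- function(mass_pg) {
  vapply(mass_pg, function(x) {
    if (x < 1000) sprintf("%d pg", as.integer(round(x)))
    else sprintf("%.1f ng", round(x / 1000, 1))
  }, "")
}

#' @export
print.concentration_estimate <- function(x, ...) {
  if (x$saturated) {
    cat(sprintf("<concentration_estimate> SATURATED: k = n = %d\n",
                x$n_total))
    return(invisible(x))
  }
  cat(sprintf(
    "<concentration_estimate> %d/%d droplets, lambda %.5g -> %.4g copies/uL [%.4g, %.4g] (%s, %d well%s)\n",
    x$k_positive, x$n_total, x$lambda, x$copies_per_ul, x$ci_low, x$ci_high,
    x$ci_kind, x$wells_merged, if (x$wells_merged > 1L) "s" else ""))
  invisible(x)
}
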