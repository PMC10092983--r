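# MRD decision rules.
#
# A target is called positive when three or more merged FAM-positive
# droplets are seen AND the sample's 95% interval does not overlap the
# negative-control cfDNA interval (sample lower bound strictly above the
# NC upper bound, on the copies/µL scale). A borderline target with >= 3
# droplets but overlapping intervals is called trace positive only when
# the assay's measured false-positive rate over the 12-well NC plate is
# zero. Everything else is negative. CI separation is tested before the
# FPR rule, so unambiguous positives are never downgraded to trace.

#' Estimate a per-assay false-positive rate from NC wells
#'
#' Total target-band droplet events across the negative-control cfDNA
#' wells divided by the number of wells; the exact rational is kept,
#' display is to two decimals.
#'
#' @param nc_wells List of `classified_well`s (NC cfDNA wells).
#' @param target Target id.
#' @return An object of class `assay_fpr` with `total_events`, `n_wells`,
#'   `fpr_events_per_well`.
#' @examples
#' # 1 event across 12 wells displays as 0.08 events/well
#' @export
estimate_fpr <- function(nc_wells, target) {
  if (!length(nc_wells)) stop("need at least one NC well", call. = FALSE)
  events <- sum(vapply(nc_wells, target_fam_count, 0, target = target))
  structure(list(
    target_id = target,
    total_events = as.integer(events),
    n_wells = length(nc_wells),
    fpr_events_per_well = events / length(nc_wells)
  ), class = "assay_fpr")
}

#' Display rounding for a false-positive rate
#'
#' @param fpr An `assay_fpr` or numeric events/well value.
#' @return Character value to two decimals, e.g. `"0.08"`.
#' @export
display_fpr <- function(fpr) {
  x <- if (inherits(fpr, "assay_fpr")) fpr$fpr_events_per_well else fpr
  sprintf("%.2f", x)
}

#' Convert a per-well false-positive rate to events per mL
#'
#' The conversion depends on how much biofluid stands behind each NC well;
#' both volumes must be supplied explicitly.
#'
#' @param fpr_events_per_well Events per well.
#' @param biofluid_ml_total Biofluid volume (mL) behind the whole NC plate.
#' @param n_wells Wells on the plate (default 12).
#' @return Events per mL of biofluid.
#' @export
fpr_per_ml <- function(fpr_events_per_well, biofluid_ml_total,
                       n_wells = ddmrd_constants$nc_plate_wells) {
  fpr_events_per_well * n_wells / biofluid_ml_total
}

#' Call one target in one sample
#'
#' Decision cascade: fewer than `min_droplets` merged FAM droplets is
#' negative; otherwise non-overlapping 95% intervals versus the NC cfDNA
#' estimate is positive; otherwise a zero measured FPR is trace positive;
#' otherwise negative.
#'
#' @param sample_est Merged `concentration_estimate` of the sample for
#'   this target.
#' @param nc_est Merged `concentration_estimate` of the NC cfDNA wells for
#'   the same target (required: calls are relative to NC by definition).
#' @param fpr An `assay_fpr` for this target.
#' @param min_droplets Minimum FAM droplets (default 3).
#' @return An object of class `target_call` with `call` one of
#'   `"positive"`, `"trace_positive"`, `"negative"`, plus evidence fields
#'   `fam_droplets`, `ci_nonoverlap`, `fpr`, `sample_ci`, `nc_ci`.
#' @export
call_target <- function(sample_est, nc_est, fpr,
                        min_droplets = ddmrd_constants$min_positive_droplets) {
  if (is.null(nc_est) || !inherits(nc_est, "concentration_estimate"))
    stop("NC cfDNA estimate is required for calling", call. = FALSE)
  stopifnot(inherits(sample_est, "concentration_estimate"),
            inherits(fpr, "assay_fpr"))
  if (!isTRUE(all.equal(sample_est$droplet_volume_ul,
                        nc_est$droplet_volume_ul)))
    stop("sample and NC estimates use different droplet volumes",
         call. = FALSE)

  k <- sample_est$k_positive
  nonoverlap <- sample_est$ci_low > nc_est$ci_high
  call <- if (k < min_droplets) "negative"
          else if (nonoverlap) "positive"
          else if (fpr$fpr_events_per_well == 0) "trace_positive"
          else "negative"

  structure(list(
    target_id     = fpr$target_id,
    fam_droplets  = k,
    sample_ci     = c(sample_est$ci_low, sample_est$ci_high),
    nc_ci         = c(nc_est$ci_low, nc_est$ci_high),
    ci_nonoverlap = nonoverlap,
    fpr           = fpr$fpr_events_per_well,
    call          = call
  ), class = "target_call")
}

#' Sample-level MRD status from per-target calls
#'
#' A sample is MRD positive if any target is positive, trace positive if
#' any target is trace positive (and none positive), otherwise negative.
#'
#' @param target_calls Non-empty list of `target_call`s.
#' @return `"positive"`, `"trace_positive"` or `"negative"`.
#' @export
call_sample <- function(target_calls) {
  if (!length(target_calls))
    stop("no target calls: cannot determine sample status", call. = FALSE)
  calls <- vapply(target_calls, `[[`, "", "call")
  if (any(calls == "positive")) "positive"
  else if (any(calls == "trace_positive")) "trace_positive"
  else "negative"
}

#' Assess the limit of detection from a dilution series
#'
#' The LoD is the smallest tumor input mass whose call — and the calls at
#' every larger mass — is positive. A series whose positives are not a
#' contiguous block at the top is flagged non-monotone (the LoD is then
#' read from the contiguous top block only). A series with no positive
#' step has an undefined LoD, reported as greater than the largest mass
#' tested.
#'
#' @param masses_pg Strictly decreasing tumor masses (pg), length >= 2.
#' @param calls Character calls (or `target_call`s) per step.
#' @return An object of class `lod_result` with `lod_mass_pg` (`NA` when
#'   undefined), `lod_label`, `monotone` and the per-step table.
#' @examples
#' assess_lod(c(1000, 100, 10, 1),
#'            c("positive", "positive", "negative", "negative"))
#' @export
assess_lod <- function(masses_pg, calls) {
  if (length(masses_pg) < 2L)
    stop("need at least two dilution steps", call. = FALSE)
  if (any(diff(masses_pg) >= 0))
    stop("masses must be strictly decreasing", call. = FALSE)
  if (length(calls) != length(masses_pg))
    stop("one call per mass required", call. = FALSE)
  calls <- vapply(calls, function(x)
    if (inherits(x, "target_call")) x$call else as.character(x), "")
  pos <- calls == "positive"

  steps <- data.frame(tumor_mass_pg = masses_pg, call = calls,
                      stringsAsFactors = FALSE)
  if (!any(pos)) {
    return(structure(list(
      lod_mass_pg = NA_real_,
      lod_label = sprintf("> %g pg", max(masses_pg)),
      monotone = TRUE, steps = steps), class = "lod_result"))
  }
  run <- which(!pos)[1L]
  top_block_end <- if (is.na(run)) length(pos) else run - 1L
  monotone <- top_block_end >= 1L && !any(pos[seq_along(pos) > top_block_end])
  if (top_block_end < 1L) {  # first step already negative but later positive
    return(structure(list(
      lod_mass_pg = NA_real_,
      lod_label = "non-monotone series",
      monotone = FALSE, steps = steps), class = "lod_result"))
  }
  structure(list(
    lod_mass_pg = masses_pg[top_block_end],
    lod_label = sprintf("%g pg", masses_pg[top_block_end]),
    monotone = monotone, steps = steps), class = "lod_result")
}

#' @export
print.assay_fpr <- function(x, ...) {
  cat(sprintf("<assay_fpr> %s: %d events / %d wells = %s events/well\n",
              x$target_id, x$total_events, x$n_wells, display_fpr(x)))
  invisible(x)
}

#' @export
print.target_call <- function(x, ...) {
  cat(sprintf(
    "<target_call> %s: %s (%d FAM droplets, CI %s NC, FPR %s)\n",
    x$target_id, x$call, x$fam_droplets,
    if (x$ci_nonoverlap) "separated from" else "overlapping",
    display_fpr(x$fpr)))
  invisible(x)
}

#' @export
print.lod_result <- function(x, ...) {
  cat(sprintf("<lod_result> LoD %s%s\n", x$lod_label,
              if (x$monotone) "" else " (non-monotone series, flagged)"))
  print(x$steps, row.names = FALSE)
  invisible(x)
}
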