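# Droplet gating and classification.
#
# The manual 2D thresholding done on instrument software is replaced here
# by rectangular gates: one global FAM threshold separating negatives from
# positives, one HEX threshold for the reference channel, and one disjoint
# FAM interval per multiplexed target. Gate intervals are half-open
# [low, high); an amplitude exactly at the FAM threshold is negative.
# Droplets above the FAM threshold but inside no target gate (rain) are
# counted as "unassigned": excluded from positives, never dropped.

#' Construct a gate set
#'
#' @param fam_threshold Global FAM negative/positive threshold (a.u.).
#' @param hex_threshold HEX reference threshold (a.u.).
#' @param target_gates data.frame with columns `target_id`, `fam_low`,
#'   `fam_high`; intervals are half-open `[fam_low, fam_high)`, must be
#'   pairwise disjoint, and every `fam_low` must exceed `fam_threshold`.
#' @return An object of class `gate_set`.
#' @export
gate_set <- function(fam_threshold, hex_threshold, target_gates) {
  stopifnot(is.data.frame(target_gates),
            all(c("target_id", "fam_low", "fam_high") %in%
                  names(target_gates)))
  if (any(target_gates$fam_low >= target_gates$fam_high))
    stop("each gate needs fam_low < fam_high", call. = FALSE)
  if (any(target_gates$fam_low <= fam_threshold))
    stop("every gate's fam_low must exceed fam_threshold", call. = FALSE)
  g <- target_gates[order(target_gates$fam_low), , drop = FALSE]
  if (nrow(g) > 1L && any(g$fam_high[-nrow(g)] > g$fam_low[-1L]))
    stop("target gates must be pairwise disjoint in FAM", call. = FALSE)
  rownames(g) <- NULL
  structure(list(fam_threshold = fam_threshold,
                 hex_threshold = hex_threshold,
                 target_gates  = g),
            class = "gate_set")
}

#' @export
print.gate_set <- function(x, ...) {
  cat(sprintf("<gate_set> FAM threshold %.1f, HEX threshold %.1f\n",
              x$fam_threshold, x$hex_threshold))
  for (i in seq_len(nrow(x$target_gates)))
    cat(sprintf("  %s: FAM [%.1f, %.1f)\n", x$target_gates$target_id[i],
                x$target_gates$fam_low[i], x$target_gates$fam_high[i]))
  invisible(x)
}

# deterministic 1-D k-means: initial centers at evenly spaced quantiles
.cluster_1d <- function(x, k) {
  if (k == 1L)
    return(list(centers = stats::median(x), sizes = length(x),
                sd = stats::sd(x), cluster = rep(1L, length(x))))
  init <- stats::quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  if (anyDuplicated(init)) init <- init + seq_len(k) * 1e-9
  km  <- stats::kmeans(x, centers = matrix(init, ncol = 1))
  ord <- order(km$centers[, 1])
  relab <- match(seq_len(k), ord)
  cl <- relab[km$cluster]
  centers <- vapply(seq_len(k), function(i) stats::median(x[cl == i]), 0)
  sds     <- vapply(seq_len(k), function(i) {
    xi <- x[cl == i]
    if (length(xi) > 1L) stats::sd(xi) else 0
  }, 0)
  list(centers = centers, sizes = tabulate(cl, k), sd = sds, cluster = cl)
}

#' Derive amplitude gates from control wells
#'
#' Gates are set from the control wells run on each plate: the FAM negative
#' cluster is read from negative-control (NC) wells, the target bands from
#' positive-control (PC) wells, and the HEX reference band from both. The
#' FAM threshold is placed at `NC mean + k_sd * SD` or at the midpoint
#' between the NC cluster and the lowest PC band, whichever is higher, and
#' must stay clear of the lowest band; gate boundaries between bands fall
#' at band-median midpoints.
#'
#' @param control_wells List of [droplet_well()]s; must contain at least
#'   one `NC_gDNA` and one `PC_gDNA` well. `NTC` wells are ignored for
#'   gate geometry.
#' @param panel Character vector of target ids, ordered by ascending
#'   expected FAM amplitude (the amplitude-multiplexing order).
#' @param k_sd Multiplier on the NC FAM standard deviation for the
#'   threshold floor (default 7).
#' @return A [gate_set()].
#' @examples
#' am <- amplitude_model()
#' nc <- simulate_well(c(T1 = 0), 100, am, seed = 1, role = "NC_gDNA")
#' pc <- simulate_well(c(T1 = 30), 100, am, seed = 2, role = "PC_gDNA")
#' derive_gates(list(nc, pc), panel = "T1")
#' @export
derive_gates <- function(control_wells, panel, k_sd = 7) {
  roles <- vapply(control_wells, `[[`, "", "role")
  nc <- control_wells[roles == "NC_gDNA"]
  pc <- control_wells[roles == "PC_gDNA"]
  if (!length(nc) || !length(pc))
    stop("need at least one NC_gDNA and one PC_gDNA control well",
         call. = FALSE)
  if (!length(panel)) stop("empty target panel", call. = FALSE)

  nc_fam  <- unlist(lapply(nc, function(w) w$droplets$fam))
  nc_mean <- mean(nc_fam)
  nc_sd   <- stats::sd(nc_fam)

  pc_fam <- unlist(lapply(pc, function(w) w$droplets$fam))
  pos    <- pc_fam[pc_fam > nc_mean + 5 * nc_sd]
  m      <- length(panel)
  if (length(pos) < 2L * m)
    stop("unresolvable multiplex: PC wells show too few FAM-positive ",
         "droplets for the panel", call. = FALSE)
  cl <- .cluster_1d(pos, m)
  if (any(cl$sizes == 0L))
    stop("unresolvable multiplex: fewer FAM clusters than panel targets",
         call. = FALSE)
  centers <- cl$centers
  if (m > 1L) {
    gaps  <- diff(centers)
    sdmax <- pmax(cl$sd[-1L], cl$sd[-m])
    if (any(gaps < 4 * pmax(sdmax, nc_sd)))
      stop("unresolvable multiplex: PC FAM clusters overlap", call. = FALSE)
  }

  band_sd1 <- max(cl$sd[1L], nc_sd)
  cand     <- nc_mean + k_sd * nc_sd
  midpoint <- (nc_mean + centers[1L]) / 2
  if (cand >= centers[1L] - 3 * band_sd1)
    stop("inseparable assay: NC and lowest PC clusters overlap",
         call. = FALSE)
  fam_threshold <- max(cand, midpoint)

  lows  <- numeric(m)
  highs <- numeric(m)
  lows[1L] <- (fam_threshold + centers[1L]) / 2
  if (m > 1L) {
    bnd <- (centers[-m] + centers[-1L]) / 2
    highs[-m] <- bnd
    lows[-1L] <- bnd
  }
  highs[m] <- centers[m] + (centers[m] - lows[m])

  # HEX: negative cluster vs reference band, pooled over NC + PC wells
  hx  <- unlist(lapply(c(nc, pc), function(w) w$droplets$hex))
  hcl <- .cluster_1d(hx, 2L)
  if (any(hcl$sizes == 0L) ||
      diff(hcl$centers) < 4 * max(hcl$sd, na.rm = TRUE))
    stop("inseparable assay: HEX reference and negative clusters overlap",
         call. = FALSE)
  hex_threshold <- mean(hcl$centers)

  gate_set(fam_threshold, hex_threshold,
           data.frame(target_id = panel, fam_low = lows, fam_high = highs,
                      stringsAsFactors = FALSE))
}

#' Classify the droplets of one well
#'
#' Assigns every droplet to exactly one class: `empty`, `reference_only`,
#' per-target `target_only` / `target_and_reference`, or `unassigned`
#' (FAM above threshold but inside no target gate — rain and off-band
#' events). Counts always sum to the droplet total.
#'
#' @param well A [droplet_well()].
#' @param gates A [gate_set()].
#' @return An object of class `classified_well` with elements `counts`
#'   (per-target data.frame), `empty`, `reference_only`, `unassigned`,
#'   `total_droplets` and the well metadata.
#' @export
classify_droplets <- function(well, gates) {
  stopifnot(inherits(well, "droplet_well"), inherits(gates, "gate_set"))
  d <- well$droplets
  if (nrow(d) == 0L) stop("empty droplet list", call. = FALSE)

  fam_pos <- d$fam > gates$fam_threshold
  ref_pos <- d$hex > gates$hex_threshold

  g <- gates$target_gates
  assigned <- rep(0L, nrow(d))
  for (i in seq_len(nrow(g)))
    assigned[d$fam >= g$fam_low[i] & d$fam < g$fam_high[i]] <- i

  unassigned <- sum(fam_pos & assigned == 0L)
  counts <- data.frame(
    target_id = g$target_id,
    target_only = vapply(seq_len(nrow(g)), function(i)
      sum(assigned == i & !ref_pos), 0L),
    target_and_reference = vapply(seq_len(nrow(g)), function(i)
      sum(assigned == i & ref_pos), 0L),
    stringsAsFactors = FALSE)

  neg <- !fam_pos & assigned == 0L
  structure(list(
    well_id            = well$well_id,
    sample_id          = well$sample_id,
    role               = well$role,
    replicate_group    = well$replicate_group,
    biofluid_volume_ml = well$biofluid_volume_ml,
    counts             = counts,
    empty              = sum(neg & !ref_pos),
    reference_only     = sum(neg & ref_pos),
    unassigned         = unassigned,
    hex_positive       = sum(ref_pos),
    total_droplets     = nrow(d),
    gates              = gates
  ), class = "classified_well")
}

#' Classify a list of wells against one gate set
#'
#' @param wells List of [droplet_well()]s.
#' @param gates A [gate_set()].
#' @return List of `classified_well`s.
#' @export
classify_plate <- function(wells, gates) {
  lapply(wells, classify_droplets, gates = gates)
}

#' FAM-positive droplet count for a target in a classified well
#'
#' Target-only plus target-and-reference (double-positive) droplets.
#'
#' @param cw A `classified_well`.
#' @param target Target id.
#' @return Integer droplet count.
#' @export
target_fam_count <- function(cw, target) {
  i <- match(target, cw$counts$target_id)
  if (is.na(i)) stop("unknown target: ", target, call. = FALSE)
  cw$counts$target_only[i] + cw$counts$target_and_reference[i]
}

#' Reference-positive droplet count in a classified well
#'
#' All droplets above the HEX threshold, regardless of FAM class.
#'
#' @param cw A `classified_well`.
#' @return Integer droplet count.
#' @export
reference_hex_count <- function(cw) {
  cw$hex_positive
}

#' @export
print.classified_well <- function(x, ...) {
  cat(sprintf("<classified_well> %s (%s): %d droplets\n", x$well_id,
              x$sample_id, x$total_droplets))
  cat(sprintf("  empty %d, reference_only %d, unassigned %d\n",
              x$empty, x$reference_only, x$unassigned))
  for (i in seq_len(nrow(x$counts)))
    cat(sprintf("  %s: target_only %d, target+reference %d\n",
                x$counts$target_id[i], x$counts$target_only[i],
                x$counts$target_and_reference[i]))
  invisible(x)
}
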