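# End-to-end orchestration: simulate or load a plate, derive gates from
# its control wells, classify, merge replicates, quantify, estimate FPRs,
# and emit MRD calls. One config drives a run; the same config and seed
# reproduce identical outputs.

#' Build a pipeline run configuration
#'
#' @param panel Character vector of target ids in ascending FAM amplitude
#'   order.
#' @param reference_assay Label of the reference (HEX) assay (default
#'   `"ABCC9"`).
#' @param seed Integer seed driving all simulation randomness.
#' @param out_dir Output directory, or `NULL` to skip file output.
#' @param min_droplets Minimum FAM droplets for a positive/trace call.
#' @param droplet_volume_nl,reaction_volume_ul,input_fraction,pg_per_hge
#'   Pipeline constants (see [ddmrd_constants]).
#' @param simulation Named list of simulation settings used when no wells
#'   are supplied to [run_pipeline()]: `sample_concentrations` (named list
#'   sample id -> named copies/µL vector), `reference_concentration`,
#'   `pc_concentration`, `nc_fp_rate`, `biofluid_volume_ml`, `replicates`,
#'   `nc_wells`.
#' @return List of class `run_config`; round-trips unchanged through
#'   [jsonlite::toJSON()]/[jsonlite::fromJSON()] via [config_to_json()].
#' @export
run_config <- function(panel,
                       reference_assay = "ABCC9",
                       seed = 1L,
                       out_dir = NULL,
                       min_droplets = ddmrd_constants$min_positive_droplets,
                       droplet_volume_nl = ddmrd_constants$droplet_volume_nl,
                       reaction_volume_ul =
                         ddmrd_constants$reaction_volume_ul,
                       input_fraction = ddmrd_constants$input_fraction,
                       pg_per_hge = ddmrd_constants$pg_per_hge,
                       simulation = list()) {
  stopifnot(length(panel) >= 1L, droplet_volume_nl > 0,
            reaction_volume_ul > 0, input_fraction > 0, pg_per_hge > 0)
  structure(list(panel = panel, reference_assay = reference_assay,
                 seed = as.integer(seed), out_dir = out_dir,
                 min_droplets = as.integer(min_droplets),
                 droplet_volume_nl = droplet_volume_nl,
                 reaction_volume_ul = reaction_volume_ul,
                 input_fraction = input_fraction,
                 pg_per_hge = pg_per_hge,
                 simulation = simulation),
            class = "run_config")
}

#' Serialize / restore a run configuration
#'
#' @param config A [run_config()].
#' @return JSON string.
#' @export
config_to_json <- function(config) {
  jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                   null = "null")
}

#' @rdname config_to_json
#' @param json JSON string from [config_to_json()].
#' @export
config_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  do.call(run_config, x[setdiff(names(x), character(0))])
}

#' Simulate a complete analysis plate
#'
#' Triplicate sample wells per sample, triplicate NC gDNA / PC gDNA / NTC
#' control wells, and a 12-well NC cfDNA complement — the plate layout the
#' pipeline expects.
#'
#' @param config A [run_config()] whose `simulation` list is populated.
#' @param amplitude_model An [amplitude_model()] with one band per panel
#'   target.
#' @param well_spec A [well_spec()].
#' @return List of [droplet_well()]s.
#' @export
simulate_plate <- function(config, amplitude_model,
                           well_spec = ddmrd::well_spec()) {
  sim <- config$simulation
  pick <- function(name, default) if (is.null(sim[[name]])) default
                                  else sim[[name]]
  ref_c  <- pick("reference_concentration", 50)
  pc_c   <- pick("pc_concentration", 30)
  fp     <- pick("nc_fp_rate", 0)
  reps   <- pick("replicates", 3L)
  vol    <- pick("biofluid_volume_ml", 2)
  ncw    <- pick("nc_wells", ddmrd_constants$nc_plate_wells)
  samples <- sim$sample_concentrations
  panel  <- config$panel
  zero   <- stats::setNames(numeric(length(panel)), panel)
  all_pc <- stats::setNames(rep(pc_c, length(panel)), panel)

  wells <- list()
  idx <- 0L
  add <- function(w) { idx <<- idx + 1L; wells[[idx]] <<- w }
  wseed <- function() .derive_seed(config$seed, idx + 1L)

  for (s in names(samples)) {
    conc <- zero
    conc[names(samples[[s]])] <- unlist(samples[[s]])
    for (r in seq_len(reps))
      add(simulate_well(conc, ref_c, amplitude_model, well_spec,
                        seed = wseed(),
                        well_id = sprintf("S_%s_%d", s, r), sample_id = s,
                        role = "sample", replicate_group = s,
                        biofluid_volume_ml = vol))
  }
  for (r in seq_len(reps)) {
    add(simulate_well(zero, ref_c, amplitude_model, well_spec,
                      seed = wseed(), well_id = sprintf("NCg_%d", r),
                      sample_id = "NC_gDNA", role = "NC_gDNA",
                      replicate_group = "NC_gDNA"))
    add(simulate_well(all_pc, ref_c, amplitude_model, well_spec,
                      seed = wseed(), well_id = sprintf("PCg_%d", r),
                      sample_id = "PC_gDNA", role = "PC_gDNA",
                      replicate_group = "PC_gDNA"))
    add(simulate_well(zero, 0, amplitude_model, well_spec,
                      seed = wseed(), well_id = sprintf("NTC_%d", r),
                      sample_id = "NTC", role = "NTC",
                      replicate_group = "NTC"))
  }
  nc <- simulate_nc_plate(ncw, fp, amplitude_model, well_spec,
                          seed = .derive_seed(config$seed, 10000L))
  c(wells, nc)
}

#' Run the full MRD pipeline on one plate
#'
#' Stages: derive gates from the plate's control wells; classify every
#' well; estimate per-assay FPRs from the NC cfDNA wells; merge sample
#' replicates and quantify; call each target against the merged NC cfDNA
#' estimate; summarise per sample. NTC wells must be droplet-free in all
#' target gates or the plate is QC-flagged.
#'
#' @param config A [run_config()].
#' @param wells Optional list of [droplet_well()]s; when `NULL` a plate is
#'   simulated from `config$simulation` (an `amplitude_model` must then be
#'   supplied).
#' @param amplitude_model Required when `wells` is `NULL`.
#' @return List of class `mrd_run` with `gates`, `classified`, `fpr`,
#'   `results` (per sample x target quantification data.frame), `calls`
#'   (per sample x target data.frame), `sample_status`, `qc`, and `paths`
#'   of written files when `config$out_dir` is set.
#' @export
run_pipeline <- function(config, wells = NULL, amplitude_model = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(wells)) {
    if (is.null(amplitude_model))
      stop("supply `wells` or an `amplitude_model` to simulate from",
           call. = FALSE)
    wells <- simulate_plate(config, amplitude_model)
  }
  vd <- .vd_ul(config$droplet_volume_nl)
  roles <- vapply(wells, `[[`, "", "role")

  gates <- derive_gates(wells[roles %in% c("NC_gDNA", "PC_gDNA", "NTC")],
                        panel = config$panel)
  classified <- classify_plate(wells, gates)

  nc_cf <- classified[roles == "NC_cfDNA"]
  if (!length(nc_cf))
    stop("calling stage requires NC cfDNA wells on the plate",
         call. = FALSE)

  # plate QC: NTC wells must be droplet-free in every target gate
  ntc <- classified[roles == "NTC"]
  ntc_events <- sum(vapply(ntc, function(cw)
    sum(cw$counts$target_only + cw$counts$target_and_reference), 0))
  qc <- list(ntc_target_events = ntc_events, ntc_clean = ntc_events == 0L)

  fprs <- lapply(config$panel, function(t) estimate_fpr(nc_cf, t))
  names(fprs) <- config$panel
  nc_est <- lapply(config$panel, function(t)
    merge_replicates(nc_cf, target = t, droplet_volume_ul = vd))
  names(nc_est) <- config$panel

  sample_cw <- classified[roles == "sample"]
  groups <- split(sample_cw,
                  vapply(sample_cw, `[[`, "", "replicate_group"))

  results <- NULL
  calls <- NULL
  sample_status <- character(0)
  for (s in names(groups)) {
    grp <- groups[[s]]
    vol <- grp[[1L]]$biofluid_volume_ml
    tcalls <- list()
    srows <- NULL
    for (t in config$panel) {
      est <- merge_replicates(grp, target = t, droplet_volume_ul = vd)
      per_ml <- copies_per_ml_biofluid(
        est, vol, reaction_volume_ul = config$reaction_volume_ul,
        input_fraction = config$input_fraction)
      tc <- call_target(est, nc_est[[t]], fprs[[t]],
                        min_droplets = config$min_droplets)
      tcalls[[t]] <- tc
      srows <- rbind(srows, data.frame(
        sample = s, target = t, k = est$k_positive, n = est$n_total,
        copies_per_ul = est$copies_per_ul, ci_low = est$ci_low,
        ci_high = est$ci_high, ci_kind = est$ci_kind,
        copies_per_ml = per_ml$copies_per_ml,
        stringsAsFactors = FALSE))
      calls <- rbind(calls, data.frame(
        sample = s, target = t, call = tc$call,
        fam_droplets = tc$fam_droplets, ci_nonoverlap = tc$ci_nonoverlap,
        fpr = fprs[[t]]$fpr_events_per_well, stringsAsFactors = FALSE))
    }
    # total cfDNA from the reference channel
    cf <- total_cfdna(grp, mode = "reference", biofluid_volume_ml = vol,
                      reaction_volume_ul = config$reaction_volume_ul,
                      input_fraction = config$input_fraction,
                      pg_per_hge = config$pg_per_hge)
    srows$hge_per_ml <- cf$hge_per_ml
    srows$mass_pg_per_ml <- cf$mass_pg_per_ml
    results <- rbind(results, srows)
    sample_status[s] <- call_sample(tcalls)
  }

  paths <- list()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(config$out_dir, f)
    write_gates(gates, p("gates.txt"))
    write_classification_tsv(classified, p("classification.tsv"))
    num <- function(x) ifelse(is.na(x), "NA", sprintf("%.6g", x))
    res_out <- results
    for (cc in c("copies_per_ul", "ci_low", "ci_high", "copies_per_ml",
                 "hge_per_ml", "mass_pg_per_ml"))
      res_out[[cc]] <- num(res_out[[cc]])
    utils::write.table(res_out, p("results.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(calls, p("calls.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    log <- list(config = unclass(config), qc = qc,
                sample_status = as.list(sample_status))
    writeLines(as.character(jsonlite::toJSON(log, auto_unbox = TRUE,
                                             digits = NA, null = "null",
                                             pretty = TRUE)),
               p("run_log.json"))
    paths <- list(gates = p("gates.txt"),
                  classification = p("classification.tsv"),
                  results = p("results.tsv"), calls = p("calls.tsv"),
                  run_log = p("run_log.json"))
  }

  structure(list(gates = gates, classified = classified, fpr = fprs,
                 nc_estimates = nc_est, results = results, calls = calls,
                 sample_status = sample_status, qc = qc, paths = paths),
            class = "mrd_run")
}

#' @export
print.mrd_run <- function(x, ...) {
  cat("<mrd_run>\n")
  cat(sprintf("  %d wells classified, NTC %s\n", length(x$classified),
              if (x$qc$ntc_clean) "clean" else
                sprintf("FLAGGED (%d target events)",
                        x$qc$ntc_target_events)))
  for (s in names(x$sample_status))
    cat(sprintf("  %s: %s\n", s, x$sample_status[[s]]))
  invisible(x)
}
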