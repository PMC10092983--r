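# Plate I/O: the droplet CSV dialect (one row per droplet, QX-Manager-
# export-like) and the plate manifest that carries sample roles and
# biofluid volumes.

#' Write wells to a droplet CSV and plate manifest
#'
#' Droplet CSV columns: `Well`, `Sample`, `Ch1Amplitude` (FAM),
#' `Ch2Amplitude` (HEX). Manifest columns: `Well`, `Sample`, `Role`,
#' `ReplicateGroup`, `BiofluidVolumeML`.
#'
#' @param wells List of [droplet_well()]s.
#' @param plate_csv,manifest_csv Output paths.
#' @return Invisibly, the two paths.
#' @export
write_droplet_csv <- function(wells, plate_csv, manifest_csv) {
  rows <- do.call(rbind, lapply(wells, function(w)
    data.frame(Well = w$well_id, Sample = w$sample_id,
               Ch1Amplitude = sprintf("%.4f", w$droplets$fam),
               Ch2Amplitude = sprintf("%.4f", w$droplets$hex),
               stringsAsFactors = FALSE)))
  utils::write.csv(rows, plate_csv, row.names = FALSE, quote = FALSE)
  man <- do.call(rbind, lapply(wells, function(w)
    data.frame(Well = w$well_id, Sample = w$sample_id, Role = w$role,
               ReplicateGroup = w$replicate_group,
               BiofluidVolumeML = w$biofluid_volume_ml,
               stringsAsFactors = FALSE)))
  utils::write.csv(man, manifest_csv, row.names = FALSE, quote = FALSE)
  invisible(c(plate_csv, manifest_csv))
}

#' Read a droplet CSV joined to its plate manifest
#'
#' Every well in the droplet table must appear in the manifest (unknown
#' wells are a hard error); malformed amplitudes report the offending
#' line. A well whose manifest row lacks a biofluid volume is loaded with
#' `biofluid_volume_ml = NA`, which downstream suppresses per-mL outputs.
#'
#' @param plate_csv Droplet CSV (`Well`, `Sample`, `Ch1Amplitude`,
#'   `Ch2Amplitude`).
#' @param manifest_csv Manifest CSV (`Well`, `Sample`, `Role`,
#'   `ReplicateGroup`, `BiofluidVolumeML`).
#' @return List of [droplet_well()]s in manifest order.
#' @export
read_droplet_csv <- function(plate_csv, manifest_csv) {
  d <- utils::read.csv(plate_csv, stringsAsFactors = FALSE)
  if (nrow(d) == 0L)
    stop("droplet CSV contains no droplets: ", plate_csv, call. = FALSE)
  need <- c("Well", "Sample", "Ch1Amplitude", "Ch2Amplitude")
  if (!all(need %in% names(d)))
    stop("droplet CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  for (cc in c("Ch1Amplitude", "Ch2Amplitude")) {
    v <- suppressWarnings(as.numeric(d[[cc]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("malformed amplitude in %s at line %d (column %s)",
                   plate_csv, bad[1L] + 1L, cc), call. = FALSE)
    d[[cc]] <- v
  }
  man <- utils::read.csv(manifest_csv, stringsAsFactors = FALSE)
  unknown <- setdiff(unique(d$Well), man$Well)
  if (length(unknown))
    stop("wells absent from manifest: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  man <- man[man$Well %in% d$Well, , drop = FALSE]
  lapply(seq_len(nrow(man)), function(i) {
    m <- man[i, ]
    dd <- d[d$Well == m$Well, , drop = FALSE]
    droplet_well(m$Well, m$Sample, m$Role,
                 data.frame(fam = dd$Ch1Amplitude, hex = dd$Ch2Amplitude),
                 replicate_group = m$ReplicateGroup,
                 biofluid_volume_ml =
                   if ("BiofluidVolumeML" %in% names(m))
                     as.numeric(m$BiofluidVolumeML) else NA_real_)
  })
}

#' Serialize a gate set to a plain-text config for audit
#'
#' @param gates A [gate_set()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gates <- function(gates, path) {
  lines <- c(sprintf("fam_threshold\t%.6f", gates$fam_threshold),
             sprintf("hex_threshold\t%.6f", gates$hex_threshold),
             sprintf("gate\t%s\t%.6f\t%.6f", gates$target_gates$target_id,
                     gates$target_gates$fam_low,
                     gates$target_gates$fam_high))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gate set written by [write_gates()]
#'
#' @param path Gate config path.
#' @return A [gate_set()].
#' @export
read_gates <- function(path) {
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  keys <- vapply(lines, `[[`, "", 1L)
  g <- lines[keys == "gate"]
  gate_set(
    fam_threshold = as.numeric(lines[[which(keys == "fam_threshold")]][2]),
    hex_threshold = as.numeric(lines[[which(keys == "hex_threshold")]][2]),
    target_gates = data.frame(
      target_id = vapply(g, `[[`, "", 2L),
      fam_low = as.numeric(vapply(g, `[[`, "", 3L)),
      fam_high = as.numeric(vapply(g, `[[`, "", 4L)),
      stringsAsFactors = FALSE))
}

#' Write per-well classification counts as TSV
#'
#' Long format: one row per (well, class) with the droplet count.
#'
#' @param classified List of `classified_well`s.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_classification_tsv <- function(classified, path) {
  rows <- do.call(rbind, lapply(classified, function(cw) {
    per_t <- do.call(rbind, lapply(seq_len(nrow(cw$counts)), function(i)
      data.frame(class = c(sprintf("target_only(%s)",
                                   cw$counts$target_id[i]),
                           sprintf("target_and_reference(%s)",
                                   cw$counts$target_id[i])),
                 count = c(cw$counts$target_only[i],
                           cw$counts$target_and_reference[i]))))
    base <- data.frame(class = c("empty", "reference_only", "unassigned"),
                       count = c(cw$empty, cw$reference_only,
                                 cw$unassigned))
    out <- rbind(base, per_t)
    out$well <- cw$well_id
    out$sample <- cw$sample_id
    out[, c("well", "sample", "class", "count")]
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
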