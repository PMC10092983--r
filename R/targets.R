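# Post-calling somatic filter chains and ddPCR target prioritization.
#
# Variant records are plain data.frames (one row per candidate) with the
# annotation fields the filter chains test. SNV/indel retention:
#   PASS  AND  tumor alternate allele count >= 5
#   AND (MAX_AF <= 0.001 OR MAX_AF absent)
#   AND (CADD_PHRED >= 20 OR CADD_PHRED absent)
#   AND IMPACT in {HIGH, MODERATE}.
# SV retention:
#   PASS AND PR >= 5 AND SR >= 5 (tumor)
#   AND <= 1 supportive read in the matched normal AND SOMATICSCORE >= 50.
# Absence is tolerated exactly where the rule says so (MAX_AF, CADD);
# a record missing a required annotation fails with reason "unannotated".

.variant_cols <- c("kind", "chrom", "pos", "end", "ref", "alt", "svtype",
                   "filter_status", "alt_count", "max_af", "cadd_phred",
                   "impact", "pr_tumor", "sr_tumor", "normal_support",
                   "somaticscore", "gene")

#' Assemble a variant record table
#'
#' Fills unspecified annotation columns with `NA` so that filter chains
#' can test presence/absence uniformly.
#'
#' @param df data.frame with at least `kind` (`"snv_indel"` or `"sv"`),
#'   `chrom`, `pos`.
#' @return data.frame with the full variant-record column set.
#' @export
variant_records <- function(df) {
  stopifnot(is.data.frame(df), all(c("kind", "chrom", "pos") %in% names(df)))
  if (!all(df$kind %in% c("snv_indel", "sv")))
    stop("`kind` must be 'snv_indel' or 'sv'", call. = FALSE)
  for (cc in setdiff(.variant_cols, names(df)))
    df[[cc]] <- rep(NA, nrow(df))
  df[, c(.variant_cols, setdiff(names(df), .variant_cols)), drop = FALSE]
}

#' Selection criteria for patient-specific ddPCR targets
#'
#' @param snv,sv Named lists of thresholds (see defaults).
#' @param min_targets Minimum assay targets per patient (default 2).
#' @return List of class `selection_criteria`.
#' @export
selection_criteria <- function(snv = list(min_alt_count = 5,
                                          max_af = 0.001,
                                          min_cadd = 20,
                                          impacts = c("HIGH", "MODERATE"),
                                          require_pass = TRUE),
                               sv = list(min_pr = 5, min_sr = 5,
                                         max_normal_support = 1,
                                         min_somaticscore = 50,
                                         require_pass = TRUE),
                               min_targets = 2L) {
  structure(list(snv = snv, sv = sv, min_targets = min_targets),
            class = "selection_criteria")
}

#' Filter somatic SNV/indel candidates
#'
#' @param records Variant record data.frame (kind `snv_indel`).
#' @param criteria A [selection_criteria()].
#' @return The retained subset, input order preserved, with attribute
#'   `"rejected"`: the rejected rows plus a `reason` column.
#' @export
filter_somatic_snv <- function(records, criteria = selection_criteria()) {
  records <- variant_records(records)
  if (!all(records$kind == "snv_indel"))
    stop("records must all be kind 'snv_indel'", call. = FALSE)
  cr <- criteria$snv
  reason <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    reason[i] <-
      if (is.na(r$impact) || is.na(r$alt_count)) "unannotated"
      else if (cr$require_pass &&
               (is.na(r$filter_status) || r$filter_status != "PASS"))
        "not PASS"
      else if (r$alt_count < cr$min_alt_count) "alt_count below minimum"
      else if (!is.na(r$max_af) && r$max_af > cr$max_af)
        "population frequency too high"
      else if (!is.na(r$cadd_phred) && r$cadd_phred < cr$min_cadd)
        "CADD below minimum"
      else if (!(r$impact %in% cr$impacts)) "impact class excluded"
      else ""
  }
  keep <- reason == ""
  out <- records[keep, , drop = FALSE]
  rej <- records[!keep, , drop = FALSE]
  rej$reason <- reason[!keep]
  attr(out, "rejected") <- rej
  out
}

#' Filter somatic structural-variant candidates
#'
#' @param records Variant record data.frame (kind `sv`).
#' @param criteria A [selection_criteria()].
#' @return The retained subset, input order preserved, with attribute
#'   `"rejected"` as in [filter_somatic_snv()].
#' @export
filter_somatic_sv <- function(records, criteria = selection_criteria()) {
  records <- variant_records(records)
  if (!all(records$kind == "sv"))
    stop("records must all be kind 'sv'", call. = FALSE)
  cr <- criteria$sv
  reason <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    reason[i] <-
      if (is.na(r$pr_tumor) || is.na(r$sr_tumor)) "unannotated"
      else if (cr$require_pass &&
               (is.na(r$filter_status) || r$filter_status != "PASS"))
        "not PASS"
      else if (r$pr_tumor < cr$min_pr) "PR support below minimum"
      else if (r$sr_tumor < cr$min_sr) "SR support below minimum"
      else if (is.na(r$normal_support) ||
               r$normal_support > cr$max_normal_support)
        "supported in matched normal"
      else if (is.na(r$somaticscore) ||
               r$somaticscore < cr$min_somaticscore)
        "SOMATICSCORE below minimum"
      else ""
  }
  keep <- reason == ""
  out <- records[keep, , drop = FALSE]
  rej <- records[!keep, , drop = FALSE]
  rej$reason <- reason[!keep]
  attr(out, "rejected") <- rej
  out
}

#' Load gene lists for target prioritization
#'
#' Plain-text files, one gene symbol per line, `#` comments allowed. The
#' bundled example lists name genes recurrently altered in
#' medulloblastoma and an excerpt of cancer-census genes; users should
#' substitute their own curated lists.
#'
#' @param mb_recurrent,cancer_census File paths; defaults are the bundled
#'   lists under `inst/extdata/gene_lists`.
#' @return Named list of character vectors.
#' @export
read_gene_lists <- function(
    mb_recurrent = system.file("extdata", "gene_lists", "mb_recurrent.txt",
                               package = "ddmrd"),
    cancer_census = system.file("extdata", "gene_lists",
                                "cancer_census_excerpt.txt",
                                package = "ddmrd")) {
  read1 <- function(p) {
    x <- trimws(readLines(p))
    x[nzchar(x) & !startsWith(x, "#")]
  }
  list(mb_recurrent = read1(mb_recurrent),
       cancer_census = read1(cancer_census))
}

#' Rank retained variants into a patient-specific assay panel
#'
#' Rank key: gene-list tier first (recurrent-in-MB > cancer census >
#' other), then read support descending (tumor alternate allele count for
#' SNVs, `min(PR, SR)` for SVs). The selected panel takes the top-ranked
#' candidates but prefers a mixed panel — when both kinds survive, the
#' best SNV and the best SV are always included. A panel with fewer than
#' `min_targets` survivors is emitted with an under-target flag.
#'
#' @param records Retained variant records (SNV and/or SV, may be mixed).
#' @param gene_lists Named list from [read_gene_lists()].
#' @param min_targets Minimum panel size (default 2).
#' @return The records ranked, with columns `tier`, `support`, `rank`,
#'   `selected`; attribute `"under_target"` is `TRUE` when fewer than
#'   `min_targets` candidates survive.
#' @export
prioritize_targets <- function(records, gene_lists = read_gene_lists(),
                               min_targets = 2L) {
  records <- variant_records(records)
  if (nrow(records) == 0L) {
    warning("no surviving variants: empty panel", call. = FALSE)
    out <- cbind(records, tier = integer(0), support = numeric(0),
                 rank = integer(0), selected = logical(0))
    attr(out, "under_target") <- TRUE
    return(out)
  }
  tier <- ifelse(records$gene %in% gene_lists$mb_recurrent, 1L,
          ifelse(records$gene %in% gene_lists$cancer_census, 2L, 3L))
  support <- ifelse(records$kind == "snv_indel",
                    records$alt_count,
                    pmin(records$pr_tumor, records$sr_tumor))
  support[is.na(support)] <- 0
  ord <- order(tier, -support)
  out <- records[ord, , drop = FALSE]
  out$tier <- tier[ord]
  out$support <- support[ord]
  out$rank <- seq_len(nrow(out))

  n_pick <- min(min_targets, nrow(out))
  picked <- integer(0)
  if (all(c("snv_indel", "sv") %in% out$kind) && n_pick >= 2L)
    picked <- c(which(out$kind == "snv_indel")[1L],
                which(out$kind == "sv")[1L])
  picked <- union(picked, seq_len(nrow(out)))[seq_len(max(n_pick,
                                                          length(picked)))]
  out$selected <- seq_len(nrow(out)) %in% picked
  attr(out, "under_target") <- nrow(out) < min_targets
  rownames(out) <- NULL
  out
}

#' Restrict targets to variants shared between two timepoints
#'
#' For relapsed cases, assay targets must be present in both the primary
#' tumor and the secondary lesion. SNVs are matched exactly on
#' (chrom, pos, ref, alt); SV breakpoints are matched per chromosome and
#' SV type within a coordinate window.
#'
#' @param primary,relapse Variant record data.frames from the same
#'   patient.
#' @param sv_window Breakpoint matching tolerance in bp (default 10).
#' @return The rows of `primary` that have a match in `relapse`.
#' @export
intersect_timepoints <- function(primary, relapse, sv_window = 10L) {
  primary <- variant_records(primary)
  relapse <- variant_records(relapse)
  if (nrow(primary) == 0L) return(primary)
  keep <- vapply(seq_len(nrow(primary)), function(i) {
    p <- primary[i, ]
    if (p$kind == "snv_indel") {
      any(relapse$kind == "snv_indel" &
            relapse$chrom == p$chrom & relapse$pos == p$pos &
            relapse$ref == p$ref & relapse$alt == p$alt)
    } else {
      cand <- relapse$kind == "sv" & relapse$chrom == p$chrom &
        (is.na(p$svtype) | is.na(relapse$svtype) |
           relapse$svtype == p$svtype) &
        abs(relapse$pos - p$pos) <= sv_window
      if (!is.na(p$end))
        cand <- cand & (is.na(relapse$end) |
                          abs(relapse$end - p$end) <= sv_window)
      any(cand, na.rm = TRUE)
    }
  }, TRUE)
  primary[keep, , drop = FALSE]
}
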