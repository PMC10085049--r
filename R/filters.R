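#' Per-caller retention thresholds
#'
#' Bundles every threshold of the call-retention stage. Defaults are the
#' workflow's operating values: calls between 1 kb and 5 Mb; CNVnator calls
#' significant at p < 0.05 with a fraction of zero-mapping-quality reads
#' (q0) below 0.5; DELLY calls supported by at least five read pairs;
#' PennCNV calls with at least 10 markers from samples passing array QC
#' (LRR SD <= 0.30, BAF drift <= 0.01, |waviness factor| <= 0.05).
#'
#' Size bounds are inclusive on both ends. `penncnv_strict_gt` switches the
#' marker rule from `num_snps >= penncnv_min_snps` to a strict `>`.
#'
#' @param min_size_bp,max_size_bp Inclusive size bounds in bp.
#' @param cnvnator_max_p CNVnator e-value threshold (retain `p <` this).
#' @param cnvnator_max_q0 q0 threshold (retain `q0 <` this).
#' @param delly_min_pe Minimum paired-end support (retain `pe >=` this).
#' @param penncnv_min_snps Minimum markers per call.
#' @param penncnv_strict_gt Use strict `>` for the marker rule.
#' @param lrr_sd_max,baf_drift_max,wf_max Per-sample array QC limits; the
#'   waviness factor is compared by absolute value.
#' @param exclude_delly_singletons Drop DELLY records carried by a single
#'   animal instead of only labelling them.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_size_bp = 1000, max_size_bp = 5e6,
                          cnvnator_max_p = 0.05, cnvnator_max_q0 = 0.5,
                          delly_min_pe = 5, penncnv_min_snps = 10,
                          penncnv_strict_gt = FALSE,
                          lrr_sd_max = 0.30, baf_drift_max = 0.01,
                          wf_max = 0.05, exclude_delly_singletons = FALSE) {
  cfg <- list(min_size_bp = min_size_bp, max_size_bp = max_size_bp,
              cnvnator_max_p = cnvnator_max_p, cnvnator_max_q0 = cnvnator_max_q0,
              delly_min_pe = delly_min_pe, penncnv_min_snps = penncnv_min_snps,
              penncnv_strict_gt = penncnv_strict_gt,
              lrr_sd_max = lrr_sd_max, baf_drift_max = baf_drift_max,
              wf_max = wf_max,
              exclude_delly_singletons = exclude_delly_singletons)
  num <- unlist(cfg[!names(cfg) %in% c("penncnv_strict_gt", "exclude_delly_singletons")])
  if (any(!is.finite(num))) stop("all filter thresholds must be finite")
  if (cfg$min_size_bp >= cfg$max_size_bp) stop("min_size_bp must be < max_size_bp")
  structure(cfg, class = "filter_config")
}

size_in_bounds <- function(calls, cfg) {
  len <- call_length(calls)
  len >= cfg$min_size_bp & len <= cfg$max_size_bp
}

#' Filter CNVnator calls
#'
#' Retains calls with size within bounds, e-value below `cnvnator_max_p`
#' and q0 below `cnvnator_max_q0`. Input order is preserved; calls are only
#' dropped, never modified.
#'
#' @param calls `cnv_calls` rows with source `CNVNATOR`.
#' @param cfg A [filter_config()].
#' @return The retained subset.
#' @export
filter_cnvnator <- function(calls, cfg = filter_config()) {
  if (nrow(calls) == 0) return(calls)
  stopifnot(all(calls$source == "CNVNATOR"))
  miss <- is.na(calls$p_value) | is.na(calls$q0)
  if (any(miss)) {
    stop("CNVnator call without p_value/q0: ",
         sprintf("%s:%d-%d (%s)", calls$chrom[miss][1], calls$start[miss][1],
                 calls$end[miss][1], calls$sample_id[miss][1]))
  }
  keep <- size_in_bounds(calls, cfg) &
    calls$p_value < cfg$cnvnator_max_p &
    calls$q0 < cfg$cnvnator_max_q0
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter DELLY calls
#'
#' Retains calls with size within bounds and paired-end support of at least
#' `delly_min_pe` read pairs. With `exclude_delly_singletons`, calls from
#' records carried by a single animal are also dropped.
#'
#' @inheritParams filter_cnvnator
#' @export
filter_delly <- function(calls, cfg = filter_config()) {
  if (nrow(calls) == 0) return(calls)
  stopifnot(all(calls$source == "DELLY"))
  miss <- is.na(calls$pe_support)
  if (any(miss)) {
    stop("DELLY call without pe_support: ",
         sprintf("%s:%d-%d (%s)", calls$chrom[miss][1], calls$start[miss][1],
                 calls$end[miss][1], calls$sample_id[miss][1]))
  }
  keep <- size_in_bounds(calls, cfg) & calls$pe_support >= cfg$delly_min_pe
  if (isTRUE(cfg$exclude_delly_singletons)) {
    keep <- keep & label_populational(calls) == "POPULATIONAL"
  }
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Label calls as populational or singleton
#'
#' A call is POPULATIONAL when its originating record (multi-sample DELLY
#' record, identified by `record_id`) has at least two carrier samples, and
#' SINGLETON when exactly one animal carries it. Calls without a record key
#' are grouped by their coordinates and type.
#'
#' @param calls A `cnv_calls` data.frame.
#' @return Character vector (`"POPULATIONAL"`/`"SINGLETON"`), one per call.
#' @export
label_populational <- function(calls) {
  if (nrow(calls) == 0) return(character(0))
  key <- ifelse(is.na(calls$record_id),
                paste(calls$chrom, calls$start, calls$end, calls$cnv_type),
                calls$record_id)
  n_carriers <- stats::ave(as.integer(!duplicated(paste(key, calls$sample_id))),
                           key, FUN = sum)
  ifelse(n_carriers >= 2, "POPULATIONAL", "SINGLETON")
}

#' Filter PennCNV calls with per-sample array QC
#'
#' First drops every call from samples failing array QC (LRR SD above
#' `lrr_sd_max`, BAF drift above `baf_drift_max`, or absolute waviness
#' factor above `wf_max` -- these are per-sample summary statistics, so the
#' whole sample is removed). Of the remaining calls, retains those with at
#' least `penncnv_min_snps` markers and size within bounds.
#'
#' @inheritParams filter_cnvnator
#' @param qc A [sample_qc()] table covering every sample that has calls.
#' @export
filter_penncnv <- function(calls, qc, cfg = filter_config()) {
  if (nrow(calls) == 0) return(calls)
  stopifnot(all(calls$source == "PENNCNV"))
  missing_qc <- setdiff(unique(calls$sample_id), qc$sample_id)
  if (length(missing_qc)) {
    stop("samples with calls but no QC row: ", paste(missing_qc, collapse = ", "))
  }
  pass_qc <- qc$sample_id[qc$lrr_sd <= cfg$lrr_sd_max &
                            qc$baf_drift <= cfg$baf_drift_max &
                            abs(qc$waviness_factor) <= cfg$wf_max]
  snp_ok <- if (isTRUE(cfg$penncnv_strict_gt)) {
    calls$num_snps > cfg$penncnv_min_snps
  } else {
    calls$num_snps >= cfg$penncnv_min_snps
  }
  keep <- calls$sample_id %in% pass_qc & snp_ok & size_in_bounds(calls, cfg)
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
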