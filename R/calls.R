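#' Construct a table of CNV calls
#'
#' The package's internal representation of caller output is a plain
#' `data.frame` with one row per call and class `cnv_calls`. Coordinates are
#' 1-based inclusive, matching VCF, CNVnator and PennCNV conventions; BED
#' files are converted at the I/O boundary only. Quality columns are
#' source-specific: `p_value` and `q0` for CNVnator, `pe_support` for DELLY,
#' `num_snps` for PennCNV; irrelevant columns hold `NA`.
#'
#' @param sample_id Character vector of sample identifiers.
#' @param chrom Character vector of chromosome labels (leading `"chr"` is
#'   stripped).
#' @param start,end Integer vectors, 1-based inclusive positions in bp.
#' @param cnv_type `"DEL"` or `"DUP"`.
#' @param source `"CNVNATOR"`, `"DELLY"` or `"PENNCNV"`.
#' @param p_value,q0,pe_support,num_snps,copy_number Optional quality fields.
#' @param record_id Optional key shared by calls expanded from the same
#'   multi-sample record (DELLY VCF line).
#' @return A `cnv_calls` data.frame.
#' @export
cnv_calls <- function(sample_id, chrom, start, end, cnv_type, source,
                      p_value = NA_real_, q0 = NA_real_,
                      pe_support = NA_integer_, num_snps = NA_integer_,
                      copy_number = NA_integer_, record_id = NA_character_) {
  n <- max(length(sample_id), length(chrom), length(start), length(end),
           length(cnv_type))
  if (length(start) == 0) n <- 0
  df <- data.frame(
    sample_id   = rep_len(as.character(sample_id), n),
    chrom       = normalize_chrom(rep_len(as.character(chrom), n)),
    start       = rep_len(as.numeric(start), n),
    end         = rep_len(as.numeric(end), n),
    cnv_type    = rep_len(as.character(cnv_type), n),
    source      = rep_len(as.character(source), n),
    p_value     = rep_len(as.numeric(p_value), n),
    q0          = rep_len(as.numeric(q0), n),
    pe_support  = rep_len(as.integer(pe_support), n),
    num_snps    = rep_len(as.integer(num_snps), n),
    copy_number = rep_len(as.integer(copy_number), n),
    record_id   = rep_len(as.character(record_id), n),
    stringsAsFactors = FALSE
  )
  validate_cnv_calls(df)
}

#' @rdname cnv_calls
#' @param df A data.frame with the `cnv_calls` columns.
#' @export
validate_cnv_calls <- function(df) {
  if (nrow(df) > 0) {
    if (any(df$start < 1)) stop("call start positions must be >= 1")
    if (any(df$end < df$start)) stop("call end must be >= start")
    bad_type <- setdiff(unique(df$cnv_type), c("DEL", "DUP"))
    if (length(bad_type)) {
      stop("unknown cnv_type: ", paste(bad_type, collapse = ", "))
    }
    bad_src <- setdiff(unique(df$source), c("CNVNATOR", "DELLY", "PENNCNV"))
    if (length(bad_src)) {
      stop("unknown source: ", paste(bad_src, collapse = ", "))
    }
  }
  class(df) <- unique(c("cnv_calls", class(df)))
  df
}

empty_cnv_calls <- function() {
  cnv_calls(character(0), character(0), numeric(0), numeric(0),
            character(0), character(0))
}

#' Call length in bp (1-based inclusive)
#'
#' @param x A `cnv_calls` or `cnvr_set` data.frame, or anything with
#'   `start`/`end` columns.
#' @return Numeric vector of `end - start + 1`.
#' @export
call_length <- function(x) x$end - x$start + 1

#' Normalize chromosome labels
#'
#' Strips a leading `"chr"` prefix and keeps the remaining token as a string,
#' so `"chr7"`, `"Chr7"` and `"7"` all map to `"7"`.
#'
#' @param chrom Character vector.
#' @return Character vector of normalized labels.
#' @export
normalize_chrom <- function(chrom) {
  sub("^[Cc][Hh][Rr]", "", as.character(chrom))
}

#' Restrict calls to an autosome list
#'
#' CNV detection in this workflow is restricted to autosomes; the default
#' list is the 29 bovine autosomes. Calls on other chromosomes are dropped.
#'
#' @param calls A `cnv_calls` data.frame.
#' @param autosomes Character vector of allowed chromosome labels.
#' @return The retained calls, with an attribute `n_dropped`.
#' @export
keep_autosomes <- function(calls, autosomes = as.character(1:29)) {
  keep <- calls$chrom %in% autosomes
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Construct a per-sample SNP-array QC table
#'
#' One row per genotyped sample with the PennCNV per-sample summary
#' statistics used for QC: Log R Ratio standard deviation, B-allele-frequency
#' drift, and the waviness factor (which may be negative).
#'
#' @param sample_id Character vector, one entry per sample.
#' @param lrr_sd,baf_drift,waviness_factor Numeric vectors.
#' @return A `sample_qc` data.frame.
#' @export
sample_qc <- function(sample_id, lrr_sd, baf_drift, waviness_factor) {
  if (anyDuplicated(sample_id)) stop("duplicate sample_id in QC table")
  if (any(lrr_sd < 0) || any(baf_drift < 0)) {
    stop("lrr_sd and baf_drift must be non-negative")
  }
  df <- data.frame(
    sample_id = as.character(sample_id),
    lrr_sd = as.numeric(lrr_sd),
    baf_drift = as.numeric(baf_drift),
    waviness_factor = as.numeric(waviness_factor),
    stringsAsFactors = FALSE
  )
  class(df) <- unique(c("sample_qc", class(df)))
  df
}
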