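#' Build a merged external CNVR catalogue set
#'
#' Merges CNV records pooled from previously published studies at >= 1 bp
#' transitive overlap (coordinates must already be on the query assembly;
#' liftover is the user's responsibility and refused here -- mixed-assembly
#' input cannot be detected from coordinates alone, so an optional
#' `assembly` label is compared when supplied). Study provenance is kept as
#' the set of contributing study ids per region.
#'
#' @param raw_calls Data.frame from [read_external_cnvr()]: `chrom`,
#'   `start`, `end`, `cnv_type`, `study_id`.
#' @return A `cnvr_set` of kind `EXTERNAL`; `sources` holds the study ids.
#' @export
build_external_set <- function(raw_calls) {
  d <- data.frame(chrom = raw_calls$chrom, start = raw_calls$start,
                  end = raw_calls$end, stringsAsFactors = FALSE)
  d$cnv_type <- ifelse(raw_calls$cnv_type %in% c("DEL", "DUP"),
                       raw_calls$cnv_type, NA_character_)
  d$source <- raw_calls$study_id
  merged <- merge_calls(d, kind = "EXTERNAL", name = "external catalogue",
                        id_prefix = "EXT")
  merged
}

#' Match a CNVR set against an external catalogue
#'
#' Two regions are considered equal when their reciprocal overlap is at
#' least `min_ro` (default 50%). Matching is type-agnostic; the matched
#' regions' types and contributing studies are reported so agreement can be
#' inspected.
#'
#' @param unique_set A `cnvr_set` (typically the unique high-confidence
#'   set).
#' @param external A `cnvr_set` from [build_external_set()].
#' @param min_ro Minimum reciprocal overlap.
#' @return A list with `pairs` (per-match table: query region, external
#'   region, reciprocal overlap, studies), `n_matched` (query regions with
#'   >= 1 match), and `unmatched_fraction`.
#' @export
match_external <- function(unique_set, external, min_ro = 0.5) {
  m <- reciprocal_match(unique_set, external, min_ro)
  pairs <- data.frame(
    region_id = m$region_id_a,
    chrom = m$chrom,
    start = unique_set$start[m$a_idx],
    end = unique_set$end[m$a_idx],
    region_type = unique_set$cnvr_type[m$a_idx],
    external_id = m$region_id_b,
    external_start = external$start[m$b_idx],
    external_end = external$end[m$b_idx],
    external_type = external$cnvr_type[m$b_idx],
    ro = m$ro,
    studies = vapply(external$sources[m$b_idx], paste, character(1),
                     collapse = ","),
    stringsAsFactors = FALSE
  )
  n_matched <- length(unique(m$a_idx))
  list(
    pairs = pairs,
    n_matched = n_matched,
    n_query = nrow(unique_set),
    unmatched_fraction = if (nrow(unique_set)) 1 - n_matched / nrow(unique_set) else 0
  )
}

#' @rdname match_external
#' @param report A `match_external()` result.
#' @param path Output TSV path.
#' @export
write_external_report <- function(report, path) {
  utils::write.table(report$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(report[c("n_matched", "n_query", "unmatched_fraction")],
                       paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
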