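#' Truth recovery of a region set
#'
#' Fraction of truth loci overlapped by at least one region of `set`.
#' Recovery follows the overlap bookkeeping convention used throughout
#' region construction: a locus counts as recovered when a region overlaps
#' it by at least `min_overlap_bp` (default 1 bp). Regions legitimately
#' grow beyond the underlying locus when many jittered carrier calls are
#' merged, so reciprocal overlap -- the cross-set *equality* criterion --
#' is deliberately not the default here, but can be requested via
#' `min_ro`.
#'
#' @param set A `cnvr_set`.
#' @param truth A `truth_cnv` data.frame (optionally pre-filtered, e.g. to
#'   loci above a population frequency).
#' @param min_overlap_bp Minimum overlap counting a locus as recovered.
#' @param min_ro Optional: if non-NULL, require this reciprocal overlap
#'   instead of the bp rule.
#' @return Fraction in `[0, 1]` (1 for an empty truth table).
#' @export
truth_recovery <- function(set, truth, min_overlap_bp = 1, min_ro = NULL) {
  if (nrow(truth) == 0) return(1)
  if (nrow(set) == 0) return(0)
  if (!is.null(min_ro)) {
    m <- reciprocal_match(truth, set, min_ro)
    return(length(unique(m$a_idx)) / nrow(truth))
  }
  hit <- logical(nrow(truth))
  for (ch in intersect(unique(truth$chrom), unique(set$chrom))) {
    i <- which(truth$chrom == ch)
    j <- which(set$chrom == ch)
    for (k in i) {
      hit[k] <- any(pmin(truth$end[k], set$end[j]) -
                      pmax(truth$start[k], set$start[j]) + 1 >= min_overlap_bp)
    }
  }
  mean(hit)
}

#' Precision of a region set against truth
#'
#' Fraction of regions that overlap any truth locus by at least
#' `min_overlap_bp`. False-positive regions scattered independently of the
#' truth landscape drive this down; cross-platform consensus drives it up.
#'
#' @param set A `cnvr_set`.
#' @param truth A `truth_cnv` data.frame.
#' @param min_overlap_bp Minimum overlap counting a region as true.
#' @return Fraction in `[0, 1]` (NA for an empty set).
#' @export
set_precision <- function(set, truth, min_overlap_bp = 1) {
  if (nrow(set) == 0) return(NA_real_)
  hit <- logical(nrow(set))
  for (ch in intersect(unique(set$chrom), unique(truth$chrom))) {
    i <- which(set$chrom == ch)
    j <- which(truth$chrom == ch)
    for (k in i) {
      hit[k] <- any(pmin(set$end[k], truth$end[j]) -
                      pmax(set$start[k], truth$start[j]) + 1 >= min_overlap_bp)
    }
  }
  mean(hit)
}
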