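#' Overlap CNVRs with genomic features
#'
#' Reports every (region, feature) pair sharing at least `min_overlap_bp`
#' (default 1 bp, inclusive arithmetic): a gene touching a region by a
#' single base is reported, a book-ended gene is not. Operates on whole
#' feature spans; exon-level resolution requires exon sub-intervals in the
#' feature table.
#'
#' @param set A `cnvr_set`.
#' @param features A [genomic_features()] data.frame.
#' @param min_overlap_bp Minimum overlap in bp.
#' @return A list with `by_region` (region id -> sorted feature ids),
#'   `by_feature` (the inverse map) and `pairs` (flat table with overlap
#'   bp, feature category and subcategory).
#' @export
overlap_features <- function(set, features, min_overlap_bp = 1) {
  stopifnot(is_count(min_overlap_bp), min_overlap_bp >= 1)
  rows <- list()
  for (ch in intersect(unique(set$chrom), unique(features$chrom))) {
    ir <- which(set$chrom == ch)
    jf <- which(features$chrom == ch)
    pairs <- expand.grid(i = ir, j = jf, KEEP.OUT.ATTRS = FALSE)
    ov <- pmin(set$end[pairs$i], features$end[pairs$j]) -
      pmax(set$start[pairs$i], features$start[pairs$j]) + 1
    hit <- ov >= min_overlap_bp
    if (any(hit)) {
      rows[[ch]] <- data.frame(
        region_id = set$region_id[pairs$i[hit]],
        region_type = set$cnvr_type[pairs$i[hit]],
        chrom = ch,
        feature_id = features$feature_id[pairs$j[hit]],
        category = features$category[pairs$j[hit]],
        subcategory = features$subcategory[pairs$j[hit]],
        p_value = features$p_value[pairs$j[hit]],
        overlap_bp = ov[hit],
        stringsAsFactors = FALSE
      )
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(region_id = character(0), region_type = character(0),
               chrom = character(0), feature_id = character(0),
               category = character(0), subcategory = character(0),
               p_value = numeric(0), overlap_bp = numeric(0),
               stringsAsFactors = FALSE)
  }
  pairs <- pairs[order(pairs$region_id, pairs$feature_id), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(
    by_region = lapply(split(pairs$feature_id, pairs$region_id), function(x) sort(unique(x))),
    by_feature = lapply(split(pairs$region_id, pairs$feature_id), function(x) sort(unique(x))),
    pairs = pairs,
    n_regions = nrow(set)
  ), class = "cnvr_annotation")
}

pct <- function(num, den) if (den > 0) round(num / den * 100, 2) else 0

#' Summarize CNVR feature annotation
#'
#' Counts annotated regions and overlapped genes/pseudogenes/QTL, with
#' percentages computed as `count / total * 100` rounded to two decimals.
#' QTL are broken down by trait class (subcategory) and by the type of the
#' region they overlap (deletion / duplication / complex). When QTL rows
#' carry database-recorded p-values, `qtl_max_p` restricts the trait-class
#' breakdown to significant associations (pure pass-through filter; no
#' p-values are recomputed).
#'
#' @param overlaps Result of [overlap_features()].
#' @param qtl_max_p Optional p-value cutoff for the QTL breakdown.
#' @return A list of counts, percentages and breakdown tables.
#' @export
summarize_annotation <- function(overlaps, qtl_max_p = NULL) {
  pairs <- overlaps$pairs
  n_regions <- overlaps$n_regions
  gene_pairs <- pairs[pairs$category %in% c("GENE", "PSEUDOGENE"), , drop = FALSE]
  qtl_pairs <- pairs[pairs$category == "QTL", , drop = FALSE]
  if (!is.null(qtl_max_p)) {
    qtl_pairs <- qtl_pairs[!is.na(qtl_pairs$p_value) &
                             qtl_pairs$p_value < qtl_max_p, , drop = FALSE]
  }
  annotated_regions <- unique(gene_pairs$region_id)
  qtl_regions <- unique(qtl_pairs$region_id)

  qtl_ids <- unique(qtl_pairs$feature_id)
  if (length(qtl_ids)) {
    class_of <- qtl_pairs$subcategory[match(qtl_ids, qtl_pairs$feature_id)]
    class_counts <- table(class_of, useNA = "ifany")
    class_tbl <- data.frame(
      trait_class = names(class_counts),
      n_qtl = as.integer(class_counts),
      pct_qtl = vapply(as.integer(class_counts), pct, numeric(1),
                       den = length(qtl_ids)),
      stringsAsFactors = FALSE
    )
    class_tbl <- class_tbl[order(-class_tbl$n_qtl, class_tbl$trait_class), ,
                           drop = FALSE]
    rownames(class_tbl) <- NULL
  } else {
    class_tbl <- data.frame(trait_class = character(0), n_qtl = integer(0),
                            pct_qtl = numeric(0), stringsAsFactors = FALSE)
  }

  # each QTL is attributed to the type(s) of region it overlaps
  type_of <- unique(qtl_pairs[, c("feature_id", "region_type")])
  type_counts <- table(factor(type_of$region_type,
                              levels = c("DELETION", "DUPLICATION", "COMPLEX")))
  type_tbl <- data.frame(
    region_type = names(type_counts),
    n_qtl = as.integer(type_counts),
    pct_qtl = vapply(as.integer(type_counts), pct, numeric(1),
                     den = length(qtl_ids)),
    stringsAsFactors = FALSE
  )

  list(
    n_regions = n_regions,
    n_genes = length(unique(gene_pairs$feature_id[gene_pairs$category == "GENE"])),
    n_pseudogenes = length(unique(gene_pairs$feature_id[gene_pairs$category == "PSEUDOGENE"])),
    n_annotated_regions = length(annotated_regions),
    pct_annotated_regions = pct(length(annotated_regions), n_regions),
    n_qtl = length(qtl_ids),
    n_qtl_regions = length(qtl_regions),
    pct_qtl_regions = pct(length(qtl_regions), n_regions),
    qtl_by_class = class_tbl,
    qtl_by_region_type = type_tbl
  )
}

#' @rdname summarize_annotation
#' @param path Output TSV path for the flat region/feature table.
#' @export
write_annotation <- function(overlaps, path) {
  utils::write.table(overlaps$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
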