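#' Write a CNVR set as BED6+
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open, so
#' `start_bed = start - 1` and `end_bed = end`. Columns: chrom, start, end,
#' region id, region type, carrier count, frequency (`.` when unset).
#'
#' @param set A `cnvr_set`.
#' @param path Output path.
#' @export
write_cnvr_bed <- function(set, path) {
  if (nrow(set) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%d\t%s",
                   set$chrom, as.integer(set$start - 1), as.integer(set$end),
                   set$region_id, set$cnvr_type, set$n_carriers,
                   ifelse(is.na(set$frequency), ".",
                          formatC(set$frequency, format = "g", digits = 8)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_cnvr_bed
#' @param kind,name Set labels for the reconstructed `cnvr_set`.
#' @return `read_cnvr_bed()` returns a `cnvr_set`; carrier identities are
#'   not stored in BED, so only the carrier count survives a round trip.
#' @export
read_cnvr_bed <- function(path, kind = "UNIQUE", name = kind) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
  if (length(lines) == 0) {
    return(cnvr_set(character(0), numeric(0), numeric(0), list(), kind = kind,
                    name = name))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 5)) stop("CNVR BED needs at least 5 columns")
  mat <- do.call(rbind, lapply(f, function(x) x[1:7][seq_len(7)]))
  bed_start <- as.numeric(mat[, 2])
  bed_end <- as.numeric(mat[, 3])
  if (any(bed_end <= bed_start)) {
    stop(sprintf("BED line %d: end <= start", which(bed_end <= bed_start)[1]))
  }
  types <- lapply(mat[, 5], function(t) switch(t,
    DELETION = "DEL", DUPLICATION = "DUP", COMPLEX = c("DEL", "DUP"),
    stop("unknown region type in BED: ", t)))
  out <- cnvr_set(chrom = normalize_chrom(mat[, 1]), start = bed_start + 1,
                  end = bed_end, types = types, kind = kind, name = name)
  # region ids, carrier counts and frequency re-attached by coordinate match
  key_in <- paste(normalize_chrom(mat[, 1]), bed_start + 1, bed_end)
  key_out <- paste(out$chrom, out$start, out$end)
  idx <- match(key_out, key_in)
  out$region_id <- mat[idx, 4]
  out$n_carriers <- ifelse(is.na(mat[idx, 6]), 0L, as.integer(mat[idx, 6]))
  freq <- mat[idx, 7]
  out$frequency <- suppressWarnings(ifelse(is.na(freq) | freq == ".",
                                           NA_real_, as.numeric(freq)))
  out
}

#' Read genomic features (genes, pseudogenes, QTL) from BED6+
#'
#' Columns: chrom, start (0-based), end, feature id, category
#' (`GENE`/`PSEUDOGENE`/`QTL`), subcategory (e.g. QTL trait class; `.` for
#' none), optional 7th column with a database-recorded p-value.
#'
#' @param path BED path.
#' @return A `genomic_features` data.frame with 1-based inclusive
#'   coordinates.
#' @export
read_feature_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
  if (length(lines) == 0) return(genomic_features())
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 6)) stop("feature BED needs at least 6 columns")
  mat <- do.call(rbind, lapply(f, function(x) x[1:7][seq_len(7)]))
  bed_start <- as.numeric(mat[, 2]); bed_end <- as.numeric(mat[, 3])
  if (any(bed_end <= bed_start)) {
    stop(sprintf("feature BED line %d: end <= start", which(bed_end <= bed_start)[1]))
  }
  genomic_features(
    chrom = normalize_chrom(mat[, 1]), start = bed_start + 1, end = bed_end,
    feature_id = mat[, 4], category = mat[, 5],
    subcategory = ifelse(mat[, 6] == ".", NA_character_, mat[, 6]),
    p_value = suppressWarnings(as.numeric(mat[, 7]))
  )
}

#' Construct a genomic feature table
#'
#' @param chrom,start,end 1-based inclusive coordinates.
#' @param feature_id Identifier (gene symbol, QTL id).
#' @param category `"GENE"`, `"PSEUDOGENE"` or `"QTL"`.
#' @param subcategory Optional grouping (QTL trait class).
#' @param p_value Optional database-recorded association p-value
#'   (pass-through; never recomputed).
#' @return A `genomic_features` data.frame.
#' @export
genomic_features <- function(chrom = character(0), start = numeric(0),
                             end = numeric(0), feature_id = character(0),
                             category = character(0),
                             subcategory = NA_character_,
                             p_value = NA_real_) {
  n <- length(start)
  if (n > 0) {
    bad <- setdiff(unique(as.character(category)), c("GENE", "PSEUDOGENE", "QTL"))
    if (length(bad)) stop("unknown feature category: ", paste(bad, collapse = ", "))
    if (any(end < start)) stop("feature end must be >= start")
  }
  df <- data.frame(
    chrom = normalize_chrom(rep_len(as.character(chrom), n)),
    start = as.numeric(start), end = as.numeric(end),
    feature_id = rep_len(as.character(feature_id), n),
    category = rep_len(as.character(category), n),
    subcategory = rep_len(as.character(subcategory), n),
    p_value = rep_len(as.numeric(p_value), n),
    stringsAsFactors = FALSE
  )
  class(df) <- unique(c("genomic_features", class(df)))
  df
}

#' Read / write an external CNVR catalogue table
#'
#' Tab-separated with header `chrom  start  end  cnv_type  study_id`
#' (1-based inclusive coordinates, assumed on the query assembly).
#'
#' @param path File path.
#' @return A data.frame of external calls.
#' @export
read_external_cnvr <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  need <- c("chrom", "start", "end", "cnv_type", "study_id")
  if (!all(need %in% names(df))) {
    stop("external catalogue needs columns: ", paste(need, collapse = ", "))
  }
  df$chrom <- normalize_chrom(df$chrom)
  bad <- setdiff(unique(df$cnv_type), c("DEL", "DUP", "COMPLEX", "UNKNOWN"))
  if (length(bad)) stop("unknown external cnv_type: ", paste(bad, collapse = ", "))
  if (nrow(df) && any(df$end < df$start)) stop("external record with end < start")
  df
}

#' @rdname read_external_cnvr
#' @param df External call data.frame.
#' @export
write_external_cnvr <- function(df, path) {
  utils::write.table(df[, c("chrom", "start", "end", "cnv_type", "study_id")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
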