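#' Read a CNVnator call table
#'
#' Parses CNVnator's native whitespace-delimited output: one call per line
#' with columns type, `chrom:start-end`, size, normalized read depth, four
#' e-values and the fraction of reads mapped with zero mapping quality (q0).
#' CNVnator reports one file per sample, so the sample id is supplied by the
#' caller. Coordinates are kept 1-based inclusive.
#'
#' CNVnator emits four e-values from different significance tests; the one
#' used for p-value filtering is selectable through `e_value_col` (default
#' the first).
#'
#' @param path Path to the CNVnator output file.
#' @param sample_id Sample identifier to attach to every call.
#' @param e_value_col Which of the four e-value columns to store as
#'   `p_value` (1--4).
#' @param autosomes Chromosome labels retained (default bovine autosomes
#'   1--29); calls elsewhere are dropped.
#' @return A `cnv_calls` data.frame with `p_value` and `q0` populated.
#' @export
read_cnvnator_calls <- function(path, sample_id, e_value_col = 1,
                                autosomes = as.character(1:29)) {
  stopifnot(e_value_col %in% 1:4)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_cnv_calls())
  fields <- strsplit(trimws(lines), "\\s+")
  n_fields <- lengths(fields)
  if (any(n_fields < 9)) {
    stop(sprintf("CNVnator line %d: expected 9 whitespace-delimited columns, got %d",
                 which(n_fields < 9)[1], n_fields[which(n_fields < 9)[1]]))
  }
  mat <- do.call(rbind, fields)
  type_tok <- mat[, 1]
  bad_type <- !type_tok %in% c("deletion", "duplication")
  if (any(bad_type)) {
    stop(sprintf("CNVnator line %d: unknown CNV type token '%s'",
                 which(bad_type)[1], type_tok[which(bad_type)[1]]))
  }
  coords <- parse_region_token(mat[, 2], format = "CNVnator", lines = seq_along(lines))
  p_val <- suppressWarnings(as.numeric(mat[, 4 + e_value_col]))
  q0 <- suppressWarnings(as.numeric(mat[, 9]))
  calls <- cnv_calls(
    sample_id = sample_id,
    chrom = coords$chrom, start = coords$start, end = coords$end,
    cnv_type = ifelse(type_tok == "deletion", "DEL", "DUP"),
    source = "CNVNATOR", p_value = p_val, q0 = q0
  )
  keep_autosomes(calls, autosomes)
}

#' @rdname read_cnvnator_calls
#' @param calls `cnv_calls` rows with source `CNVNATOR` (one sample).
#' @export
write_cnvnator_calls <- function(calls, path) {
  rd <- ifelse(calls$cnv_type == "DEL", 0.5, 1.5)
  p <- format_num(calls$p_value)
  lines <- sprintf("%s\t%s:%d-%d\t%d\t%s\t%s\t%s\t%s\t%s\t%s",
                   ifelse(calls$cnv_type == "DEL", "deletion", "duplication"),
                   calls$chrom, as.integer(calls$start), as.integer(calls$end),
                   as.integer(call_length(calls)), format_num(rd),
                   p, p, p, p, format_num(calls$q0))
  writeLines(lines, path)
  invisible(path)
}

# "chrom:start-end" -> data.frame(chrom, start, end); errors name the line.
parse_region_token <- function(tok, format = "region", lines = seq_along(tok)) {
  m <- regmatches(tok, regexec("^([^:]+):([0-9]+)-([0-9]+)$", tok))
  bad <- lengths(m) != 4
  if (any(bad)) {
    stop(sprintf("%s line %d: malformed coordinate token '%s'",
                 format, lines[which(bad)[1]], tok[which(bad)[1]]))
  }
  mm <- do.call(rbind, m)
  data.frame(chrom = normalize_chrom(mm[, 2]),
             start = as.numeric(mm[, 3]),
             end = as.numeric(mm[, 4]),
             stringsAsFactors = FALSE)
}

format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else format(v, scientific = v != 0 && abs(v) < 1e-3, digits = 8)
  }, character(1))
  out
}

#' Read DELLY structural-variant calls from a VCF
#'
#' Reads a DELLY-style SV VCF (INFO fields `SVTYPE`, `END`, `PE`; per-sample
#' genotype columns) and expands each DEL/DUP record into one call per
#' carrier sample. A carrier is any sample whose genotype contains at least
#' one ALT allele; missing genotypes (`./.`) are non-carriers. Records with
#' other SVTYPEs (INV, TRA, INS, BND) are skipped and counted in the
#' `n_skipped_svtype` attribute; records lacking END are skipped with a
#' warning.
#'
#' @param path Path to the VCF.
#' @param autosomes Chromosome labels retained.
#' @return A `cnv_calls` data.frame with `pe_support` populated and a shared
#'   `record_id` per VCF record; attributes `n_skipped_svtype` and
#'   `n_records`.
#' @export
read_delly_vcf <- function(path, autosomes = as.character(1:29)) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (is.null(vcf@gt) || ncol(vcf@gt) < 2) {
    stop("DELLY VCF has no sample genotype columns: ", path)
  }
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  svtype <- vcfR::extract.info(vcf, element = "SVTYPE")
  endpos <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = "END")))
  pe <- suppressWarnings(as.integer(vcfR::extract.info(vcf, element = "PE")))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = n, dimnames = list(NULL, colnames(vcf@gt)[-1]))

  is_cnv <- svtype %in% c("DEL", "DUP")
  n_skipped <- sum(!is_cnv, na.rm = TRUE) + sum(is.na(svtype))
  no_end <- is_cnv & is.na(endpos)
  if (any(no_end)) {
    warning(sum(no_end), " DEL/DUP record(s) without INFO END skipped")
  }
  keep <- which(is_cnv & !is.na(endpos))

  out <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    i <- keep[k]
    g <- gt[i, ]
    carrier <- !is.na(g) & grepl("1", g, fixed = TRUE)
    if (!any(carrier)) {
      out[[k]] <- NULL
      next
    }
    rid <- fix[i, "ID"]
    if (is.na(rid) || rid == ".") rid <- sprintf("SV%06d", i)
    out[[k]] <- cnv_calls(
      sample_id = names(g)[carrier],
      chrom = fix[i, "CHROM"],
      start = as.numeric(fix[i, "POS"]),
      end = endpos[i],
      cnv_type = svtype[i],
      source = "DELLY",
      pe_support = pe[i],
      record_id = rid
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  calls <- if (length(out)) do.call(rbind, out) else empty_cnv_calls()
  calls <- validate_cnv_calls(calls)
  calls <- keep_autosomes(calls, autosomes)
  attr(calls, "n_skipped_svtype") <- n_skipped
  attr(calls, "n_records") <- n
  calls
}

#' Write a DELLY-style SV VCF
#'
#' Inverse of [read_delly_vcf()] for simulation and round-trip testing: one
#' VCF record per unique `record_id`, with `0/1` genotypes for carriers and
#' `0/0` otherwise.
#'
#' @param calls `cnv_calls` rows with source `DELLY`.
#' @param samples Character vector of all sample columns to emit.
#' @param path Output path.
#' @export
write_delly_vcf <- function(calls, samples, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=cnvrcons-simulator",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=PE,Number=1,Type=Integer,Description=\"Paired-end support\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- character(0)
  if (nrow(calls) > 0) {
    recs <- split(seq_len(nrow(calls)), calls$record_id)
    first <- vapply(recs, `[`, integer(1), 1)
    ord <- order(match(calls$chrom[first], unique(calls$chrom[chrom_order(calls$chrom)])),
                 calls$start[first], calls$end[first])
    recs <- recs[ord]
    body <- vapply(seq_along(recs), function(k) {
      idx <- recs[[k]]
      i <- idx[1]
      gts <- ifelse(samples %in% calls$sample_id[idx], "0/1", "0/0")
      paste(c(calls$chrom[i], as.integer(calls$start[i]), calls$record_id[i],
              "N", sprintf("<%s>", calls$cnv_type[i]), ".", "PASS",
              sprintf("SVTYPE=%s;END=%d;PE=%d", calls$cnv_type[i],
                      as.integer(calls$end[i]), as.integer(calls$pe_support[i])),
              "GT", gts), collapse = "\t")
    }, character(1))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a PennCNV rawcnv file
#'
#' Parses PennCNV's rawcnv lines, e.g.
#' `chr7:9455783-9693750 numsnp=25 length=237,968 state2,cn=1 sample ...`.
#' Copy number below 2 maps to DEL, above 2 to DUP; a copy-neutral `cn=2`
#' line is an error. A mismatch between the `length=` field and the
#' coordinates is reported as a warning only (coordinates win).
#'
#' @param path Path to the rawcnv file.
#' @param autosomes Chromosome labels retained.
#' @return A `cnv_calls` data.frame with `num_snps` and `copy_number`
#'   populated.
#' @export
read_penncnv_rawcnv <- function(path, autosomes = as.character(1:29)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_cnv_calls())
  fields <- strsplit(trimws(lines), "\\s+")
  n_fields <- lengths(fields)
  if (any(n_fields < 5)) {
    stop(sprintf("rawcnv line %d: expected at least 5 columns", which(n_fields < 5)[1]))
  }
  mat <- do.call(rbind, lapply(fields, `[`, 1:5))
  coords <- parse_region_token(mat[, 1], format = "rawcnv", lines = seq_along(lines))
  numsnp <- as.integer(sub("^numsnp=", "", mat[, 2]))
  len_field <- as.numeric(gsub(",", "", sub("^length=", "", mat[, 3])))
  cn <- as.integer(sub("^state[0-9]+,cn=", "", mat[, 4]))
  if (any(is.na(cn))) {
    stop(sprintf("rawcnv line %d: malformed state/cn field '%s'",
                 which(is.na(cn))[1], mat[which(is.na(cn))[1], 4]))
  }
  if (any(cn == 2)) {
    stop(sprintf("rawcnv line %d: cn=2 is copy-neutral, not a CNV", which(cn == 2)[1]))
  }
  real_len <- coords$end - coords$start + 1
  mism <- !is.na(len_field) & len_field != real_len
  if (any(mism)) {
    warning(sum(mism), " rawcnv line(s) with length= field inconsistent with coordinates")
  }
  calls <- cnv_calls(
    sample_id = mat[, 5],
    chrom = coords$chrom, start = coords$start, end = coords$end,
    cnv_type = ifelse(cn < 2, "DEL", "DUP"),
    source = "PENNCNV", num_snps = numsnp, copy_number = cn
  )
  keep_autosomes(calls, autosomes)
}

#' @rdname read_penncnv_rawcnv
#' @param calls `cnv_calls` rows with source `PENNCNV`.
#' @export
write_penncnv_rawcnv <- function(calls, path) {
  cn <- ifelse(is.na(calls$copy_number),
               ifelse(calls$cnv_type == "DEL", 1L, 3L),
               calls$copy_number)
  state <- ifelse(cn < 2, 2L, 5L)
  lines <- sprintf("chr%s:%d-%d numsnp=%d length=%s state%d,cn=%d %s startsnp=NA endsnp=NA",
                   calls$chrom, as.integer(calls$start), as.integer(calls$end),
                   as.integer(calls$num_snps),
                   formatC(as.integer(call_length(calls)), big.mark = ",", format = "d"),
                   state, cn, calls$sample_id)
  writeLines(lines, path)
  invisible(path)
}

#' Read / write the per-sample SNP-array QC table
#'
#' Tab-separated with header `sample_id  lrr_sd  baf_drift  waviness_factor`.
#'
#' @param path File path.
#' @return A `sample_qc` data.frame.
#' @export
read_sample_qc <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "lrr_sd", "baf_drift", "waviness_factor")
  if (!all(need %in% names(df))) {
    stop("QC table must have columns: ", paste(need, collapse = ", "))
  }
  sample_qc(df$sample_id, df$lrr_sd, df$baf_drift, df$waviness_factor)
}

#' @rdname read_sample_qc
#' @param qc A `sample_qc` data.frame.
#' @export
write_sample_qc <- function(qc, path) {
  utils::write.table(qc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
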