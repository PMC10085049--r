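#' CNVR set container
#'
#' A CNVR set is a data.frame of copy-number variation regions with one row
#' per region, sorted by (chromosome, start), carrying list-columns for the
#' member call types, carrier samples and caller provenance, plus a `kind`
#' attribute naming the construction stage (`SEQ`, `GEN`, `POP`, `ANI`,
#' `UNIQUE`, `EXTERNAL`).
#'
#' Region type is derived from member call types: `DELETION` if all members
#' are DEL, `DUPLICATION` if all are DUP, `COMPLEX` when both occur.
#'
#' @param chrom,start,end Region coordinates (1-based inclusive).
#' @param types List of character vectors: member call types per region.
#' @param carriers List of character vectors: carrier sample ids per region.
#' @param sources List of character vectors: caller provenance per region.
#' @param n_members Integer vector: number of contributing calls.
#' @param kind Set kind label.
#' @param name Human-readable set name (defaults to `kind`).
#' @param id_prefix Prefix for generated region ids.
#' @return A `cnvr_set` data.frame.
#' @export
cnvr_set <- function(chrom, start, end, types, carriers = NULL, sources = NULL,
                     n_members = 1L, kind = "SEQ", name = kind,
                     id_prefix = "CNVR") {
  n <- length(start)
  if (is.null(carriers)) carriers <- rep(list(character(0)), n)
  if (is.null(sources)) sources <- rep(list(character(0)), n)
  df <- data.frame(
    region_id = character(n),
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    cnvr_type = character(n),
    n_carriers = integer(n),
    frequency = rep(NA_real_, n),
    n_members = rep_len(as.integer(n_members), n),
    stringsAsFactors = FALSE
  )
  df$types <- lapply(types, function(x) sort(unique(as.character(x))))
  df$carriers <- lapply(carriers, function(x) sort(unique(as.character(x))))
  df$sources <- lapply(sources, function(x) sort(unique(as.character(x))))
  df$cnvr_type <- vapply(df$types, derive_region_type, character(1))
  df$n_carriers <- vapply(df$carriers, length, integer(1))
  if (n > 0 && any(df$end < df$start)) stop("region end must be >= start")
  ord <- order(match(df$chrom, df$chrom[chrom_order(df$chrom)]), df$start, df$end)
  df <- df[ord, , drop = FALSE]
  df$region_id <- sprintf("%s%d", id_prefix, seq_len(n))
  rownames(df) <- NULL
  structure(df, class = c("cnvr_set", "data.frame"), kind = kind, set_name = name)
}

derive_region_type <- function(types) {
  has_del <- "DEL" %in% types
  has_dup <- "DUP" %in% types
  if (has_del && has_dup) "COMPLEX"
  else if (has_del) "DELETION"
  else if (has_dup) "DUPLICATION"
  else "UNKNOWN"
}

#' @export
print.cnvr_set <- function(x, ...) {
  cat(sprintf("CNVR set '%s' (kind %s): %d region(s)",
              attr(x, "set_name"), attr(x, "kind"), nrow(x)))
  if (nrow(x) > 0) {
    cat(sprintf(", %d DELETION / %d DUPLICATION / %d COMPLEX, %s bp covered",
                sum(x$cnvr_type == "DELETION"), sum(x$cnvr_type == "DUPLICATION"),
                sum(x$cnvr_type == "COMPLEX"),
                format(sum(call_length(x)), big.mark = ",")))
  }
  cat("\n")
  invisible(x)
}

# Normalize cnv_calls / cnvr_set / plain interval df into the internal
# merge representation (chrom, start, end + member sets).
as_merge_input <- function(x) {
  if (inherits(x, "cnvr_set")) {
    d <- data.frame(chrom = x$chrom, start = x$start, end = x$end,
                    stringsAsFactors = FALSE)
    d$types <- x$types
    d$carriers <- x$carriers
    d$sources <- x$sources
    d$n_members <- x$n_members
    d
  } else {
    d <- data.frame(chrom = as.character(x$chrom), start = as.numeric(x$start),
                    end = as.numeric(x$end), stringsAsFactors = FALSE)
    d$types <- if (is.list(x$types)) x$types
               else if (!is.null(x$cnv_type)) {
                 lapply(as.character(x$cnv_type), function(t) t[!is.na(t)])
               } else rep(list(character(0)), nrow(d))
    d$carriers <- if (is.list(x$carriers)) x$carriers
                  else if (!is.null(x$sample_id)) {
      lapply(as.character(x$sample_id), function(s) s[!is.na(s)])
    } else rep(list(character(0)), nrow(d))
    d$sources <- if (is.list(x$sources)) x$sources
                 else if (!is.null(x$source)) as.list(as.character(x$source))
                 else rep(list(character(0)), nrow(d))
    d$n_members <- if (!is.null(x$n_members)) as.integer(x$n_members)
                   else rep(1L, nrow(d))
    d
  }
}

#' Merge calls or regions into CNVRs by transitive overlap
#'
#' Groups intervals that overlap by at least `min_overlap_bp` (default 1 bp)
#' into connected components of the overlap graph; each resulting CNVR spans
#' `min(start)`--`max(end)` of its component. Book-ended intervals
#' (`end + 1 == start`) share 0 bp and are NOT merged. Carrier sets, member
#' call types and caller provenance are unioned across the component, and
#' the region type is re-derived (DEL + DUP members give COMPLEX). Output is
#' deterministic: sorted by (chromosome, start).
#'
#' @param x A `cnv_calls` data.frame, a `cnvr_set`, or any data.frame with
#'   `chrom`, `start`, `end` (and optionally `cnv_type`, `sample_id`,
#'   `source`) columns.
#' @param min_overlap_bp Minimum pairwise overlap in bp to connect two
#'   intervals (>= 1).
#' @param kind,name,id_prefix Passed to [cnvr_set()].
#' @return A `cnvr_set`.
#' @export
merge_calls <- function(x, min_overlap_bp = 1, kind = "SEQ", name = kind,
                        id_prefix = "CNVR") {
  stopifnot(is_count(min_overlap_bp), min_overlap_bp >= 1)
  d <- as_merge_input(x)
  if (nrow(d) == 0) {
    return(cnvr_set(character(0), numeric(0), numeric(0), list(),
                    kind = kind, name = name, id_prefix = id_prefix))
  }
  ord <- order(d$chrom, d$start, d$end)
  d <- d[ord, , drop = FALSE]
  if (min_overlap_bp == 1) {
    # linear sweep: a new component starts when the next interval does not
    # reach back into the running max end
    cme <- stats::ave(d$end, d$chrom, FUN = cummax)
    new_chrom <- c(TRUE, d$chrom[-1] != d$chrom[-nrow(d)])
    gap <- c(TRUE, d$start[-1] > cme[-nrow(d)])
    grp <- cumsum(new_chrom | gap)
  } else {
    # exact connected components for stricter overlap requirements
    grp <- integer(nrow(d))
    offset <- 0L
    for (ch in unique(d$chrom)) {
      idx <- which(d$chrom == ch)
      s <- d$start[idx]; e <- d$end[idx]
      ei <- integer(0); ej <- integer(0)
      for (i in seq_along(idx)) {
        j <- which(pmin(e[i], e) - pmax(s[i], s) + 1 >= min_overlap_bp)
        j <- j[j > i]
        ei <- c(ei, rep(i, length(j))); ej <- c(ej, j)
      }
      comp <- uf_components(length(idx), ei, ej)
      grp[idx] <- offset + match(comp, unique(comp))
      offset <- offset + length(unique(comp))
    }
  }
  groups <- split(seq_len(nrow(d)), grp)
  cnvr_set(
    chrom = vapply(groups, function(i) d$chrom[i[1]], character(1)),
    start = vapply(groups, function(i) min(d$start[i]), numeric(1)),
    end = vapply(groups, function(i) max(d$end[i]), numeric(1)),
    types = lapply(groups, function(i) unlist(d$types[i])),
    carriers = lapply(groups, function(i) unlist(d$carriers[i])),
    sources = lapply(groups, function(i) unlist(d$sources[i])),
    n_members = vapply(groups, function(i) sum(d$n_members[i]), numeric(1)),
    kind = kind, name = name, id_prefix = id_prefix
  )
}

# Elementwise reciprocal overlap on coordinate vectors (1-based inclusive).
ro_vec <- function(a_start, a_end, b_start, b_end) {
  ov <- pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start) + 1)
  pmin(ov / (a_end - a_start + 1), ov / (b_end - b_start + 1))
}

#' Reciprocal overlap of two intervals
#'
#' For two intervals on the same chromosome, the overlap length (1-based
#' inclusive arithmetic) divided by each interval's length; the pair's
#' reciprocal overlap is the minimum of the two fractions. Intervals on
#' different chromosomes have reciprocal overlap 0.
#'
#' @param a,b Data frames (or single rows) with `chrom`, `start`, `end`;
#'   recycled elementwise.
#' @return Numeric vector in `[0, 1]`.
#' @export
reciprocal_overlap <- function(a, b) {
  n <- max(nrow(a) %||% 1, nrow(b) %||% 1, length(a$start), length(b$start))
  same <- rep_len(as.character(a$chrom), n) == rep_len(as.character(b$chrom), n)
  ro <- ro_vec(rep_len(a$start, n), rep_len(a$end, n),
               rep_len(b$start, n), rep_len(b$end, n))
  ifelse(same, ro, 0)
}

#' Match two CNVR sets by minimum reciprocal overlap
#'
#' Returns all cross-set region pairs whose reciprocal overlap reaches
#' `min_ro` (default 50%, the consensus criterion). A region may appear in
#' several pairs; resolving many-to-many matches into final regions is the
#' responsibility of the set builders.
#'
#' @param set_a,set_b `cnvr_set` objects (or data.frames with `chrom`,
#'   `start`, `end`).
#' @param min_ro Minimum reciprocal overlap in `(0, 1]`.
#' @return A data.frame with columns `a_idx`, `b_idx`, `region_id_a`,
#'   `region_id_b`, `chrom`, `ro`, sorted by (chromosome, start of the
#'   A-side region).
#' @export
reciprocal_match <- function(set_a, set_b, min_ro = 0.5) {
  stopifnot(min_ro > 0, min_ro <= 1)
  empty <- data.frame(a_idx = integer(0), b_idx = integer(0),
                      region_id_a = character(0), region_id_b = character(0),
                      chrom = character(0), ro = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(set_a) == 0 || nrow(set_b) == 0) return(empty)
  ida <- set_a$region_id %||% as.character(seq_len(nrow(set_a)))
  idb <- set_b$region_id %||% as.character(seq_len(nrow(set_b)))
  res <- list()
  for (ch in intersect(unique(set_a$chrom), unique(set_b$chrom))) {
    ia <- which(set_a$chrom == ch)
    ib <- which(set_b$chrom == ch)
    # all-pairs on one chromosome, vectorized via index expansion
    pairs <- expand.grid(i = ia, j = ib, KEEP.OUT.ATTRS = FALSE)
    ro <- ro_vec(set_a$start[pairs$i], set_a$end[pairs$i],
                 set_b$start[pairs$j], set_b$end[pairs$j])
    hit <- ro >= min_ro
    if (any(hit)) {
      res[[ch]] <- data.frame(a_idx = pairs$i[hit], b_idx = pairs$j[hit],
                              region_id_a = ida[pairs$i[hit]],
                              region_id_b = idb[pairs$j[hit]],
                              chrom = ch, ro = ro[hit],
                              stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out <- out[order(match(out$chrom, unique(out$chrom[chrom_order(out$chrom)])),
                   set_a$start[out$a_idx], set_a$end[out$a_idx], out$b_idx), ]
  rownames(out) <- NULL
  out
}

#' Carrier frequency of CNVRs
#'
#' Frequency of a region is the number of distinct carrier samples divided
#' by an explicit population size. The denominator is never inferred from
#' the data: the cohort a frequency refers to (e.g. genotyped vs sequenced
#' animals) is an analysis decision.
#'
#' @param region A `cnvr_set` (vectorized over its rows).
#' @param n_individuals Population size (> 0, >= max carrier count).
#' @return Numeric vector of frequencies in `[0, 1]`.
#' @export
region_frequency <- function(region, n_individuals) {
  if (!is_count(n_individuals) || n_individuals <= 0) {
    stop("n_individuals must be a positive integer")
  }
  if (nrow(region) > 0 && max(region$n_carriers) > n_individuals) {
    stop("n_individuals is smaller than a region's carrier count")
  }
  region$n_carriers / n_individuals
}

#' @rdname region_frequency
#' @description `with_frequency()` returns the set with its `frequency`
#'   column filled in.
#' @export
with_frequency <- function(region, n_individuals) {
  region$frequency <- region_frequency(region, n_individuals)
  region
}

#' Total genome coverage of a region set in bp
#'
#' @param set A `cnvr_set`.
#' @return Total bp covered (regions within a merged set are disjoint).
#' @export
covered_bp <- function(set) sum(call_length(set))
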