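# Consensus CNVR set construction.
#
# Two high-confidence constructions are implemented:
#   * population-level (POP): per-caller CNVR from WGS callers are matched
#     across callers at >= 50% reciprocal overlap (SEQ set), then matched
#     against the SNP-array CNVR (GEN set) at the same criterion, and
#     regions carried by at least `min_freq` of the population are kept;
#   * per-animal (ANI): within each dual-platform animal, SNP-array and
#     read-depth calls that reciprocally overlap >= 50% are retained and
#     pooled across animals into regions.
# The union of both sets is the unique high-confidence set used downstream.

# Resolve many-to-many cross-set matches into transitive clusters and emit
# one region per cluster spanning the union of its members.
cluster_matches <- function(set_a, set_b, matches, kind, name = kind,
                            id_prefix = "CNVR") {
  if (nrow(matches) == 0) {
    return(cnvr_set(character(0), numeric(0), numeric(0), list(),
                    kind = kind, name = name, id_prefix = id_prefix))
  }
  na <- nrow(set_a)
  comp <- uf_components(na + nrow(set_b), matches$a_idx, na + matches$b_idx)
  involved <- sort(unique(c(matches$a_idx, na + matches$b_idx)))
  groups <- split(involved, comp[involved])
  pick <- function(i) {
    a <- i[i <= na]
    b <- i[i > na] - na
    list(
      chrom = c(set_a$chrom[a], set_b$chrom[b])[1],
      start = min(set_a$start[a], set_b$start[b]),
      end = max(set_a$end[a], set_b$end[b]),
      types = c(unlist(set_a$types[a]), unlist(set_b$types[b])),
      carriers = c(unlist(set_a$carriers[a]), unlist(set_b$carriers[b])),
      sources = c(unlist(set_a$sources[a]), unlist(set_b$sources[b])),
      n_members = sum(set_a$n_members[a], set_b$n_members[b])
    )
  }
  parts <- lapply(groups, pick)
  cnvr_set(
    chrom = vapply(parts, `[[`, character(1), "chrom"),
    start = vapply(parts, `[[`, numeric(1), "start"),
    end = vapply(parts, `[[`, numeric(1), "end"),
    types = lapply(parts, `[[`, "types"),
    carriers = lapply(parts, `[[`, "carriers"),
    sources = lapply(parts, `[[`, "sources"),
    n_members = vapply(parts, `[[`, numeric(1), "n_members"),
    kind = kind, name = name, id_prefix = id_prefix
  )
}

#' Build the WGS consensus CNVR set (SEQ)
#'
#' Merges each WGS caller's filtered calls into per-caller CNVR (transitive
#' >= 1 bp overlap), keeps the CNVR that participate in a cross-caller
#' reciprocal-overlap match at `min_ro`, and merges matched clusters into
#' consensus regions spanning the union of the matched intervals. Region
#' type is re-derived from all member calls, so a deletion matching a
#' duplication yields a COMPLEX region.
#'
#' @param cnvnator_calls,delly_calls Filtered `cnv_calls`.
#' @param min_ro Minimum cross-caller reciprocal overlap.
#' @return A `cnvr_set` of kind `SEQ`.
#' @export
build_cnvr_seq <- function(cnvnator_calls, delly_calls, min_ro = 0.5) {
  if (nrow(cnvnator_calls) == 0 || nrow(delly_calls) == 0) {
    warning("empty call list from a WGS caller; SEQ set is empty")
  }
  cn <- merge_calls(cnvnator_calls, kind = "CALLER", name = "CNVnator")
  dl <- merge_calls(delly_calls, kind = "CALLER", name = "DELLY")
  m <- reciprocal_match(cn, dl, min_ro)
  out <- cluster_matches(cn, dl, m, kind = "SEQ", name = "CNVR_SEQ")
  attr(out, "n_caller_regions") <- c(CNVNATOR = nrow(cn), DELLY = nrow(dl))
  out
}

#' Build the SNP-array CNVR set (GEN)
#'
#' Merges filtered PennCNV calls into CNVR at >= 1 bp transitive overlap.
#'
#' @param penncnv_calls Filtered `cnv_calls`.
#' @return A `cnvr_set` of kind `GEN`.
#' @export
build_cnvr_gen <- function(penncnv_calls) {
  merge_calls(penncnv_calls, kind = "GEN", name = "CNVR_GEN")
}

#' Build the population-level high-confidence set (POP)
#'
#' Matches the SNP-array (GEN) and WGS-consensus (SEQ) sets at `min_ro`
#' reciprocal overlap, resolves matches into transitive clusters whose
#' regions span the union of the matched intervals, computes carrier
#' frequency as distinct carriers over `n_individuals`, and keeps regions
#' at frequency >= `min_freq` (default 5% -- the common-polymorphism
#' threshold).
#'
#' @param gen,seq `cnvr_set`s from [build_cnvr_gen()] / [build_cnvr_seq()].
#' @param n_individuals Frequency denominator (population size).
#' @param min_freq Minimum carrier frequency.
#' @param min_ro Minimum reciprocal overlap for the GEN/SEQ match.
#' @return A `cnvr_set` of kind `POP` with `frequency` filled in; regions
#'   failing the frequency rule are reported in attribute `n_below_freq`.
#' @export
build_cnvr_pop <- function(gen, seq, n_individuals, min_freq = 0.05,
                           min_ro = 0.5) {
  if (!is_count(n_individuals) || n_individuals <= 0) {
    stop("n_individuals must be a positive integer")
  }
  m <- reciprocal_match(gen, seq, min_ro)
  pop <- cluster_matches(gen, seq, m, kind = "POP", name = "CNVR_POP")
  pop <- with_frequency(pop, n_individuals)
  keep <- pop$frequency >= min_freq
  out <- pop[keep, , drop = FALSE]
  rownames(out) <- NULL
  out$region_id <- sprintf("CNVR%d", seq_len(nrow(out)))
  attr(out, "kind") <- "POP"
  attr(out, "set_name") <- "CNVR_POP"
  attr(out, "n_below_freq") <- sum(!keep)
  class(out) <- c("cnvr_set", "data.frame")
  out
}

#' Build the per-animal high-confidence set (ANI)
#'
#' For each animal with both SNP-array and WGS read-depth data, retains the
#' calls that participate in a within-sample cross-platform match at
#' `min_ro` reciprocal overlap (type-agnostic; region type is re-derived
#' afterwards), pools the retained calls across animals, and merges them at
#' >= 1 bp transitive overlap into regions.
#'
#' @param penncnv_calls,cnvnator_calls Filtered `cnv_calls`.
#' @param samples Animals to use; defaults to those present on both
#'   platforms. Samples present on one platform only are excluded with a
#'   warning.
#' @param min_ro Minimum within-sample reciprocal overlap.
#' @return A `cnvr_set` of kind `ANI`.
#' @export
build_cnvr_ani <- function(penncnv_calls, cnvnator_calls, samples = NULL,
                           min_ro = 0.5) {
  both <- intersect(unique(penncnv_calls$sample_id),
                    unique(cnvnator_calls$sample_id))
  if (is.null(samples)) samples <- both
  partial <- setdiff(samples, both)
  if (length(partial)) {
    warning("samples present on one platform only are excluded: ",
            paste(partial, collapse = ", "))
    samples <- intersect(samples, both)
  }
  kept <- list()
  for (s in samples) {
    p <- penncnv_calls[penncnv_calls$sample_id == s, , drop = FALSE]
    w <- cnvnator_calls[cnvnator_calls$sample_id == s, , drop = FALSE]
    if (nrow(p) == 0 || nrow(w) == 0) next
    m <- reciprocal_match(p, w, min_ro)
    if (nrow(m) == 0) next
    kept[[s]] <- rbind(p[unique(m$a_idx), , drop = FALSE],
                       w[unique(m$b_idx), , drop = FALSE])
  }
  pooled <- if (length(kept)) validate_cnv_calls(do.call(rbind, kept))
            else empty_cnv_calls()
  merge_calls(pooled, kind = "ANI", name = "CNVR_ANI")
}

# TRUE for each region of `a` overlapping (>= 1 bp) any region of `b`.
overlaps_any <- function(a, b) {
  hit <- logical(nrow(a))
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == ch)
    ib <- which(b$chrom == ch)
    for (i in ia) {
      hit[i] <- any(pmin(a$end[i], b$end[ib]) - pmax(a$start[i], b$start[ib]) + 1 >= 1)
    }
  }
  hit
}

#' Merge POP and ANI into the unique high-confidence set
#'
#' The unique set is the >= 1 bp transitive merge of the POP and ANI
#' regions. Each unique region records which source set(s) contributed
#' (`POP`, `ANI` or `BOTH`); `shared_count` is the number of POP regions
#' overlapping at least one ANI region by >= 1 bp.
#'
#' @param pop,ani `cnvr_set`s.
#' @return A list with `set` (kind `UNIQUE`, extra column `set_origin`) and
#'   `shared_count`.
#' @export
build_unique_set <- function(pop, ani) {
  pool <- rbind(as_merge_input(pop), as_merge_input(ani))
  uni <- merge_calls(pool, kind = "UNIQUE", name = "unique high-confidence CNVR")
  from_pop <- overlaps_any(uni, pop)
  from_ani <- overlaps_any(uni, ani)
  uni$set_origin <- ifelse(from_pop & from_ani, "BOTH",
                           ifelse(from_pop, "POP", "ANI"))
  list(set = uni, shared_count = sum(overlaps_any(pop, ani)))
}

#' Summary statistics of a CNVR set
#'
#' @param set A `cnvr_set`.
#' @return A list: region count, type breakdown, size statistics
#'   (mean/min/max/median/SD in bp) and total covered bp.
#' @export
cnvr_summary <- function(set) {
  len <- call_length(set)
  list(
    n_regions = nrow(set),
    n_deletion = sum(set$cnvr_type == "DELETION"),
    n_duplication = sum(set$cnvr_type == "DUPLICATION"),
    n_complex = sum(set$cnvr_type == "COMPLEX"),
    mean_size_bp = if (nrow(set)) mean(len) else 0,
    min_size_bp = if (nrow(set)) min(len) else 0,
    max_size_bp = if (nrow(set)) max(len) else 0,
    median_size_bp = if (nrow(set)) stats::median(len) else 0,
    sd_size_bp = if (nrow(set) > 1) stats::sd(len) else 0,
    total_bp = sum(len)
  )
}

#' Assemble the per-stage build report
#'
#' Collects input/retained call counts and per-set summaries into one
#' structure; the unique-set bookkeeping identity
#' `|UNIQUE| = |POP| + |ANI| - shared` holds when sharing is one-to-one.
#'
#' @param call_counts Named list of per-stage call counts.
#' @param sets Named list of `cnvr_set`s.
#' @param shared_count POP regions overlapping ANI regions.
#' @return A `build_report` list.
#' @export
build_report <- function(call_counts, sets, shared_count = NA_integer_) {
  structure(list(
    call_counts = call_counts,
    set_summaries = lapply(sets, cnvr_summary),
    shared_pop_ani = shared_count
  ), class = "build_report")
}

#' @rdname build_report
#' @param report A `build_report`.
#' @param path Output JSON path.
#' @export
write_build_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
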