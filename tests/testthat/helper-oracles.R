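# Shared fixtures and independent brute-force oracles.
#
# The oracles deliberately avoid the package's sweep/clustering code paths:
# merging is done by exhaustive pairwise adjacency + breadth-first search,
# reciprocal overlap by direct arithmetic on every pair.

empty_calls <- function() {
  cnv_calls(character(0), character(0), numeric(0), numeric(0),
            character(0), character(0))
}

mk_calls <- function(chrom, start, end, type = "DEL", sample = "S1",
                     source = "CNVNATOR", ...) {
  cnv_calls(sample_id = sample, chrom = chrom, start = start, end = end,
            cnv_type = type, source = source, ...)
}

random_intervals_df <- function(n, n_chrom = 3, max_pos = 2000, max_len = 300) {
  start <- sample.int(max_pos, n, replace = TRUE)
  data.frame(
    chrom = as.character(sample.int(n_chrom, n, replace = TRUE)),
    start = start,
    end = start + sample.int(max_len, n, replace = TRUE) - 1,
    cnv_type = sample(c("DEL", "DUP"), n, replace = TRUE),
    sample_id = sample(paste0("S", 1:8), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# Brute-force transitive merge: pairwise overlap graph + BFS components.
bf_merge <- function(df, min_ov = 1) {
  n <- nrow(df)
  if (n == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_members = integer(0)))
  }
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ov <- min(df$end[i], df$end[j]) - max(df$start[i], df$start[j]) + 1
      adj[i, j] <- df$chrom[i] == df$chrom[j] && ov >= min_ov
    }
  }
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    k <- k + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  out <- do.call(rbind, lapply(split(seq_len(n), comp), function(idx) {
    data.frame(chrom = df$chrom[idx[1]], start = min(df$start[idx]),
               end = max(df$end[idx]), n_members = length(idx),
               stringsAsFactors = FALSE)
  }))
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}

# Brute-force reciprocal-overlap matching over all pairs.
bf_match <- function(a, b, min_ro = 0.5) {
  hits <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j]) + 1
      if (ov < 1) next
      ro <- min(ov / (a$end[i] - a$start[i] + 1), ov / (b$end[j] - b$start[j] + 1))
      if (ro >= min_ro) hits[[length(hits) + 1]] <- c(i, j)
    }
  }
  if (!length(hits)) {
    return(data.frame(a_idx = integer(0), b_idx = integer(0)))
  }
  m <- do.call(rbind, hits)
  data.frame(a_idx = m[, 1], b_idx = m[, 2])
}

# canonical string for comparing merge outputs
region_key <- function(df) {
  paste(df$chrom, df$start, df$end, sep = ":")
}

pair_key <- function(df) sort(paste(df$a_idx, df$b_idx, sep = "-"))

# small simulated dataset ready for pipeline-level tests
sim_dataset <- function(out_dir, preset = "zero", n_loci = 25,
                        n_genotyped = 100, n_sequenced = 15, n_dual = 12,
                        seed = 101, qc_fail_fraction = 0) {
  co <- cohort(n_genotyped, n_sequenced, n_dual)
  truth <- simulate_truth(n_loci = n_loci, freq_range = c(0.03, 0.5),
                          seed = seed)
  truth <- assign_carriers(truth, unique(c(co$genotyped, co$sequenced)),
                           seed = seed + 1)
  files <- emit_caller_files(truth, co, noise_preset(preset), out_dir,
                             seed = seed + 2,
                             qc_fail_fraction = qc_fail_fraction)
  list(cohort = co, truth = truth, files = files, out_dir = out_dir)
}

# truth loci satisfying the population-level set definition: detected
# support on both platforms and carrier frequency over the denominator
truth_pop_expected <- function(truth, co, min_freq = 0.05,
                               denom = length(co$genotyped)) {
  qualifies <- vapply(seq_len(nrow(truth)), function(i) {
    carr <- truth$carriers[[i]]
    genc <- intersect(carr, co$genotyped)
    seqc <- intersect(carr, co$sequenced)
    length(genc) > 0 && length(seqc) > 0 &&
      length(union(genc, seqc)) / denom >= min_freq
  }, logical(1))
  truth[qualifies, , drop = FALSE]
}

# truth loci satisfying the per-animal set definition: carried by at least
# one dual-platform animal
truth_ani_expected <- function(truth, co) {
  qualifies <- vapply(truth$carriers, function(carr) {
    length(intersect(carr, co$dual)) > 0
  }, logical(1))
  truth[qualifies, , drop = FALSE]
}

pipeline_from_dir <- function(dir, out = file.path(dir, "res"), ...) {
  pipeline_config(
    cnvnator_dir = file.path(dir, "cnvnator"),
    delly_vcf = file.path(dir, "delly.vcf"),
    penncnv_rawcnv = file.path(dir, "penncnv.rawcnv"),
    sample_qc_path = file.path(dir, "sample_qc.tsv"),
    out_dir = out, ...
  )
}

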