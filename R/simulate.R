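# Call-level simulator.
#
# Simulation operates at the level the pipeline consumes -- caller output
# tables -- not at read or intensity level. A truth landscape of CNV loci
# with population frequencies is drawn, carriers are assigned per animal,
# and each platform emits noisy calls for its own sample list with
# platform-specific false positives (independent across platforms), false
# negatives, Gaussian breakpoint jitter and occasional call splitting.

#' Default synthetic genome
#'
#' Five autosomes of 50 Mb each: large enough to place hundreds of loci,
#' small enough for sub-minute simulations.
#'
#' @param n_chrom Number of autosomes.
#' @param chrom_length Length of each autosome in bp.
#' @return Data.frame with `chrom` and `length`.
#' @export
default_genome <- function(n_chrom = 5, chrom_length = 50e6) {
  data.frame(chrom = as.character(seq_len(n_chrom)),
             length = rep(chrom_length, n_chrom),
             stringsAsFactors = FALSE)
}

#' Study cohort layout
#'
#' Emulates the study design: a large genotyped cohort, a small
#' whole-genome-sequenced cohort, and the dual-platform animals present in
#' both (defaults 547 genotyped / 38 sequenced / 36 dual, the post-QC
#' sizes of the source population).
#'
#' @param n_genotyped,n_sequenced,n_dual Cohort sizes
#'   (`n_dual <= min(n_genotyped, n_sequenced)`).
#' @return List with character vectors `genotyped`, `sequenced`, `dual`.
#' @export
cohort <- function(n_genotyped = 547, n_sequenced = 38, n_dual = 36) {
  stopifnot(n_dual <= n_genotyped, n_dual <= n_sequenced)
  genotyped <- sprintf("GIR%04d", seq_len(n_genotyped))
  dual <- genotyped[seq_len(n_dual)]
  seq_only <- if (n_sequenced > n_dual) {
    sprintf("SEQ%04d", seq_len(n_sequenced - n_dual))
  } else character(0)
  list(genotyped = genotyped, sequenced = c(dual, seq_only), dual = dual)
}

#' Per-caller noise model
#'
#' @param fp_rate_per_mb False-positive calls per Mb of genome per sample
#'   (per record for the multi-sample caller).
#' @param fn_rate Probability a true carrier call is missed.
#' @param jitter_sd_bp Gaussian SD of breakpoint jitter, truncated so calls
#'   stay within chromosome bounds and non-inverted.
#' @param split_prob Probability a call is split into two abutting calls.
#' @param min_detectable_bp Loci shorter than this are invisible to the
#'   platform.
#' @param size_bias Multiplier applied to the emitted call span.
#' @return A `caller_noise` list.
#' @export
caller_noise <- function(fp_rate_per_mb = 0, fn_rate = 0, jitter_sd_bp = 0,
                         split_prob = 0, min_detectable_bp = 0,
                         size_bias = 1) {
  stopifnot(fp_rate_per_mb >= 0, fn_rate >= 0, fn_rate <= 1,
            jitter_sd_bp >= 0, split_prob >= 0, split_prob <= 1,
            min_detectable_bp >= 0, size_bias > 0)
  structure(list(fp_rate_per_mb = fp_rate_per_mb, fn_rate = fn_rate,
                 jitter_sd_bp = jitter_sd_bp, split_prob = split_prob,
                 min_detectable_bp = min_detectable_bp,
                 size_bias = size_bias), class = "caller_noise")
}

#' Named noise presets
#'
#' * `"zero"`: perfect callers -- emitted calls equal truth intervals.
#' * `"moderate"`: realistic per-platform noise -- WGS callers with
#'   scattered independent false positives and small jitter; the SNP-array
#'   caller with low resolution (10 kb detectability, marker-scale jitter,
#'   higher miss rate) but few false positives.
#' * `"skewed"`: as moderate but with the WGS false-positive load and
#'   array miss rate pushed to the regime where WGS yields hundreds of
#'   times more calls than the SNP panel on the same animals.
#'
#' @param name Preset name.
#' @return Named list of `caller_noise` models (`cnvnator`, `delly`,
#'   `penncnv`).
#' @export
noise_preset <- function(name = c("zero", "moderate", "skewed")) {
  name <- match.arg(name)
  switch(name,
    zero = list(cnvnator = caller_noise(), delly = caller_noise(),
                penncnv = caller_noise()),
    moderate = list(
      cnvnator = caller_noise(fp_rate_per_mb = 0.5, fn_rate = 0.10,
                              jitter_sd_bp = 400, split_prob = 0.02,
                              min_detectable_bp = 1000),
      delly = caller_noise(fp_rate_per_mb = 0.3, fn_rate = 0.15,
                           jitter_sd_bp = 200, split_prob = 0.02,
                           min_detectable_bp = 1000),
      penncnv = caller_noise(fp_rate_per_mb = 0.02, fn_rate = 0.30,
                             jitter_sd_bp = 3000, split_prob = 0,
                             min_detectable_bp = 10000)
    ),
    skewed = list(
      cnvnator = caller_noise(fp_rate_per_mb = 6, fn_rate = 0.10,
                              jitter_sd_bp = 400, split_prob = 0.02,
                              min_detectable_bp = 1000),
      delly = caller_noise(fp_rate_per_mb = 4, fn_rate = 0.15,
                           jitter_sd_bp = 200, split_prob = 0.02,
                           min_detectable_bp = 1000),
      penncnv = caller_noise(fp_rate_per_mb = 0.005, fn_rate = 0.50,
                             jitter_sd_bp = 3000, split_prob = 0,
                             min_detectable_bp = 10000)
    )
  )
}

#' Simulate a truth landscape of CNV loci
#'
#' Places `n_loci` non-overlapping loci on the genome with log-normal sizes
#' clamped to `[min_size, max_size]`, types drawn from `type_probs`, and
#' population frequencies drawn log-uniformly over `freq_range` (spanning
#' rare variants to common polymorphisms above 30%).
#'
#' @param genome Data.frame from [default_genome()].
#' @param n_loci Number of loci.
#' @param size_meanlog,size_sdlog Log-normal size parameters (bp).
#' @param type_probs Named probabilities for `DEL` and `DUP`.
#' @param freq_range Range of population frequencies (log-uniform draw).
#' @param min_size,max_size Size clamp in bp.
#' @param min_gap Minimum gap between loci in bp (keeps distinct loci from
#'   merging downstream).
#' @param seed Integer seed (required; fixed seed gives identical output).
#' @return A `truth_cnv` data.frame: `locus_id`, `chrom`, `start`, `end`,
#'   `cnv_type`, `pop_frequency` and an empty `carriers` list-column.
#' @export
simulate_truth <- function(genome = default_genome(), n_loci = 60,
                           size_meanlog = log(8e4), size_sdlog = 0.8,
                           type_probs = c(DEL = 0.6, DUP = 0.4),
                           freq_range = c(0.02, 0.5),
                           min_size = 1000, max_size = 5e6,
                           min_gap = 10000, seed) {
  if (missing(seed)) stop("simulate_truth() requires an explicit seed")
  stopifnot(is_count(n_loci), n_loci >= 0, min_size <= max_size)
  with_seed(seed, {
    sizes <- round(pmin(pmax(stats::rlnorm(n_loci, size_meanlog, size_sdlog),
                             min_size), max_size))
    types <- sample(names(type_probs), n_loci, replace = TRUE,
                    prob = unname(type_probs))
    freqs <- exp(stats::runif(n_loci, log(freq_range[1]), log(freq_range[2])))
    placed <- vector("list", n_loci)
    occupied <- lapply(stats::setNames(genome$chrom, genome$chrom),
                       function(x) data.frame(start = numeric(0), end = numeric(0)))
    for (i in seq_len(n_loci)) {
      ok <- FALSE
      for (attempt in seq_len(200)) {
        ch <- sample(genome$chrom, 1, prob = genome$length)
        L <- genome$length[genome$chrom == ch]
        if (L < sizes[i]) next
        s <- floor(stats::runif(1, 1, L - sizes[i] + 1))
        e <- s + sizes[i] - 1
        occ <- occupied[[ch]]
        if (nrow(occ) == 0 ||
            all(pmin(e + min_gap, occ$end) < pmax(s - min_gap, occ$start))) {
          occupied[[ch]] <- rbind(occ, data.frame(start = s, end = e))
          placed[[i]] <- data.frame(chrom = ch, start = s, end = e,
                                    stringsAsFactors = FALSE)
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("genome too small to place ", n_loci, " non-overlapping loci")
    }
    pos <- do.call(rbind, placed)
    truth <- data.frame(
      locus_id = sprintf("L%03d", seq_len(n_loci)),
      chrom = pos$chrom, start = pos$start, end = pos$end,
      cnv_type = types, pop_frequency = freqs,
      stringsAsFactors = FALSE
    )
    truth$carriers <- rep(list(character(0)), n_loci)
    ord <- order(match(truth$chrom, genome$chrom), truth$start)
    truth <- truth[ord, , drop = FALSE]
    rownames(truth) <- NULL
    class(truth) <- c("truth_cnv", "data.frame")
    truth
  })
}

#' Assign carriers to truth loci
#'
#' Each sample carries each locus independently with that locus's
#' population frequency (Bernoulli draws; the realized carrier count is
#' Binomial(n, frequency)).
#'
#' @param truth A `truth_cnv` data.frame.
#' @param samples Character vector: the whole population of individuals.
#' @param seed Integer seed.
#' @return `truth` with the `carriers` list-column filled.
#' @export
assign_carriers <- function(truth, samples, seed) {
  if (missing(seed)) stop("assign_carriers() requires an explicit seed")
  with_seed(seed, {
    truth$carriers <- lapply(truth$pop_frequency, function(f) {
      samples[stats::runif(length(samples)) < f]
    })
    truth
  })
}

# Apply jitter / size bias / chromosome clamping to one interval.
jitter_interval <- function(s, e, chrom_len, jitter_sd, size_bias) {
  if (size_bias != 1) {
    mid <- (s + e) / 2
    half <- (e - s + 1) * size_bias / 2
    s <- mid - half
    e <- mid + half
  }
  if (jitter_sd > 0) {
    s2 <- round(s + stats::rnorm(1, 0, jitter_sd))
    e2 <- round(e + stats::rnorm(1, 0, jitter_sd))
    if (e2 > s2) {
      s <- s2
      e <- e2
    }
  }
  s <- max(1, round(s))
  e <- min(chrom_len, round(e))
  if (e <= s) e <- s + 1
  c(s, e)
}

# Random false-positive intervals for one sample/platform.
random_intervals <- function(n, genome, noise) {
  if (n == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), cnv_type = character(0),
                      stringsAsFactors = FALSE))
  }
  sizes <- round(pmin(pmax(stats::rlnorm(n, log(2e4), 1),
                           max(1000, noise$min_detectable_bp)), 5e6))
  ch <- sample(genome$chrom, n, replace = TRUE, prob = genome$length)
  L <- genome$length[match(ch, genome$chrom)]
  sizes <- pmin(sizes, L - 1)
  start <- floor(stats::runif(n, 1, L - sizes + 1))
  data.frame(chrom = ch, start = start, end = start + sizes - 1,
             cnv_type = sample(c("DEL", "DUP"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# maybe split an interval into two abutting pieces
maybe_split <- function(s, e, split_prob) {
  if (stats::runif(1) < split_prob && e - s > 10) {
    m <- floor(stats::runif(1, s + (e - s) * 0.2, s + (e - s) * 0.8))
    list(c(s, m), c(m + 1, e))
  } else {
    list(c(s, e))
  }
}

#' Emit caller output files for a simulated truth landscape
#'
#' Writes, under `out_dir`: per-sample CNVnator tables
#' (`cnvnator/<sample>.txt`), a multi-sample DELLY-style VCF (`delly.vcf`),
#' a PennCNV rawcnv file (`penncnv.rawcnv`), the per-sample array QC table
#' (`sample_qc.tsv`) and the truth table (`truth.tsv`). For every
#' (carrier, locus, platform), a call is emitted with probability
#' `1 - fn_rate` if the locus is at least `min_detectable_bp` long, with
#' jittered breakpoints and optional splitting; false positives are
#' scattered independently per platform at `fp_rate_per_mb`. Quality fields
#' of true and false calls are drawn from the same distributions that pass
#' the default retention filters, so consensus -- not per-caller filtering
#' -- is what removes cross-platform-inconsistent calls. DELLY false
#' positives are single-carrier records (singletons). All outputs parse
#' back losslessly through the package readers, and identical seeds give
#' byte-identical files.
#'
#' @param truth A `truth_cnv` with carriers assigned over the genotyped
#'   and sequenced cohorts.
#' @param cohort_def A [cohort()] list.
#' @param noise Named list of [caller_noise()] models (a [noise_preset()]).
#' @param out_dir Output directory (created if needed).
#' @param genome The genome used to simulate `truth`.
#' @param seed Integer seed.
#' @param qc_fail_fraction Fraction of genotyped samples given a failing
#'   LRR SD so the array QC filter has work to do.
#' @return Invisibly, a list of file paths and per-platform call counts.
#' @export
emit_caller_files <- function(truth, cohort_def, noise = noise_preset("zero"),
                              out_dir, genome = default_genome(), seed,
                              qc_fail_fraction = 0) {
  if (missing(seed)) stop("emit_caller_files() requires an explicit seed")
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output directory: ", out_dir)
  }
  dir.create(file.path(out_dir, "cnvnator"), showWarnings = FALSE)
  genome_mb <- sum(genome$length) / 1e6
  chrom_len <- stats::setNames(genome$length, genome$chrom)

  with_seed(seed, {
    ## CNVnator: per-sample read-depth calls for sequenced animals
    nm <- noise$cnvnator
    cnvnator_paths <- character(0)
    n_cnvnator <- 0L
    n_cnvnator_dual <- 0L
    for (s in cohort_def$sequenced) {
      rows <- list()
      for (i in seq_len(nrow(truth))) {
        if (!s %in% truth$carriers[[i]]) next
        if (call_length(truth[i, ]) < nm$min_detectable_bp) next
        if (stats::runif(1) < nm$fn_rate) next
        se <- jitter_interval(truth$start[i], truth$end[i],
                              chrom_len[[truth$chrom[i]]],
                              nm$jitter_sd_bp, nm$size_bias)
        for (piece in maybe_split(se[1], se[2], nm$split_prob)) {
          rows[[length(rows) + 1]] <- data.frame(
            chrom = truth$chrom[i], start = piece[1], end = piece[2],
            cnv_type = truth$cnv_type[i], stringsAsFactors = FALSE)
        }
      }
      fp <- random_intervals(stats::rpois(1, nm$fp_rate_per_mb * genome_mb),
                             genome, nm)
      df <- rbind(do.call(rbind, rows), fp)
      if (is.null(df)) df <- fp
      calls <- if (nrow(df)) cnv_calls(
        sample_id = s, chrom = df$chrom, start = df$start, end = df$end,
        cnv_type = df$cnv_type, source = "CNVNATOR",
        p_value = stats::runif(nrow(df), 1e-6, 0.045),
        q0 = stats::runif(nrow(df), 0, 0.45)
      ) else empty_cnv_calls()
      ord <- order(match(calls$chrom, genome$chrom), calls$start, calls$end)
      calls <- calls[ord, , drop = FALSE]
      p <- file.path(out_dir, "cnvnator", paste0(s, ".txt"))
      write_cnvnator_calls(calls, p)
      cnvnator_paths <- c(cnvnator_paths, p)
      n_cnvnator <- n_cnvnator + nrow(calls)
      if (s %in% cohort_def$dual) n_cnvnator_dual <- n_cnvnator_dual + nrow(calls)
    }

    ## DELLY: multi-sample records; one record per detected truth locus,
    ## single-carrier records for false positives
    nd <- noise$delly
    delly_rows <- list()
    rec <- 0L
    for (i in seq_len(nrow(truth))) {
      if (call_length(truth[i, ]) < nd$min_detectable_bp) next
      carriers <- intersect(truth$carriers[[i]], cohort_def$sequenced)
      carriers <- carriers[stats::runif(length(carriers)) >= nd$fn_rate]
      if (length(carriers) == 0) next
      se <- jitter_interval(truth$start[i], truth$end[i],
                            chrom_len[[truth$chrom[i]]],
                            nd$jitter_sd_bp, nd$size_bias)
      for (piece in maybe_split(se[1], se[2], nd$split_prob)) {
        rec <- rec + 1L
        delly_rows[[rec]] <- cnv_calls(
          sample_id = carriers, chrom = truth$chrom[i],
          start = piece[1], end = piece[2], cnv_type = truth$cnv_type[i],
          source = "DELLY", pe_support = 5L + stats::rpois(1, 8),
          record_id = sprintf("SIM%05d", rec))
      }
    }
    for (s in cohort_def$sequenced) {
      fp <- random_intervals(stats::rpois(1, nd$fp_rate_per_mb * genome_mb),
                             genome, nd)
      if (nrow(fp)) {
        delly_rows[[length(delly_rows) + 1]] <- cnv_calls(
          sample_id = s, chrom = fp$chrom, start = fp$start, end = fp$end,
          cnv_type = fp$cnv_type, source = "DELLY",
          pe_support = 5L + stats::rpois(nrow(fp), 8),
          record_id = sprintf("SIM%05d", rec + seq_len(nrow(fp))))
        rec <- rec + nrow(fp)
      }
    }
    delly_calls <- if (length(delly_rows)) {
      validate_cnv_calls(do.call(rbind, delly_rows))
    } else empty_cnv_calls()
    delly_path <- file.path(out_dir, "delly.vcf")
    write_delly_vcf(delly_calls, cohort_def$sequenced, delly_path)

    ## PennCNV: array calls for genotyped animals, single rawcnv file
    np <- noise$penncnv
    penn_rows <- list()
    for (i in seq_len(nrow(truth))) {
      if (call_length(truth[i, ]) < np$min_detectable_bp) next
      carriers <- intersect(truth$carriers[[i]], cohort_def$genotyped)
      carriers <- carriers[stats::runif(length(carriers)) >= np$fn_rate]
      for (s in carriers) {
        se <- jitter_interval(truth$start[i], truth$end[i],
                              chrom_len[[truth$chrom[i]]],
                              np$jitter_sd_bp, np$size_bias)
        penn_rows[[length(penn_rows) + 1]] <- data.frame(
          sample_id = s, chrom = truth$chrom[i], start = se[1], end = se[2],
          cnv_type = truth$cnv_type[i], stringsAsFactors = FALSE)
      }
    }
    for (s in cohort_def$genotyped) {
      fp <- random_intervals(stats::rpois(1, np$fp_rate_per_mb * genome_mb),
                             genome, np)
      if (nrow(fp)) {
        fp$sample_id <- s
        penn_rows[[length(penn_rows) + 1]] <- fp[, c("sample_id", "chrom",
                                                     "start", "end", "cnv_type")]
      }
    }
    penn_df <- if (length(penn_rows)) do.call(rbind, penn_rows) else NULL
    penn_calls <- if (!is.null(penn_df) && nrow(penn_df)) {
      len <- penn_df$end - penn_df$start + 1
      cnv_calls(sample_id = penn_df$sample_id, chrom = penn_df$chrom,
                start = penn_df$start, end = penn_df$end,
                cnv_type = penn_df$cnv_type, source = "PENNCNV",
                num_snps = pmax(10L, as.integer(round(len / 3430))),
                copy_number = ifelse(penn_df$cnv_type == "DEL", 1L, 3L))
    } else empty_cnv_calls()
    ord <- order(match(penn_calls$sample_id, cohort_def$genotyped),
                 match(penn_calls$chrom, genome$chrom), penn_calls$start)
    penn_calls <- penn_calls[ord, , drop = FALSE]
    penn_path <- file.path(out_dir, "penncnv.rawcnv")
    write_penncnv_rawcnv(penn_calls, penn_path)

    ## per-sample array QC; a configurable fraction fails on LRR SD
    n_g <- length(cohort_def$genotyped)
    fail <- stats::runif(n_g) < qc_fail_fraction
    qc <- sample_qc(
      sample_id = cohort_def$genotyped,
      lrr_sd = ifelse(fail, stats::runif(n_g, 0.31, 0.6),
                      stats::runif(n_g, 0.05, 0.25)),
      baf_drift = stats::runif(n_g, 0, 0.008),
      waviness_factor = stats::runif(n_g, -0.04, 0.04)
    )
    qc_path <- file.path(out_dir, "sample_qc.tsv")
    write_sample_qc(qc, qc_path)

    truth_path <- file.path(out_dir, "truth.tsv")
    write_truth_table(truth, truth_path)

    invisible(list(
      cnvnator = cnvnator_paths, delly = delly_path, penncnv = penn_path,
      sample_qc = qc_path, truth = truth_path,
      n_calls = c(cnvnator = n_cnvnator, delly = nrow(delly_calls),
                  penncnv = nrow(penn_calls)),
      # per-platform call counts restricted to the dual-platform animals:
      # the basis of the WGS-vs-array call disparity comparison
      n_calls_dual = c(
        cnvnator = n_cnvnator_dual,
        delly = sum(delly_calls$sample_id %in% cohort_def$dual),
        penncnv = sum(penn_calls$sample_id %in% cohort_def$dual)
      )
    ))
  })
}

#' Read / write the simulation truth table
#'
#' Tab-separated: `locus_id chrom start end cnv_type pop_frequency
#' carriers` (carriers comma-joined).
#'
#' @param truth A `truth_cnv` data.frame.
#' @param path File path.
#' @export
write_truth_table <- function(truth, path) {
  out <- truth
  out$carriers <- vapply(truth$carriers, paste, character(1), collapse = ",")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  df$carriers <- lapply(strsplit(df$carriers, ",", fixed = TRUE),
                        function(x) x[nzchar(x)])
  df$carriers[is.na(df$carriers)] <- list(character(0))
  class(df) <- c("truth_cnv", "data.frame")
  df
}
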