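#' Pipeline configuration
#'
#' Validated bundle of input paths, thresholds and output location for
#' [run_pipeline()]. Serializable to/from YAML; the effective configuration
#' is written verbatim into the output directory so every run is
#' self-describing.
#'
#' @param cnvnator_dir Directory of per-sample CNVnator tables
#'   (`<sample>.txt`; the file stem is the sample id).
#' @param delly_vcf DELLY-style SV VCF path.
#' @param penncnv_rawcnv PennCNV rawcnv path.
#' @param sample_qc_path Per-sample array QC table path.
#' @param out_dir Output directory.
#' @param filters A [filter_config()] (or list of its fields, as from
#'   YAML).
#' @param min_ro Reciprocal-overlap criterion for all cross-set matching.
#' @param min_freq Minimum carrier frequency for the POP set.
#' @param frequency_denominator Population size for the frequency rule;
#'   defaults to the number of samples in the QC table (the genotyped
#'   cohort).
#' @param autosomes Allowed chromosome labels.
#' @param external_path Optional external-catalogue TSV for comparison.
#' @param features_path Optional feature BED for annotation.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cnvnator_dir, delly_vcf, penncnv_rawcnv,
                            sample_qc_path, out_dir,
                            filters = filter_config(), min_ro = 0.5,
                            min_freq = 0.05, frequency_denominator = NULL,
                            autosomes = as.character(1:29),
                            external_path = NULL, features_path = NULL) {
  if (!is.null(filters) && !inherits(filters, "filter_config")) {
    filters <- do.call(filter_config, filters)
  }
  stopifnot(min_ro > 0, min_ro <= 1, min_freq >= 0, min_freq <= 1)
  structure(list(
    cnvnator_dir = cnvnator_dir, delly_vcf = delly_vcf,
    penncnv_rawcnv = penncnv_rawcnv, sample_qc_path = sample_qc_path,
    out_dir = out_dir, filters = filters, min_ro = min_ro,
    min_freq = min_freq, frequency_denominator = frequency_denominator,
    autosomes = as.character(autosomes), external_path = external_path,
    features_path = features_path
  ), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML path.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$filters <- do.call(filter_config, y$filters %||% list())
  do.call(pipeline_config, y)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  y <- unclass(config)
  y$filters <- unclass(y$filters)
  y <- y[!vapply(y, is.null, logical(1))]
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Run the consensus CNVR pipeline end to end
#'
#' Stages: parse caller outputs, apply per-caller filters, build the
#' per-caller and consensus sets (SEQ, GEN, POP, ANI), merge into the
#' unique high-confidence set, and optionally compare against an external
#' catalogue and annotate with genomic features. Every stage's input and
#' output counts are logged to `pipeline.log`; each set is written as BED,
#' the stage counts as a JSON build report, and the effective configuration
#' as YAML, all under `out_dir`. The pipeline is deterministic: same
#' configuration and inputs give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the call tables, all `cnvr_set`s, the
#'   `build_report`, and any comparison/annotation results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)

  ## -- parse ---------------------------------------------------------------
  stage <- "parse"
  res <- tryCatch({
    cn_files <- sort(list.files(config$cnvnator_dir, pattern = "\\.txt$",
                                full.names = TRUE))
    if (length(cn_files) == 0) stop("no CNVnator call files in ", config$cnvnator_dir)
    cn_raw <- do.call(rbind, lapply(cn_files, function(f) {
      read_cnvnator_calls(f, sample_id = tools::file_path_sans_ext(basename(f)),
                          autosomes = config$autosomes)
    }))
    cn_raw <- validate_cnv_calls(cn_raw)
    dl_raw <- read_delly_vcf(config$delly_vcf, autosomes = config$autosomes)
    if (is.null(config$penncnv_rawcnv)) stop("PennCNV rawcnv input is required")
    pc_raw <- read_penncnv_rawcnv(config$penncnv_rawcnv,
                                  autosomes = config$autosomes)
    qc <- read_sample_qc(config$sample_qc_path)
    list(cn = cn_raw, dl = dl_raw, pc = pc_raw, qc = qc)
  }, error = function(e) stop_stage(stage, conditionMessage(e)))
  say("parse: %d CNVnator, %d DELLY, %d PennCNV calls; %d QC samples",
      nrow(res$cn), nrow(res$dl), nrow(res$pc), nrow(res$qc))

  ## -- filter --------------------------------------------------------------
  stage <- "filter"
  filt <- tryCatch({
    list(cn = filter_cnvnator(res$cn, config$filters),
         dl = filter_delly(res$dl, config$filters),
         pc = filter_penncnv(res$pc, res$qc, config$filters))
  }, error = function(e) stop_stage(stage, conditionMessage(e)))
  say("filter: retained %d/%d CNVnator, %d/%d DELLY, %d/%d PennCNV calls",
      nrow(filt$cn), nrow(res$cn), nrow(filt$dl), nrow(res$dl),
      nrow(filt$pc), nrow(res$pc))

  ## -- build ---------------------------------------------------------------
  stage <- "build_seq"
  seq_set <- tryCatch(build_cnvr_seq(filt$cn, filt$dl, min_ro = config$min_ro),
                      error = function(e) stop_stage(stage, conditionMessage(e)))
  say("build_seq: %d consensus WGS regions", nrow(seq_set))

  stage <- "build_gen"
  gen_set <- tryCatch(build_cnvr_gen(filt$pc),
                      error = function(e) stop_stage(stage, conditionMessage(e)))
  say("build_gen: %d array regions", nrow(gen_set))

  stage <- "build_pop"
  denom <- config$frequency_denominator %||% nrow(res$qc)
  pop_set <- tryCatch(
    build_cnvr_pop(gen_set, seq_set, n_individuals = denom,
                   min_freq = config$min_freq, min_ro = config$min_ro),
    error = function(e) stop_stage(stage, conditionMessage(e)))
  say("build_pop: %d regions at frequency >= %g (denominator %d)",
      nrow(pop_set), config$min_freq, denom)

  stage <- "build_ani"
  ani_set <- tryCatch({
    if (nrow(filt$pc) == 0) stop("no PennCNV calls available for per-animal matching")
    build_cnvr_ani(filt$pc, filt$cn, min_ro = config$min_ro)
  }, error = function(e) stop_stage(stage, conditionMessage(e)))
  say("build_ani: %d regions from dual-platform animals", nrow(ani_set))

  stage <- "build_unique"
  uni <- tryCatch(build_unique_set(pop_set, ani_set),
                  error = function(e) stop_stage(stage, conditionMessage(e)))
  say("build_unique: %d unique regions (%d POP regions shared with ANI)",
      nrow(uni$set), uni$shared_count)

  sets <- list(SEQ = seq_set, GEN = gen_set, POP = pop_set, ANI = ani_set,
               UNIQUE = uni$set)
  report <- build_report(
    call_counts = list(
      input = c(cnvnator = nrow(res$cn), delly = nrow(res$dl),
                penncnv = nrow(res$pc)),
      retained = c(cnvnator = nrow(filt$cn), delly = nrow(filt$dl),
                   penncnv = nrow(filt$pc))
    ),
    sets = sets, shared_count = uni$shared_count
  )

  out <- list(calls = filt, sets = sets, report = report,
              shared_count = uni$shared_count)

  ## -- optional comparison / annotation ------------------------------------
  if (!is.null(config$external_path)) {
    stage <- "compare"
    out$external <- tryCatch({
      ext <- build_external_set(read_external_cnvr(config$external_path))
      cmp <- match_external(uni$set, ext, min_ro = config$min_ro)
      write_external_report(cmp, file.path(config$out_dir, "external_overlap.tsv"))
      cmp
    }, error = function(e) stop_stage(stage, conditionMessage(e)))
    say("compare: %d/%d unique regions matched externally",
        out$external$n_matched, nrow(uni$set))
  }
  if (!is.null(config$features_path)) {
    stage <- "annotate"
    out$annotation <- tryCatch({
      feats <- read_feature_bed(config$features_path)
      ov <- overlap_features(uni$set, feats)
      write_annotation(ov, file.path(config$out_dir, "annotation.tsv"))
      list(overlaps = ov, summary = summarize_annotation(ov))
    }, error = function(e) stop_stage(stage, conditionMessage(e)))
    say("annotate: %d/%d unique regions annotated with genes",
        out$annotation$summary$n_annotated_regions, nrow(uni$set))
  }

  ## -- write ---------------------------------------------------------------
  stage <- "write"
  tryCatch({
    for (nm in names(sets)) {
      write_cnvr_bed(sets[[nm]], file.path(config$out_dir,
                                           sprintf("cnvr_%s.bed", tolower(nm))))
    }
    write_build_report(report, file.path(config$out_dir, "build_report.json"))
    write_pipeline_config(config, file.path(config$out_dir, "config.yaml"))
    writeLines(log_lines, file.path(config$out_dir, "pipeline.log"))
  }, error = function(e) stop_stage(stage, conditionMessage(e)))

  invisible(out)
}
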