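test_that("WGS consensus keeps only cross-caller matches and spans their union", {
  cn <- mk_calls(chrom = 1, start = 1000, end = 2000, type = "DEL",
                 p_value = 0.01, q0 = 0.1)
  dl <- mk_calls(chrom = 1, start = 1400, end = 2400, type = "DEL",
                 source = "DELLY", pe_support = 8L, record_id = "R1")
  lone <- mk_calls(chrom = 2, start = 5e5, end = 6e5, type = "DEL",
                   p_value = 0.01, q0 = 0.1)
  seq_set <- build_cnvr_seq(validate_cnv_calls(rbind(cn, lone)), dl)
  expect_equal(nrow(seq_set), 1)          # unmatched caller region excluded
  expect_equal(seq_set$start, 1000)       # span union of the matched pair
  expect_equal(seq_set$end, 2400)
  expect_equal(seq_set$cnvr_type, "DELETION")
  expect_setequal(seq_set$sources[[1]], c("CNVNATOR", "DELLY"))

  # mixed types across callers re-derive to COMPLEX
  dl_dup <- mk_calls(chrom = 1, start = 1400, end = 2400, type = "DUP",
                     source = "DELLY", pe_support = 8L, record_id = "R1")
  cx <- build_cnvr_seq(cn, dl_dup)
  expect_equal(cx$cnvr_type, "COMPLEX")

  expect_warning(empty <- build_cnvr_seq(empty_calls(), dl), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("array regions merge with carriers and complex typing", {
  calls <- validate_cnv_calls(rbind(
    mk_calls(chrom = 5, start = 1e6, end = 1.1e6, type = "DEL", sample = "A",
             source = "PENNCNV", num_snps = 30L),
    mk_calls(chrom = 5, start = 1.05e6, end = 1.2e6, type = "DEL", sample = "B",
             source = "PENNCNV", num_snps = 30L)
  ))
  gen <- build_cnvr_gen(calls)
  expect_equal(nrow(gen), 1)
  expect_equal(gen$cnvr_type, "DELETION")
  expect_equal(gen$n_carriers, 2L)

  mixed <- validate_cnv_calls(rbind(
    calls,
    mk_calls(chrom = 5, start = 1.15e6, end = 1.3e6, type = "DUP", sample = "C",
             source = "PENNCNV", num_snps = 20L)
  ))
  expect_equal(build_cnvr_gen(mixed)$cnvr_type, "COMPLEX")
})

test_that("population set applies the frequency rule over an explicit denominator", {
  gen <- merge_calls(validate_cnv_calls(rbind(
    mk_calls(chrom = 1, start = 1000, end = 2000, sample = c("A", "B", "C"),
             source = "PENNCNV", num_snps = 15L),
    mk_calls(chrom = 2, start = 1000, end = 2000, sample = "Z",
             source = "PENNCNV", num_snps = 15L)
  )), kind = "GEN")
  seq_set <- merge_calls(validate_cnv_calls(rbind(
    mk_calls(chrom = 1, start = 1100, end = 2100, sample = "W1"),
    mk_calls(chrom = 2, start = 1100, end = 2100, sample = "W2")
  )), kind = "SEQ")
  pop <- build_cnvr_pop(gen, seq_set, n_individuals = 40)
  # region 1: carriers {A,B,C,W1} -> 0.1 >= 0.05 retained;
  # region 2: {Z,W2} -> 0.05 retained at the boundary
  expect_equal(nrow(pop), 2)
  expect_equal(pop$frequency, c(4 / 40, 2 / 40))

  strict <- build_cnvr_pop(gen, seq_set, n_individuals = 80)
  expect_equal(nrow(strict), 1)          # 2/80 = 0.025 dropped
  expect_equal(attr(strict, "n_below_freq"), 1)

  none <- build_cnvr_pop(gen, merge_calls(mk_calls(chrom = 9, start = 1, end = 100)),
                         n_individuals = 40)
  expect_equal(nrow(none), 0)
  expect_error(build_cnvr_pop(gen, seq_set, n_individuals = 0), "positive")
})

test_that("per-animal set demands within-sample dual-platform agreement", {
  p1 <- mk_calls(chrom = 1, start = 1000, end = 2000, sample = "S1",
                 source = "PENNCNV", num_snps = 12L)
  w1 <- mk_calls(chrom = 1, start = 1200, end = 2200, sample = "S1")  # RO ~ 0.80
  p2 <- mk_calls(chrom = 1, start = 2100, end = 3100, sample = "S2",
                 source = "PENNCNV", num_snps = 12L)
  w2 <- mk_calls(chrom = 1, start = 2150, end = 3150, sample = "S2")
  p3 <- mk_calls(chrom = 9, start = 5000, end = 6000, sample = "S3",
                 source = "PENNCNV", num_snps = 12L)
  w3 <- mk_calls(chrom = 20, start = 5000, end = 6000, sample = "S3")  # no match

  penn <- validate_cnv_calls(rbind(p1, p2, p3))
  wgs <- validate_cnv_calls(rbind(w1, w2, w3))
  ani <- build_cnvr_ani(penn, wgs)
  # S1 and S2 matched pairs pool and chain into one region; S3 contributes nothing
  expect_equal(nrow(ani), 1)
  expect_equal(ani$start, 1000)
  expect_equal(ani$end, 3150)
  expect_setequal(ani$carriers[[1]], c("S1", "S2"))

  solo <- build_cnvr_ani(p1, w1)
  expect_equal(nrow(solo), 1)
  expect_equal(c(solo$start, solo$end), c(1000, 2200))

  expect_warning(build_cnvr_ani(penn, wgs, samples = c("S1", "GHOST")),
                 "one platform only")
})

test_that("unique set merges POP and ANI with origin bookkeeping", {
  pop <- merge_calls(validate_cnv_calls(rbind(
    mk_calls(chrom = 1, start = 1000, end = 2000, sample = "A"),
    mk_calls(chrom = 2, start = 1000, end = 2000, sample = "B")
  )), kind = "POP")
  ani_overlap <- merge_calls(validate_cnv_calls(rbind(
    mk_calls(chrom = 1, start = 1500, end = 2500, sample = "C"),
    mk_calls(chrom = 3, start = 1, end = 1000, sample = "D"),
    mk_calls(chrom = 4, start = 1, end = 1000, sample = "E"),
    mk_calls(chrom = 5, start = 1, end = 1000, sample = "F")
  )), kind = "ANI")
  res <- build_unique_set(pop, ani_overlap)
  expect_equal(nrow(res$set), 5)             # 2 + 4 - 1 shared
  expect_equal(res$shared_count, 1)
  expect_equal(res$set$set_origin[res$set$chrom == "1"], "BOTH")
  expect_equal(res$set$set_origin[res$set$chrom == "2"], "POP")
  expect_setequal(res$set$set_origin[res$set$chrom %in% c("3", "4", "5")], "ANI")

  disjoint <- build_unique_set(pop, merge_calls(
    mk_calls(chrom = 9, start = 1, end = 1000, sample = "X")))
  expect_equal(nrow(disjoint$set), 3)
  expect_equal(disjoint$shared_count, 0)
})

test_that("unique-set size identity holds for one-to-one sharing (random cases)", {
  set.seed(202)
  for (rep in 1:20) {
    pop <- merge_calls(random_intervals_df(12), kind = "POP")
    ani <- merge_calls(random_intervals_df(20), kind = "ANI")
    res <- build_unique_set(pop, ani)
    # against the brute-force merge oracle
    pool <- rbind(pop[, c("chrom", "start", "end")], ani[, c("chrom", "start", "end")])
    pool$cnv_type <- "DEL"; pool$sample_id <- "S"
    expect_equal(region_key(res$set), region_key(bf_merge(pool)))
    one_to_one <- all(table(reciprocal_match(pop, ani, 1e-9)$a_idx) <= 1) &&
      all(table(reciprocal_match(pop, ani, 1e-9)$b_idx) <= 1)
    if (one_to_one) {
      expect_equal(nrow(res$set), nrow(pop) + nrow(ani) - res$shared_count)
    }
  }
})

test_that("build report counts are internally consistent", {
  pop <- merge_calls(mk_calls(chrom = 1, start = 1000, end = 3000), kind = "POP")
  ani <- merge_calls(mk_calls(chrom = 1, start = 2000, end = 4000), kind = "ANI")
  res <- build_unique_set(pop, ani)
  rep <- build_report(list(input = c(a = 2)), list(POP = pop, ANI = ani,
                                                   UNIQUE = res$set),
                      res$shared_count)
  expect_equal(rep$set_summaries$UNIQUE$n_regions,
               rep$set_summaries$POP$n_regions +
                 rep$set_summaries$ANI$n_regions - rep$shared_pop_ani)
  expect_equal(rep$set_summaries$POP$total_bp, 2001)
  expect_equal(rep$set_summaries$UNIQUE$mean_size_bp, 3001)
  f <- withr::local_tempfile(fileext = ".json")
  write_build_report(rep, f)
  expect_equal(jsonlite::read_json(f)$shared_pop_ani, 1)
})
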