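test_that("CNVnator lines map to calls with 1-based coordinates intact", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "deletion\t1:1001-3000\t2000\t0.31\t1.2e-05\t1\t1\t1\t0.10",
    "duplication\t2:500-1499\t1000\t1.62\t0.003\t1\t1\t1\t0.45"
  ), f)
  calls <- read_cnvnator_calls(f, sample_id = "S01")
  expect_s3_class(calls, "cnv_calls")
  expect_equal(nrow(calls), 2)
  expect_equal(calls$chrom, c("1", "2"))
  expect_equal(calls$start, c(1001, 500))
  expect_equal(calls$end, c(3000, 1499))
  expect_equal(calls$cnv_type, c("DEL", "DUP"))
  expect_equal(calls$p_value, c(1.2e-05, 0.003))
  expect_equal(calls$q0, c(0.10, 0.45))
  expect_equal(call_length(calls), c(2000, 1000))
  expect_true(all(calls$source == "CNVNATOR"))
})

test_that("CNVnator parser flags malformed input and handles empty files", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines("deletion\t1:abc-3000\t2000\t0.31\t1e-5\t1\t1\t1\t0.1", f)
  expect_error(read_cnvnator_calls(f, "S01"), "line 1.*malformed coordinate")
  writeLines("inversion\t1:100-3000\t2901\t0.31\t1e-5\t1\t1\t1\t0.1", f)
  expect_error(read_cnvnator_calls(f, "S01"), "unknown CNV type")
  writeLines(character(0), f)
  expect_equal(nrow(read_cnvnator_calls(f, "S01")), 0)
})

test_that("CNVnator calls survive a write/read round trip", {
  set.seed(42)
  n <- 50
  start <- sample.int(1e6, n)
  calls <- mk_calls(chrom = sample(1:29, n, replace = TRUE), start = start,
                    end = start + sample.int(5e4, n) + 999,
                    type = sample(c("DEL", "DUP"), n, replace = TRUE),
                    sample = "S7",
                    p_value = round(runif(n, 1e-6, 0.05), 8),
                    q0 = round(runif(n), 6))
  f <- withr::local_tempfile(fileext = ".txt")
  write_cnvnator_calls(calls, f)
  back <- read_cnvnator_calls(f, "S7")
  for (col in c("sample_id", "chrom", "start", "end", "cnv_type", "p_value", "q0")) {
    expect_equal(back[[col]], calls[[col]], info = col)
  }
})

test_that("DELLY VCF records expand to one call per carrier", {
  f <- withr::local_tempfile(fileext = ".vcf")
  calls <- cnv_calls(sample_id = c("A", "C"), chrom = "1", start = 5001,
                     end = 9000, cnv_type = "DEL", source = "DELLY",
                     pe_support = 7L, record_id = "DEL001")
  write_delly_vcf(calls, samples = c("A", "B", "C"), f)
  back <- read_delly_vcf(f)
  expect_equal(nrow(back), 2)
  expect_setequal(back$sample_id, c("A", "C"))
  expect_true(all(back$start == 5001 & back$end == 9000 & back$pe_support == 7))
  expect_true(all(back$record_id == back$record_id[1]))
})

test_that("DELLY reader skips non-CNV SVTYPEs, empty-genotype and END-less records", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"e\">",
    "##INFO=<ID=PE,Number=1,Type=Integer,Description=\"p\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tA\tB",
    "1\t100\tinv1\tN\t<INV>\t.\tPASS\tSVTYPE=INV;END=900;PE=9\tGT\t0/1\t0/1",
    "1\t2000\tdel1\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=4000;PE=6\tGT\t0/0\t./.",
    "2\t100\tdel2\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;PE=6\tGT\t1/1\t0/1",
    "2\t5000\tdup1\tN\t<DUP>\t.\tPASS\tSVTYPE=DUP;END=9000;PE=8\tGT\t0/1\t1/1"
  ), f)
  expect_warning(back <- read_delly_vcf(f), "without INFO END")
  expect_equal(attr(back, "n_skipped_svtype"), 1)
  # only the last record has both END and at least one ALT-carrying genotype
  expect_equal(nrow(back), 2)
  expect_true(all(back$cnv_type == "DUP"))
  expect_setequal(back$sample_id, c("A", "B"))
})

test_that("DELLY reader refuses a VCF without sample columns", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "1\t100\td\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=900"
  ), f)
  expect_error(read_delly_vcf(f), "no sample genotype columns")
})

test_that("DELLY carrier expansion count equals the sum of carriers over records", {
  set.seed(7)
  samples <- paste0("S", 1:6)
  recs <- lapply(1:20, function(i) {
    carr <- sample(samples, sample.int(5, 1))
    s <- sample.int(1e6, 1)
    cnv_calls(sample_id = carr, chrom = sample(1:5, 1), start = s,
              end = s + sample.int(1e5, 1) + 999,
              cnv_type = sample(c("DEL", "DUP"), 1), source = "DELLY",
              pe_support = 5L + i, record_id = sprintf("R%02d", i))
  })
  calls <- validate_cnv_calls(do.call(rbind, recs))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_delly_vcf(calls, samples, f)
  back <- read_delly_vcf(f)
  expect_equal(nrow(back), nrow(calls))
  key <- function(x) sort(paste(x$sample_id, x$chrom, x$start, x$end,
                                x$cnv_type, x$pe_support))
  expect_equal(key(back), key(calls))
})

test_that("PennCNV rawcnv lines parse with copy-number mapping", {
  f <- withr::local_tempfile(fileext = ".rawcnv")
  writeLines(c(
    "chr7:9455783-9693750 numsnp=25 length=237,968 state2,cn=1 S014 startsnp=rs1 endsnp=rs2",
    "chr3:100000-200000 numsnp=40 length=100,001 state5,cn=3 S015 startsnp=rs3 endsnp=rs4"
  ), f)
  calls <- read_penncnv_rawcnv(f)
  expect_equal(calls$chrom, c("7", "3"))  # file order preserved
  expect_setequal(calls$cnv_type, c("DEL", "DUP"))
  del <- calls[calls$cnv_type == "DEL", ]
  expect_equal(del$chrom, "7")
  expect_equal(del$start, 9455783)
  expect_equal(del$end, 9693750)
  expect_equal(del$num_snps, 25L)
  expect_equal(call_length(del), 237968)
  expect_equal(del$sample_id, "S014")
})

test_that("PennCNV parser rejects copy-neutral lines and warns on length mismatch", {
  f <- withr::local_tempfile(fileext = ".rawcnv")
  writeLines("chr1:1000-2000 numsnp=12 length=1,001 state3,cn=2 S01", f)
  expect_error(read_penncnv_rawcnv(f), "cn=2")
  writeLines("chr1:1000-2000 numsnp=12 length=999 state2,cn=1 S01", f)
  expect_warning(calls <- read_penncnv_rawcnv(f), "inconsistent")
  expect_equal(call_length(calls), 1001)  # coordinates win
})

test_that("PennCNV calls survive a write/read round trip", {
  set.seed(11)
  n <- 50
  start <- sample.int(1e7, n)
  calls <- mk_calls(chrom = sample(1:29, n, replace = TRUE), start = start,
                    end = start + sample.int(2e5, n) + 999,
                    type = sample(c("DEL", "DUP"), n, replace = TRUE),
                    sample = sample(paste0("S", 1:9), n, replace = TRUE),
                    source = "PENNCNV",
                    num_snps = sample(10:200, n, replace = TRUE))
  calls$copy_number <- ifelse(calls$cnv_type == "DEL", 1L, 3L)
  f <- withr::local_tempfile(fileext = ".rawcnv")
  write_penncnv_rawcnv(calls, f)
  back <- read_penncnv_rawcnv(f)
  for (col in c("sample_id", "chrom", "start", "end", "cnv_type",
                "num_snps", "copy_number")) {
    expect_equal(back[[col]], calls[[col]], info = col)
  }
})

test_that("chromosome normalization and the autosome gate behave", {
  expect_equal(normalize_chrom(c("chr7", "Chr7", "7", "chrX")),
               c("7", "7", "7", "X"))
  calls <- mk_calls(chrom = c("1", "29", "30", "X"), start = 1:4 * 1000,
                    end = 1:4 * 1000 + 1999)
  kept <- keep_autosomes(calls)
  expect_equal(kept$chrom, c("1", "29"))
  expect_equal(attr(kept, "n_dropped"), 2)
})

test_that("CNVR BED output is 0-based half-open and round-trips", {
  set <- merge_calls(mk_calls(chrom = 28, start = 123251, end = 413750))
  f <- withr::local_tempfile(fileext = ".bed")
  write_cnvr_bed(set, f)
  line <- readLines(f)
  expect_match(line, "^28\t123250\t413750\t")
  # length from BED equals internal inclusive length
  fields <- strsplit(line, "\t")[[1]]
  expect_equal(as.numeric(fields[3]) - as.numeric(fields[2]), call_length(set))

  set.seed(5)
  n <- 100
  start <- sample.int(1e7, n)
  regions <- merge_calls(data.frame(
    chrom = as.character(sample(1:29, n, replace = TRUE)),
    start = start, end = start + sample.int(1e5, n),
    cnv_type = sample(c("DEL", "DUP"), n, replace = TRUE),
    sample_id = "S1"
  ))
  regions <- with_frequency(regions, 40)
  write_cnvr_bed(regions, f)
  back <- read_cnvr_bed(f, kind = "UNIQUE")
  for (col in c("region_id", "chrom", "start", "end", "cnvr_type",
                "n_carriers", "frequency")) {
    expect_equal(back[[col]], regions[[col]], info = col)
  }
})

test_that("CNVR BED reader validates coordinates; empty sets give empty files", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("1\t500\t500\tR1\tDELETION\t0\t.", f)
  expect_error(read_cnvr_bed(f), "end <= start")
  empty <- merge_calls(empty_calls())
  write_cnvr_bed(empty, f)
  expect_equal(nrow(read_cnvr_bed(f)), 0)
})

test_that("sample QC table round-trips", {
  qc <- sample_qc(c("A", "B"), c(0.1, 0.31), c(0.001, 0.02), c(-0.02, 0.06))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sample_qc(qc, f)
  expect_equal(read_sample_qc(f), qc, ignore_attr = TRUE)
})
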