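test_that("transitive merging chains overlaps and respects the 1 bp rule", {
  calls <- validate_cnv_calls(rbind(
    mk_calls(chrom = 1, start = 101, end = 200, type = "DEL"),
    mk_calls(chrom = 1, start = 150, end = 300, type = "DEL"),
    mk_calls(chrom = 1, start = 400, end = 500, type = "DUP")
  ))
  set <- merge_calls(calls)
  expect_equal(set$start, c(101, 400))
  expect_equal(set$end, c(300, 500))
  expect_equal(set$cnvr_type, c("DELETION", "DUPLICATION"))

  # book-ended intervals share 0 bp and stay apart
  two <- merge_calls(rbind(mk_calls(chrom = 1, start = 101, end = 200),
                           mk_calls(chrom = 1, start = 201, end = 300)))
  expect_equal(nrow(two), 2)
  # a single shared base is enough
  one <- merge_calls(rbind(mk_calls(chrom = 1, start = 101, end = 200),
                           mk_calls(chrom = 1, start = 200, end = 300)))
  expect_equal(nrow(one), 1)

  # DEL + DUP overlap gives a COMPLEX region with both member types
  cx <- merge_calls(rbind(mk_calls(chrom = 1, start = 101, end = 200, type = "DEL"),
                          mk_calls(chrom = 1, start = 180, end = 250, type = "DUP")))
  expect_equal(cx$start, 101)
  expect_equal(cx$end, 250)
  expect_equal(cx$cnvr_type, "COMPLEX")
  expect_setequal(cx$types[[1]], c("DEL", "DUP"))
})

test_that("merging carries carriers/provenance and handles empty input", {
  calls <- validate_cnv_calls(rbind(
    mk_calls(chrom = 2, start = 100, end = 220, sample = "A"),
    mk_calls(chrom = 2, start = 200, end = 350, sample = "B",
             source = "DELLY", pe_support = 9L),
    mk_calls(chrom = 2, start = 100, end = 240, sample = "A")
  ))
  set <- merge_calls(calls)
  expect_equal(nrow(set), 1)
  expect_equal(set$carriers[[1]], c("A", "B"))
  expect_equal(set$n_carriers, 2L)
  expect_setequal(set$sources[[1]], c("CNVNATOR", "DELLY"))
  expect_equal(set$n_members, 3L)
  expect_equal(nrow(merge_calls(empty_calls())), 0)
})

test_that("merge agrees with the brute-force component oracle on random instances", {
  set.seed(1234)
  for (rep in 1:120) {
    df <- random_intervals_df(sample.int(60, 1))
    got <- merge_calls(df)
    want <- bf_merge(df)
    expect_equal(region_key(got), region_key(want))
    expect_equal(sort(got$n_members), sort(want$n_members))
  }
  # stricter overlap requirements go through the exact graph path
  for (rep in 1:40) {
    df <- random_intervals_df(30)
    k <- sample(c(5, 50, 120), 1)
    got <- merge_calls(df, min_overlap_bp = k)
    want <- bf_merge(df, min_ov = k)
    expect_equal(region_key(got), region_key(want))
  }
})

test_that("merge is idempotent, permutation-invariant, and coverage-preserving", {
  set.seed(77)
  for (rep in 1:25) {
    df <- random_intervals_df(40)
    set1 <- merge_calls(df)
    expect_equal(region_key(merge_calls(set1)), region_key(set1))   # idempotent
    perm <- df[sample.int(nrow(df)), , drop = FALSE]
    expect_equal(region_key(merge_calls(perm)), region_key(set1))   # order-free
    # covered bp equals the union of the inputs
    cov_in <- sum(vapply(split(df, df$chrom), function(d) {
      pos <- unique(unlist(mapply(seq, d$start, d$end, SIMPLIFY = FALSE)))
      length(pos)
    }, numeric(1)))
    expect_equal(covered_bp(set1), cov_in)
  }
})

test_that("reciprocal overlap follows inclusive arithmetic", {
  iv <- function(chrom, start, end) data.frame(chrom = as.character(chrom),
                                               start = start, end = end)
  expect_equal(reciprocal_overlap(iv(1, 101, 200), iv(1, 151, 250)), 0.5)
  expect_equal(reciprocal_overlap(iv(1, 101, 200), iv(1, 101, 200)), 1.0)
  expect_equal(reciprocal_overlap(iv(1, 101, 200), iv(1, 301, 400)), 0.0)
  expect_equal(reciprocal_overlap(iv(1, 101, 200), iv(2, 101, 200)), 0.0)
  # 1000-2000 vs 1400-2400: 601 shared bases over length 1001 each
  expect_equal(reciprocal_overlap(iv(3, 1000, 2000), iv(3, 1400, 2400)),
               601 / 1001)
  # nested interval of half the length sits exactly at the 50% threshold
  expect_equal(reciprocal_overlap(iv(1, 1000, 1499), iv(1, 1000, 1999)), 0.5)
})

test_that("reciprocal overlap is symmetric, bounded and 1 only at identity", {
  set.seed(31)
  a <- random_intervals_df(200)
  b <- random_intervals_df(200)
  ro_ab <- reciprocal_overlap(a, b)
  ro_ba <- reciprocal_overlap(b, a)
  expect_equal(ro_ab, ro_ba)
  expect_true(all(ro_ab >= 0 & ro_ab <= 1))
  ident <- ro_ab == 1
  same <- a$chrom == b$chrom & a$start == b$start & a$end == b$end
  expect_equal(ident, same)
})

test_that("set matching reproduces hand arithmetic and the brute-force oracle", {
  A <- merge_calls(mk_calls(chrom = 1, start = 1000, end = 2000))
  B1 <- merge_calls(mk_calls(chrom = 1, start = 1400, end = 2400))
  expect_equal(nrow(reciprocal_match(A, B1)), 1)        # RO ~ 0.600
  B2 <- merge_calls(mk_calls(chrom = 1, start = 1950, end = 3000))
  expect_equal(nrow(reciprocal_match(A, B2)), 0)        # RO ~ 0.05
  nested <- merge_calls(mk_calls(chrom = 1, start = 1000, end = 1500))
  host <- merge_calls(mk_calls(chrom = 1, start = 1000, end = 2001))
  expect_equal(reciprocal_match(nested, host)$ro, 501 / 1002)

  set.seed(55)
  for (rep in 1:60) {
    a <- merge_calls(random_intervals_df(25))
    b <- merge_calls(random_intervals_df(25))
    for (ro in c(0.3, 0.5, 0.9)) {
      got <- reciprocal_match(a, b, ro)
      want <- bf_match(a, b, ro)
      expect_equal(pair_key(got), pair_key(want))
    }
  }
})

test_that("carrier frequency needs an explicit positive denominator", {
  set <- merge_calls(validate_cnv_calls(rbind(
    mk_calls(chrom = 1, start = 100, end = 300, sample = "A"),
    mk_calls(chrom = 1, start = 150, end = 350, sample = "B"),
    mk_calls(chrom = 1, start = 200, end = 260, sample = "C")
  )))
  expect_equal(region_frequency(set, 40), 0.075)
  expect_equal(region_frequency(set, 38), 3 / 38)
  empty_set <- merge_calls(mk_calls(chrom = 1, start = 5000, end = 6000))
  empty_set$carriers <- list(character(0))
  empty_set$n_carriers <- 0L
  expect_equal(region_frequency(empty_set, 40), 0)
  expect_error(region_frequency(set, 0), "positive")
  expect_error(region_frequency(set, 2), "smaller")
})
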