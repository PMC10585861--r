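# helper to build a per-CpG table with planted DM status
cpg_fixture <- function(pos, beta, p_adj, chrom = "chr1") {
  data.frame(chrom = chrom, pos = as.integer(pos), strand = "+",
             beta = beta, p = pmin(p_adj, 1) / 2, p_adj = p_adj)
}

test_that("runs of >= 3 same-direction DM CpGs within 50 bp become calls", {
  cpg <- cpg_fixture(c(100, 130, 160), beta = 1, p_adj = 0.01)
  calls <- call_candidate_dmrs(cpg)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$n_cpgs, 3L)
  expect_equal(c(calls$start, calls$end), c(100L, 161L))
  expect_equal(calls$direction, "hyper")

  # a 51-bp gap breaks the run at the boundary of <= 50
  cpg2 <- cpg_fixture(c(100, 130, 181), beta = 1, p_adj = 0.01)
  expect_equal(nrow(call_candidate_dmrs(cpg2)), 0L)
  cpg3 <- cpg_fixture(c(100, 130, 180), beta = 1, p_adj = 0.01)
  expect_equal(nrow(call_candidate_dmrs(cpg3)), 1L)

  # direction change splits runs; only the hypo run reaches length 3
  cpg4 <- cpg_fixture(c(100, 130, 160, 190, 220),
                      beta = c(1, 1, -1, -1, -1), p_adj = 0.01)
  calls4 <- call_candidate_dmrs(cpg4)
  expect_equal(nrow(calls4), 1L)
  expect_equal(calls4$direction, "hypo")
  expect_equal(calls4$n_cpgs, 3L)

  # non-DM CpGs do not join runs
  cpg5 <- cpg_fixture(c(100, 130, 160), beta = 1, p_adj = c(0.01, 0.5, 0.01))
  expect_equal(nrow(call_candidate_dmrs(cpg5)), 0L)

  expect_error(call_candidate_dmrs(cpg[c(2, 1, 3), ]), "sorted")
})

test_that("calls are invariant to input record order after sorting", {
  set.seed(17)
  pos <- sort(sample(1:5000, 200))
  cpg <- cpg_fixture(pos, beta = rnorm(200),
                     p_adj = sample(c(0.01, 0.3), 200, replace = TRUE))
  ref <- call_candidate_dmrs(cpg)
  perm <- cpg[sample(nrow(cpg)), ]
  perm <- perm[order(perm$chrom, perm$pos), ]
  expect_identical(call_candidate_dmrs(perm), ref)
})

test_that("inclusion criteria flags reproduce a hand-enumerated truth table", {
  islands <- as_region_set(data.frame(region_id = "CGI1", chrom = "chr1",
                                      start = 1000L, end = 2000L))
  calls <- data.frame(
    chrom = "chr1",
    start = c(1100L, 1100L, 1100L, 1100L, 5000L, 1100L),
    end   = c(1300L, 1179L, 1300L, 1300L, 5200L, 1250L),
    n_cpgs = 5L,
    direction = c("hyper", "hyper", "hyper", "hyper", "hyper", "hypo"),
    delta = c(0.60, 0.60, 0.50, 0.60, 0.60, -0.60),
    simes_p = 1e-6,
    q = c(0.001, 0.001, 0.001, 0.20, 0.001, 0.001))
  out <- apply_inclusion_criteria(calls, islands)
  # row 1: passes all; row 2: 79 bp fails length only; row 3: delta == 0.5
  # passes (inclusive); row 4: fails q only; row 5: fails island only;
  # row 6: hypo fails delta only
  expect_equal(out$pass, c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$min_length, c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE))
  expect_equal(out$max_q, c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(out$cpg_island_overlap, c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(out$min_delta, c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(sum(out$pass), 2L)
})

test_that("an 80-bp call at the length boundary passes; 1-bp island overlap counts", {
  islands <- as_region_set(data.frame(chrom = "chr1", start = 0L, end = 101L))
  calls <- data.frame(chrom = "chr1", start = 100L, end = 180L, n_cpgs = 3L,
                      direction = "hyper", delta = 0.5, simes_p = 1e-8,
                      q = 0.01)
  out <- apply_inclusion_criteria(calls, islands)
  expect_true(out$pass)  # length exactly 80, delta exactly 0.5, 1-bp overlap
  no_touch <- as_region_set(data.frame(chrom = "chr1", start = 0L, end = 100L))
  expect_false(apply_inclusion_criteria(calls, no_touch)$pass)
})

test_that("de novo calling on a simulated cohort recovers biomarker regions", {
  co <- small_cohort(seed = 41, n_patients = 12)
  counts <- filter_coverage(co$counts, 7)
  dm <- dm_test(counts, co$sheet, co$regions)
  calls <- call_candidate_dmrs(dm$cpg, counts = counts, sheet = co$sheet)
  screened <- apply_inclusion_criteria(calls, co$islands)
  passing <- screened[screened$pass, ]
  hit <- GenomicRanges::countOverlaps(
    GenomicRanges::GRanges(co$regions$chrom,
                           IRanges::IRanges(co$regions$start + 1L, co$regions$end)),
    GenomicRanges::GRanges(passing$chrom,
                           IRanges::IRanges(passing$start + 1L, passing$end)))
  cls <- co$regions$truth_class
  # with only 12 patients, a region whose true difference sits at the 0.5
  # boundary can fall just short of the delta criterion; most must be hit
  expect_gte(mean(hit[cls == "biomarker"] >= 1), 0.8)
  expect_true(all(hit[cls == "negative_control"] == 0))
})
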