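test_that("segment filtering applies the LOD and length thresholds", {
  seg <- data.frame(sample1 = "a", hap1 = 1L, sample2 = "b", hap2 = 1L,
                    chrom = "1", start_bp = 1, end_bp = 100,
                    lod = c(3.5, 2.9, 5.0, 2.0),
                    length_cm = c(2.0, 2.0, 0.8, 0.5))
  out <- filter_segments(seg, segment_filter_params())
  expect_equal(out$segments$lod, 3.5)          # only (3.5, 2.0 cM) kept
  expect_equal(out$report$n_lod, 2)
  expect_equal(out$report$n_length, 2)
  expect_equal(out$report$n_excluded, 3)
  # literal-conjunction reading: exclude only when both criteria fail
  both <- filter_segments(seg, segment_filter_params(rule = "both"))
  expect_equal(both$segments$lod, c(3.5, 2.9, 5.0))
  expect_error(filter_segments(seg[, -9], segment_filter_params()),
               "length_cm")
})

test_that("spanning counts follow the inclusive spanning rule", {
  mk <- make_markers(5)
  ph <- c(a = "case", b = "case", c = "control")
  none <- spanning_counts(
    data.frame(sample1 = character(0), hap1 = integer(0),
               sample2 = character(0), hap2 = integer(0),
               chrom = character(0), start_bp = numeric(0),
               end_bp = numeric(0), lod = numeric(0)), mk, ph)
  expect_true(all(none$count_cc == 0 & none$count_cn == 0 &
                    none$count_nn == 0))
  seg <- data.frame(sample1 = "a", hap1 = 1L, sample2 = "b", hap2 = 2L,
                    chrom = "1", start_bp = mk$bp[2], end_bp = mk$bp[4],
                    lod = 4)
  prof <- spanning_counts(seg, mk, ph)
  expect_equal(prof$count_cc, c(0, 1, 1, 1, 0))
  expect_equal(prof$N_cc, 1)
  expect_equal(prof$N_cn, 2)
  expect_error(spanning_counts(seg, mk, c(a = "case", c = "control")),
               "without a phenotype")
})

test_that("sweep spanning counts equal the brute-force double loop", {
  set.seed(55)
  ids <- sprintf("s%02d", 1:12)
  ph <- setNames(rep(c("case", "control"), 6), ids)
  mk <- make_markers(25, chroms = c("1", "2"))
  for (rep in 1:25) {
    seg <- make_random_segments(60, ids, chroms = c("1", "2"))
    prof <- spanning_counts(seg, mk, ph)
    bf <- brute_spanning(seg, mk, ph)
    expect_identical(as.integer(prof$count_cc), bf$cc)
    expect_identical(as.integer(prof$count_cn), bf$cn)
    expect_identical(as.integer(prof$count_nn), bf$nn)
    expect_identical(as.integer(prof$coverage), bf$coverage)
  }
})

test_that("genome-wide average and statistic have the stated form", {
  mk <- make_markers(4)
  ph <- c(a = "case", b = "case", c = "case", d = "control")
  seg <- data.frame(sample1 = rep("a", 3), hap1 = 1L,
                    sample2 = rep("b", 3), hap2 = 1L, chrom = "1",
                    start_bp = 1, end_bp = 1e6, lod = 4)
  prof <- spanning_counts(seg, mk, ph)   # every marker spanned 3x
  expect_equal(genomewide_average(prof), 3 / prof$N_cc)
  s <- mapping_statistic(prof)
  expect_equal(s, rep(1, 4))             # uniform profile: s = 1 everywhere
  # scale invariance: doubling counts leaves s unchanged
  prof2 <- prof
  prof2$count_cc <- prof$count_cc * 2L
  expect_equal(mapping_statistic(prof2), s)
  # direct recomputation on a random profile
  prof$count_cc <- c(5L, 0L, 2L, 9L)
  expect_equal(genomewide_average(prof), mean(prof$count_cc / prof$N_cc))
  expect_equal(mapping_statistic(prof),
               (prof$count_cc / prof$N_cc) / mean(prof$count_cc / prof$N_cc))
  expect_equal(mapping_statistic(prof)[2], 0)
  # no case-case pairs is an error
  ph2 <- c(a = "case", b = "control", c = "control", d = "control")
  expect_error(genomewide_average(spanning_counts(seg[0, ], mk, ph2)),
               "N_cc")
})

test_that("low-coverage masking uses the interpolated quantile, strictly", {
  expect_false(any(low_coverage_mask(rep(7, 20), 0.1)))   # all equal: none
  m <- low_coverage_mask(c(0, rep(5, 9)), 0.10)
  expect_equal(attr(m, "q"), 4.5)                         # hand-computed
  expect_equal(which(m), 1L)
  m2 <- low_coverage_mask(1:100, 0.10)
  expect_equal(sum(m2), 10)                               # counts 1..10 < 10.9
  expect_error(low_coverage_mask(numeric(0), 0.1), "no markers")
  expect_error(low_coverage_mask(1:5, 0), "fraction")
})

test_that("removing a segment never increases a spanning count", {
  set.seed(66)
  mk <- make_markers(30)
  ids <- sprintf("s%02d", 1:8)
  seg <- make_random_segments(50, ids)
  full <- coverage_filter(seg, mk, 0.1)
  less <- coverage_filter(seg[-10, ], mk, 0.1)
  expect_true(all(attr(less, "counts") <= attr(full, "counts")))
})
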