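test_that("refined-IBD text parses, canonicalises and round-trips", {
  f <- withr::local_tempfile(fileext = ".ibd")
  writeLines(c("S1\t1\tS2\t2\tchr1\t1000\t500000\t4.2",
               "S9\t2\tS3\t1\tchr2\t200\t900\t3.1"), f)
  seg <- read_refined_ibd(f)
  expect_equal(nrow(seg), 2)
  expect_equal(seg$lod[1], 4.2)
  expect_equal(seg$start_bp[1], 1000)
  # second line swapped into canonical order, haplotypes following samples
  expect_equal(seg$sample1[2], "S3")
  expect_equal(seg$hap1[2], 1L)
  expect_equal(seg$sample2[2], "S9")
  expect_equal(seg$hap2[2], 2L)

  g <- withr::local_tempfile(fileext = ".ibd")
  write_refined_ibd(seg, g)
  seg2 <- read_refined_ibd(g)
  expect_equal(seg, seg2, ignore_attr = TRUE)

  empty <- withr::local_tempfile()
  file.create(empty)
  expect_equal(nrow(read_refined_ibd(empty)), 0)
})

test_that("malformed refined-IBD lines raise errors naming the line", {
  f <- withr::local_tempfile()
  writeLines(c("S1\t1\tS2\t2\tchr1\t1000\t500000\t4.2",
               "S1\t1\tS2\t2\tchr1\t9000\t2000\t4.2"), f)
  expect_error(read_refined_ibd(f), "line 2.*start")
  writeLines("S1\t1\tS2\t2\tchr1\t1000", f)
  expect_error(read_refined_ibd(f), "line 1.*8")
  writeLines("S1\t1\tS2\t2\tchr1\tx\t500000\t4.2", f)
  expect_error(read_refined_ibd(f), "line 1.*non-numeric")
})

test_that("centiMorgan interpolation is exact, extrapolates and floors at 0", {
  map <- genetic_map(data.frame(chrom = "1", bp = c(0, 1e6), cm = c(0, 1)))
  expect_equal(interpolate_cm(5e5, map, "1"), 0.5)
  expect_equal(interpolate_cm(c(0, 1e6), map, "1"), c(0, 1))  # anchors exact
  expect_equal(interpolate_cm(2e6, map, "1"), 2)              # extrapolation
  expect_error(interpolate_cm(100, map, "2"), "absent")
  # floor at 0 below the first anchor
  map2 <- genetic_map(data.frame(chrom = "1", bp = c(1e6, 2e6), cm = c(1, 2)))
  expect_equal(interpolate_cm(0, map2, "1"), 0)
  # monotone non-decreasing on a multi-anchor map with flat stretches
  map3 <- genetic_map(data.frame(chrom = "1", bp = c(0, 1e5, 2e5, 5e5),
                                 cm = c(0, 0.5, 0.5, 2)))
  q <- seq(0, 6e5, by = 1e4)
  v <- interpolate_cm(q, map3, "1")
  expect_true(all(diff(v) >= 0))
  expect_equal(interpolate_cm(c(1e5, 2e5, 5e5), map3, "1"), c(0.5, 0.5, 2))
})

test_that("annotation fills genetic lengths consistently with the map", {
  map <- genetic_map(data.frame(chrom = "1", bp = c(0, 1e6), cm = c(0, 1)))
  seg <- data.frame(sample1 = "a", hap1 = 1L, sample2 = "b", hap2 = 1L,
                    chrom = "1", start_bp = 1, end_bp = 1e6, lod = 5)
  ann <- annotate_segments(seg, map)
  expect_equal(ann$length_cm, 1, tolerance = 1e-5)
  # sub-interval length never exceeds the parent interval's
  sub <- seg; sub$start_bp <- 2e5; sub$end_bp <- 7e5
  expect_lte(annotate_segments(sub, map)$length_cm, ann$length_cm)
})

test_that("genetic map IO round-trips", {
  map <- genetic_map(data.frame(chrom = c("1", "1", "2", "2"),
                                bp = c(0, 1e6, 0, 2e6),
                                cm = c(0, 1.5, 0, 2.2)))
  f <- withr::local_tempfile(fileext = ".map")
  write_genetic_map(map, f)
  expect_equal(read_genetic_map(f), map, ignore_attr = TRUE)
})

test_that("fastIBD conversion uses 0-based indices and drops empty spans", {
  mk <- make_markers(5)                     # bp ~ 166667, 333333, ...
  seg <- data.frame(sample1 = c("a", "a"), hap1 = 1L,
                    sample2 = c("b", "b"), hap2 = 2L, chrom = "1",
                    start_bp = c(mk$bp[3] - 10, mk$bp[1] + 1),
                    end_bp = c(mk$bp[5] + 10, mk$bp[2] - 1),
                    lod = c(4, 5))
  out <- convert_to_fastibd(seg, mk)
  expect_equal(nrow(out$records), 1)
  expect_equal(out$records$start_index, 2L)  # markers 2..4, 0-based
  expect_equal(out$records$end_index, 4L)
  expect_equal(out$n_dropped, 1)
  expect_error(convert_to_fastibd(data.frame(seg[1, -5], chrom = "99"), mk),
               "chromosome")
})

test_that("fastIBD index ranges agree with direct bp spanning counts", {
  set.seed(33)
  mk <- make_markers(50)
  ids <- sprintf("s%02d", 1:10)
  for (rep in 1:20) {
    seg <- make_random_segments(40, ids)
    out <- convert_to_fastibd(seg, mk)
    idx_counts <- integer(nrow(mk))
    for (i in seq_len(nrow(out$records)))
      idx_counts[(out$records$start_index[i]:out$records$end_index[i]) + 1] <-
        idx_counts[(out$records$start_index[i]:out$records$end_index[i]) + 1] + 1L
    ph <- setNames(rep("case", 10), ids)
    direct <- brute_spanning(seg, mk, ph)
    expect_identical(idx_counts, direct$coverage)
  }
})

test_that("ped/map and VCF panel IO round-trip genotypes and phenotypes", {
  p <- make_clean_panel(12, 8, seed = 3)
  p$calls[2, 3] <- NA
  prefix <- withr::local_tempfile()
  write_ped(p, prefix)
  p2 <- read_ped(prefix)
  expect_identical(unname(p2$calls), unname(p$calls))
  expect_equal(p2$sample_ids, p$sample_ids)
  expect_equal(p2$phenotype, p$phenotype)
  expect_equal(p2$markers$bp, p$markers$bp)

  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_panel(p, vcf)
  phf <- withr::local_tempfile(fileext = ".tsv")
  write_phenotypes(panel_phenotypes(p), phf)
  p3 <- read_vcf_panel(vcf, read_phenotypes(phf))
  expect_identical(unname(p3$calls), unname(p$calls))
  expect_equal(p3$phenotype, p$phenotype)
})
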