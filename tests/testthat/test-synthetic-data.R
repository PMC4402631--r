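test_that("a clean simulated panel passes QC and is seed-deterministic", {
  spec <- sim_spec(n_cases = 30, n_controls = 30, n_markers_per_chrom = 40,
                   missing_rate = 0, seed = 5)
  sim <- simulate_panel(spec)
  res <- apply_qc(sim$panel)
  expect_equal(nrow(res$removed_individuals), 0)
  expect_equal(nrow(res$removed_markers), 0)
  sim2 <- simulate_panel(spec)
  expect_identical(sim$panel$calls, sim2$panel$calls)
  expect_identical(sim$truth, sim2$truth)
})

test_that("infeasible HWE plants are rejected with an explicit error", {
  spec <- sim_spec(n_cases = 4, n_controls = 4, n_markers_per_chrom = 10,
                   seed = 1)
  expect_error(simulate_panel(spec, n_hwe_fail = 1), "infeasible")
})

test_that("simulated embeddings separate planted outliers from the core", {
  sim <- simulate_embedding(200, 0, seed = 3)
  expect_true(all(sim$truth == "core"))
  expect_error(simulate_embedding(10, 1), ">= 11")
  expect_error(simulate_embedding(50, 1, outlier_offset = 0), "> 0")

  sim <- simulate_embedding(300, 8, dims = 6, core_scale = 0.03,
                            outlier_offset = 0.3, seed = 9)
  expect_equal(ncol(sim$embedding$coords), 6)
  mkd <- mean_knn_distance(sim$embedding, 10)
  expect_true(all(mkd[sim$truth == "core"] < 0.15))
  expect_true(all(mkd[sim$truth == "outlier"] > 0.15))
})

test_that("segment simulation respects chromosome bounds and determinism", {
  spec <- sim_spec(n_cases = 15, n_controls = 15, seed = 21,
                   telomere_retention = 0.5)
  sim <- simulate_ibd_segments(spec)
  seg <- sim$segments
  expect_true(all(seg$start_bp < seg$end_bp))
  len <- spec$chromosomes$length_bp[match(seg$chrom, spec$chromosomes$name)]
  expect_true(all(seg$start_bp >= 1 & seg$end_bp <= len))
  expect_true(all(seg$sample1 <= seg$sample2))
  expect_true(all(seg$hap1 %in% 1:2 & seg$hap2 %in% 1:2))
  sim2 <- simulate_ibd_segments(spec)
  expect_identical(seg, sim2$segments)
})

test_that("segment lengths follow the Pareto closed-form mean", {
  set.seed(99)
  draws <- rpareto(1e5, 2.5, 0.65)
  mu <- 2.5 * 0.65 / 1.5          # alpha * x_m / (alpha - 1) = 1.0833
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - mu), 2 * se)
  expect_true(all(draws >= 0.65))
})

test_that("pair classes are exchangeable under enrichment 1", {
  spec <- sim_spec(n_cases = 40, n_controls = 40, seed = 31)
  sim <- simulate_ibd_segments(spec)
  ph <- sim_phenotypes(spec)
  prof <- spanning_counts(sim$segments, sim_markers(spec), ph)
  # per-pair per-marker rates should agree across classes up to noise
  r_cc <- mean(prof$count_cc) / prof$N_cc
  r_cn <- mean(prof$count_cn) / prof$N_cn
  r_nn <- mean(prof$count_nn) / prof$N_nn
  expect_lt(abs(r_cc / r_cn - 1), 0.15)
  expect_lt(abs(r_cc / r_nn - 1), 0.15)
})

test_that("a planted locus enriches case-case sharing there", {
  mk <- sim_markers(sim_spec())
  locus_bp <- mk$bp[mk$chrom == "1"][125]
  spec <- sim_spec(n_cases = 40, n_controls = 40, seed = 13,
                   planted_locus = list(chrom = "1", bp = locus_bp),
                   enrichment = 5)
  sim <- simulate_ibd_segments(spec)
  expect_gt(sim$truth$n_enriched_copies, 0)
  prof <- spanning_counts(sim$segments, mk, sim_phenotypes(spec))
  i <- which(mk$chrom == "1" & mk$bp == locus_bp)
  expect_gt(prof$count_cc[i], 2 * mean(prof$count_cc))
  # control-control sharing is not enriched
  expect_lt(prof$count_nn[i], 2 * mean(prof$count_nn))
})

test_that("telomeric depletion thins segments near chromosome ends", {
  base <- sim_spec(n_cases = 40, n_controls = 40, seed = 17,
                   telomere_width_cm = 10, telomere_retention = 1)
  dep <- sim_spec(n_cases = 40, n_controls = 40, seed = 17,
                  telomere_width_cm = 10, telomere_retention = 0.2)
  mid_of <- function(s) (s$start_bp + s$end_bp) / 2e6  # cM at 1 cM/Mb
  near_end <- function(s) {
    m <- mid_of(s)
    sum(m < 10 | m > 90)
  }
  n_base <- near_end(simulate_ibd_segments(base)$segments)
  n_dep <- near_end(simulate_ibd_segments(dep)$segments)
  expect_lt(n_dep, 0.5 * n_base)
})

test_that("planted locus outside the genome is rejected", {
  expect_error(sim_spec(planted_locus = list(chrom = "7", bp = 100)),
               "not in the genome")
  expect_error(sim_spec(planted_locus = list(chrom = "1", bp = 2e8)),
               "outside")
})
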