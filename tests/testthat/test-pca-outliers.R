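test_that("compute_pcs handles zero variance and separates clusters", {
  mk <- make_markers(20)
  p0 <- genotype_panel(matrix(1L, 15, 20), sprintf("s%02d", 1:15),
                       rep("case", 15), mk)
  emb0 <- compute_pcs(p0, 3)
  expect_true(attr(emb0, "zero_variance"))
  expect_true(all(emb0$coords == 0))

  # two groups with different allele frequencies at every marker
  set.seed(2)
  gA <- vapply(1:20, function(j) rbinom(20, 2, 0.1), integer(20))
  gB <- vapply(1:20, function(j) rbinom(20, 2, 0.9), integer(20))
  p <- genotype_panel(rbind(gA, gB), sprintf("s%02d", 1:40),
                      rep(c("case", "control"), each = 20), mk)
  emb <- compute_pcs(p, 4)
  pc1 <- emb$coords[, 1]
  expect_true(all(sign(pc1[1:20]) == sign(pc1[1])))
  expect_true(all(sign(pc1[21:40]) == -sign(pc1[1])))
  # orthogonality of components
  cv <- crossprod(emb$coords)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-10)
})

test_that("compute_pcs matches a brute-force eigendecomposition", {
  set.seed(8)
  p <- make_clean_panel(30, 120, seed = 8)
  emb <- compute_pcs(p, 5)
  X <- p$calls
  ph <- colMeans(X) / 2
  W <- sweep(sweep(X, 2, 2 * ph), 2, sqrt(ph * (1 - ph)), "/")
  ev <- eigen(tcrossprod(W), symmetric = TRUE)$vectors[, 1:5]
  for (j in 1:5) {
    v <- ev[, j]
    i <- which.max(abs(v))
    if (v[i] < 0) v <- -v
    expect_equal(unname(emb$coords[, j]), v, tolerance = 1e-8)
  }
})

test_that("mean_knn_distance matches hand-computed values", {
  # two points at distance d, k = 1
  e2 <- pc_embedding(matrix(c(0, 3), 2, 1), c("a", "b"))
  expect_equal(unname(mean_knn_distance(e2, 1)), c(3, 3))
  # 12 unit-spaced colinear points, middle point, k = 10:
  # distances {1,1,2,2,3,3,4,4,5,5} -> mean 3; end point: 1..10 -> 5.5
  e12 <- pc_embedding(matrix(0:11, 12, 1), sprintf("p%02d", 1:12))
  mkd <- mean_knn_distance(e12, 10)
  expect_equal(unname(mkd[6]), 3)
  expect_equal(unname(mkd[1]), 5.5)
  # duplicated points have distance 0 to each other
  edup <- pc_embedding(matrix(c(0, 0, 5), 3, 1), c("a", "b", "c"))
  expect_equal(unname(mean_knn_distance(edup, 1)), c(0, 0, 5))
  expect_error(mean_knn_distance(e2, 5), "at least")
})

test_that("two-stage removal keeps a tight cluster intact", {
  set.seed(4)
  coords <- matrix(rnorm(20 * 6, sd = 0.005), 20, 6)
  emb <- pc_embedding(coords, sprintf("s%02d", 1:20))
  res <- two_stage_outlier_removal(emb, outlier_params())
  expect_setequal(res$kept, emb$sample_ids)
})

test_that("planted outliers are removed and the core is retained", {
  sim <- simulate_embedding(400, 6, core_scale = 0.03, outlier_offset = 0.3,
                            seed = 12)
  res <- two_stage_outlier_removal(sim$embedding)
  out_ids <- names(sim$truth)[sim$truth == "outlier"]
  core_ids <- names(sim$truth)[sim$truth == "core"]
  expect_length(intersect(res$kept, out_ids), 0)
  expect_gte(length(intersect(res$kept, core_ids)), 0.95 * length(core_ids))
})

test_that("the 9-of-10 interior rule removes boundary samples passing stage 1", {
  # 11 tight cluster points, a boundary sample X whose 10 nearest
  # neighbours include 2 sparse points failing stage 1, and those 2 points
  a <- matrix(seq(0, 0.01, by = 0.001), ncol = 1)     # 11 cluster points
  x <- matrix(-0.1, 1, 1)                              # boundary sample
  b <- matrix(c(-0.15, -0.16), 2, 1)                   # sparse pair
  emb <- pc_embedding(rbind(a, x, b),
                      c(sprintf("a%02d", 1:11), "x", "b1", "b2"))
  par <- outlier_params(n_neighbors = 10, density_cutoff = 0.1,
                        interior_min = 9, n_pcs = 1)
  res <- two_stage_outlier_removal(emb, par)
  d <- res$diagnostics
  expect_true(d$stage1[d$sample_id == "x"])
  expect_false(d$stage1[d$sample_id == "b1"])
  expect_equal(d$n_interior[d$sample_id == "x"], 8)
  expect_false("x" %in% res$kept)
  expect_true(all(sprintf("a%02d", 1:11) %in% res$kept))
})

test_that("stage sets are nested and stage 1 is monotone in the cutoff", {
  sim <- simulate_embedding(100, 5, core_scale = 0.05, outlier_offset = 0.4,
                            seed = 77)
  for (cut in c(0.05, 0.1, 0.2)) {
    par <- outlier_params(density_cutoff = cut)
    res <- two_stage_outlier_removal(sim$embedding, par)
    d <- res$diagnostics
    expect_true(all(d$stage2 <= d$stage1))  # stage2 subset of stage1
  }
  s1_at <- function(cut) {
    d <- two_stage_outlier_removal(sim$embedding,
                                   outlier_params(density_cutoff = cut))
    d$diagnostics$stage1
  }
  lo <- s1_at(0.05); hi <- s1_at(0.15)
  expect_true(all(!lo | hi))  # lowering the cutoff never adds samples
})
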