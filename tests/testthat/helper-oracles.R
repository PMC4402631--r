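# Independent oracles and small fixture builders used across the suite.

# Exact HWE test by upward recurrence over heterozygote counts, conditioning
# on the observed allele counts. Independent of the package's log-gamma
# implementation.
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n - nA
  if (nA == 0 || na == 0) return(1)
  hs <- seq(nA %% 2, min(nA, na), by = 2)
  p <- numeric(length(hs))
  p[1] <- 1
  if (length(hs) > 1) for (i in 2:length(hs)) {
    h <- hs[i - 1]
    p[i] <- p[i - 1] * 4 * ((nA - h) / 2) * ((na - h) / 2) /
      ((h + 1) * (h + 2))
  }
  p <- p / sum(p)
  p_obs <- p[match(n_Aa, hs)]
  sum(p[p <= p_obs * (1 + 1e-12)])
}

# Brute-force per-marker spanning counts: double loop over (segment, marker).
brute_spanning <- function(segments, markers, phenotypes) {
  cls <- paste0(ifelse(phenotypes[segments$sample1] == "case", "c", "n"),
                ifelse(phenotypes[segments$sample2] == "case", "c", "n"))
  cls[cls == "nc"] <- "cn"
  out <- matrix(0L, nrow(markers), 3,
                dimnames = list(NULL, c("cc", "cn", "nn")))
  cov <- integer(nrow(markers))
  for (i in seq_len(nrow(segments))) {
    hit <- markers$chrom == segments$chrom[i] &
      markers$bp >= segments$start_bp[i] & markers$bp <= segments$end_bp[i]
    out[hit, cls[i]] <- out[hit, cls[i]] + 1L
    cov[hit] <- cov[hit] + 1L
  }
  list(cc = out[, "cc"], cn = out[, "cn"], nn = out[, "nn"], coverage = cov)
}

# Evenly spaced marker table on one or more chromosomes.
make_markers <- function(n_per_chrom, chroms = "1", length_bp = 1e6) {
  do.call(rbind, lapply(chroms, function(ch) {
    bp <- round(seq_len(n_per_chrom) * length_bp / (n_per_chrom + 1))
    data.frame(id = sprintf("m%s_%03d", ch, seq_len(n_per_chrom)),
               chrom = ch, bp = bp, stringsAsFactors = FALSE)
  }))
}

# Random annotated-ish segment fixture over given samples and chromosomes.
make_random_segments <- function(n, sample_ids, chroms = "1",
                                 length_bp = 1e6) {
  pr <- replicate(n, sort(sample(sample_ids, 2)))
  a <- sample.int(length_bp - 1, n, replace = TRUE)
  b <- a + sample.int(round(length_bp / 4), n, replace = TRUE)
  data.frame(sample1 = pr[1, ], hap1 = sample(1:2, n, TRUE),
             sample2 = pr[2, ], hap2 = sample(1:2, n, TRUE),
             chrom = sample(chroms, n, replace = TRUE),
             start_bp = a, end_bp = pmin(b, length_bp),
             lod = 3 + rexp(n, 0.5),
             stringsAsFactors = FALSE)
}

# A small clean panel: HWE genotypes at moderate MAF, no missingness.
make_clean_panel <- function(n_samples = 40, n_markers = 30, seed = 42) {
  set.seed(seed)
  markers <- make_markers(n_markers)
  calls <- vapply(seq_len(n_markers), function(j) {
    p <- runif(1, 0.2, 0.45)
    sample(0:2, n_samples, TRUE, prob = c((1 - p)^2, 2 * p * (1 - p), p^2))
  }, integer(n_samples))
  ids <- sprintf("s%03d", seq_len(n_samples))
  pheno <- rep(c("case", "control"), length.out = n_samples)
  genotype_panel(calls, ids, pheno, markers)
}
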