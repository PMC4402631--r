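#' Simulate a genotype panel with planted QC failures
#'
#' Generates a diploid biallelic panel in which all markers and
#' individuals pass the standard QC thresholds with margin, except for an
#' exactly specified set of planted failures: markers failing the MAF
#' filter (rare coded allele), markers failing the exact HWE filter
#' (complete heterozygote excess), markers failing the marker-missingness
#' filter, and individuals failing the individual-missingness filter.
#' Clean markers draw their allele frequency from \code{spec$maf_range}
#' under Hardy-Weinberg proportions and are rejection-sampled until they
#' pass all thresholds with margin (MAF >= 0.10, HWE p >= 1e-4,
#' missingness <= 0.05) on the sample set that survives individual
#' removal.
#'
#' @param spec a \code{\link{sim_spec}}.
#' @param n_maf_fail,n_hwe_fail,n_marker_missing_fail number of markers
#'   planted to fail each filter.
#' @param n_ind_missing_fail number of individuals planted to exceed the
#'   individual-missingness threshold.
#' @param thresholds the \code{\link{qc_thresholds}} the plants are set
#'   against.
#' @return list with \code{panel} (a \code{genotype_panel}) and
#'   \code{truth}: character vectors \code{maf_fail}, \code{hwe_fail},
#'   \code{marker_missing_fail} (marker ids) and \code{ind_missing_fail}
#'   (sample ids).
#' @export
simulate_panel <- function(spec, n_maf_fail = 0, n_hwe_fail = 0,
                           n_marker_missing_fail = 0, n_ind_missing_fail = 0,
                           thresholds = qc_thresholds()) {
  stopifnot(inherits(spec, "sim_spec"))
  ph <- sim_phenotypes(spec)
  markers <- sim_markers(spec)
  n <- length(ph)
  m <- nrow(markers)
  n_plant_markers <- n_maf_fail + n_hwe_fail + n_marker_missing_fail
  if (n_plant_markers > m) stop2("more planted marker failures than markers")
  if (n_ind_missing_fail > n) stop2("more planted individuals than samples")
  n_eff <- n - n_ind_missing_fail  # samples entering marker QC statistics
  if (n_eff < 2) stop2("too few surviving individuals to compute marker QC")
  if (n_hwe_fail > 0 && hwe_exact_p(0, n_eff, 0) >= thresholds$hwe_p_min)
    stop2("infeasible plant: all-heterozygote configuration at n = ", n_eff,
          " cannot reach HWE p < ", thresholds$hwe_p_min)
  maf_target <- floor(0.8 * thresholds$maf_min * 2 * n_eff)  # minor alleles
  if (n_maf_fail > 0 && maf_target / (2 * n_eff) >= thresholds$maf_min)
    stop2("infeasible plant: cannot place MAF below ", thresholds$maf_min)

  set.seed(spec$seed)
  plant_ids <- sample.int(n, n_ind_missing_fail)
  marker_plant <- sample.int(m, n_plant_markers)
  maf_markers <- marker_plant[seq_len(n_maf_fail)]
  hwe_markers <- marker_plant[n_maf_fail + seq_len(n_hwe_fail)]
  miss_markers <- marker_plant[n_maf_fail + n_hwe_fail +
                                 seq_len(n_marker_missing_fail)]
  surv <- setdiff(seq_len(n), plant_ids)

  calls <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    if (j %in% maf_markers) {
      # rare coded allele carried only by heterozygotes among survivors
      g <- integer(n)
      g[sample(surv, maf_target)] <- 1L
      calls[, j] <- g
    } else if (j %in% hwe_markers) {
      calls[, j] <- 1L  # every sample heterozygous
    } else {
      # clean marker, redrawn until it passes QC with margin on survivors
      for (try in 1:100) {
        p <- stats::runif(1, spec$maf_range[1], spec$maf_range[2])
        g <- sample(0:2, n, replace = TRUE,
                    prob = c((1 - p)^2, 2 * p * (1 - p), p^2))
        if (spec$missing_rate > 0)
          g[stats::runif(n) < spec$missing_rate] <- NA_integer_
        if (j %in% miss_markers) {
          # push marker missingness well past the threshold among survivors
          k <- ceiling(2 * thresholds$marker_missing_max * length(surv))
          g[sample(surv, k)] <- NA_integer_
        }
        gs <- g[surv]
        nobs <- sum(!is.na(gs))
        if (nobs < 2) next
        n1 <- sum(gs == 1L, na.rm = TRUE); n2 <- sum(gs == 2L, na.rm = TRUE)
        freq <- (n1 + 2 * n2) / (2 * nobs)
        maf <- min(freq, 1 - freq)
        miss <- 1 - nobs / length(surv)
        if (j %in% miss_markers) {
          if (miss > 1.5 * thresholds$marker_missing_max) break
        } else if (maf >= 2 * thresholds$maf_min &&
                   miss <= 0.5 * thresholds$marker_missing_max &&
                   hwe_exact_p(nobs - n1 - n2, n1, n2) >=
                     100 * thresholds$hwe_p_min) break
        if (try == 100) stop2("could not generate a passing marker")
      }
      calls[, j] <- g
    }
  }
  # plant high-missingness individuals: blank out well over the threshold
  if (n_ind_missing_fail > 0) {
    k <- ceiling(1.7 * thresholds$ind_missing_max * m)
    for (i in plant_ids) calls[i, sample.int(m, k)] <- NA_integer_
  }
  panel <- genotype_panel(calls, names(ph), unname(ph), markers)
  # construction guarantees: verify non-planted individuals pass with margin
  imiss <- rowMeans(is.na(calls[surv, , drop = FALSE]))
  if (any(imiss > 0.9 * thresholds$ind_missing_max))
    stop2("clean individual drifted toward the missingness threshold; ",
          "lower spec$missing_rate")
  list(panel = panel,
       truth = list(maf_fail = markers$id[sort(maf_markers)],
                    hwe_fail = markers$id[sort(hwe_markers)],
                    marker_missing_fail = markers$id[sort(miss_markers)],
                    ind_missing_fail = names(ph)[sort(plant_ids)]))
}
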