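#' Quality-control thresholds
#'
#' Standard GWAS-style marker and individual filters: minimum minor allele
#' frequency, exact Hardy-Weinberg p-value floor, maximum missingness per
#' individual and per marker. Defaults are the conventional values for
#' IBD-mapping panels (MAF 0.05, HWE 1e-6, individual missingness 0.07,
#' marker missingness 0.1).
#'
#' @param maf_min minimum minor allele frequency; markers below are removed.
#' @param hwe_p_min minimum exact HWE p-value; markers below are removed.
#' @param ind_missing_max maximum per-individual missing-call proportion.
#' @param marker_missing_max maximum per-marker missing-call proportion.
#' @param hwe_samples which samples enter the HWE test: \code{"all"} (default)
#'   or \code{"controls"}.
#' @return an object of class \code{qc_thresholds}.
#' @export
qc_thresholds <- function(maf_min = 0.05, hwe_p_min = 1e-6,
                          ind_missing_max = 0.07, marker_missing_max = 0.1,
                          hwe_samples = c("all", "controls")) {
  hwe_samples <- match.arg(hwe_samples)
  vals <- c(maf_min, hwe_p_min, ind_missing_max, marker_missing_max)
  if (any(vals < 0) || any(vals > 1))
    stop2("all thresholds must lie in [0, 1]")
  structure(list(maf_min = maf_min, hwe_p_min = hwe_p_min,
                 ind_missing_max = ind_missing_max,
                 marker_missing_max = marker_missing_max,
                 hwe_samples = hwe_samples),
            class = "qc_thresholds")
}

#' Per-marker genotype statistics
#'
#' Genotype counts, minor allele frequency and call rate per marker.
#' MAF is the frequency of the rarer allele among non-missing calls:
#' minor allele count / (2 x non-missing sample count). A marker with no
#' non-missing calls has call rate 0 and undefined (NA) MAF, flagged in the
#' \code{undefined} column.
#'
#' @param panel a \code{genotype_panel}.
#' @param samples optional sample ids to restrict to.
#' @return data.frame with one row per marker: \code{id}, \code{n_0},
#'   \code{n_1}, \code{n_2}, \code{n_missing}, \code{maf}, \code{call_rate},
#'   \code{undefined}.
#' @export
marker_stats <- function(panel, samples = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  calls <- panel$calls
  if (!is.null(samples)) {
    idx <- match(samples, panel$sample_ids)
    if (anyNA(idx)) stop2("unknown sample id")
    calls <- calls[idx, , drop = FALSE]
  }
  if (length(calls) == 0L) stop2("empty panel")
  n <- nrow(calls)
  n0 <- colSums(calls == 0L, na.rm = TRUE)
  n1 <- colSums(calls == 1L, na.rm = TRUE)
  n2 <- colSums(calls == 2L, na.rm = TRUE)
  nobs <- n0 + n1 + n2
  freq <- ifelse(nobs > 0, (n1 + 2 * n2) / (2 * nobs), NA_real_)
  maf <- pmin(freq, 1 - freq)
  data.frame(id = panel$markers$id,
             n_0 = as.integer(n0), n_1 = as.integer(n1),
             n_2 = as.integer(n2),
             n_missing = as.integer(n - nobs),
             maf = maf,
             call_rate = nobs / n,
             undefined = nobs == 0L,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided conditional exact test: conditioning on the observed allele
#' counts, the p-value is the total probability of heterozygote
#' configurations as probable or less probable than the observed one.
#'
#' @param n_AA,n_Aa,n_aa observed genotype counts (non-negative, not all
#'   zero).
#' @return p-value in (0, 1].
#' @examples
#' hwe_exact_p(5, 0, 0)   # monomorphic: 1
#' hwe_exact_p(0, 50, 0)  # extreme heterozygote excess: << 1e-6
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop2("genotype counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop2("all genotype counts are zero")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n - nA
  if (nA == 0 || na == 0) return(1)  # monomorphic: single configuration
  # heterozygote counts compatible with the allele counts share nA's parity
  hmax <- min(nA, na)
  h <- seq.int(nA %% 2, hmax, by = 2)
  # log P(h het | allele counts) up to the common normaliser
  lp <- h * log(2) - lfactorial((nA - h) / 2) - lfactorial(h) -
    lfactorial((na - h) / 2)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  p_obs <- p[match(n_Aa, h)]
  sum(p[p <= p_obs * (1 + 1e-12)])
}

#' Apply quality-control filters to a genotype panel
#'
#' Removes individuals whose missing-call proportion exceeds
#' \code{ind_missing_max}, then removes markers failing (in order of
#' precedence) the marker-missingness, MAF or exact-HWE threshold, with
#' marker statistics recomputed after the individual removal.
#'
#' @param panel a \code{genotype_panel}.
#' @param thresholds a \code{qc_thresholds} object.
#' @return an object of class \code{qc_result}: \code{panel} (filtered),
#'   \code{removed_individuals} (data.frame id, missing_rate),
#'   \code{removed_markers} (data.frame id, reason, value; reason one of
#'   \code{"missing"}, \code{"maf"}, \code{"hwe"}), \code{thresholds},
#'   \code{empty} flag set when nothing survives.
#' @export
apply_qc <- function(panel, thresholds = qc_thresholds()) {
  stopifnot(inherits(panel, "genotype_panel"),
            inherits(thresholds, "qc_thresholds"))
  ind_miss <- rowMeans(is.na(panel$calls))
  drop_ind <- ind_miss > thresholds$ind_missing_max
  removed_individuals <- data.frame(
    id = panel$sample_ids[drop_ind],
    missing_rate = unname(ind_miss[drop_ind]),
    stringsAsFactors = FALSE)

  kept <- subset_panel(panel, samples = !drop_ind)

  reason <- character(0); value <- numeric(0); bad_id <- character(0)
  keep_marker <- rep(TRUE, nrow(kept$markers))
  if (length(kept$sample_ids) > 0L) {
    hwe_set <- if (thresholds$hwe_samples == "controls")
      kept$sample_ids[kept$phenotype == "control"] else NULL
    st <- marker_stats(kept)
    st_hwe <- if (is.null(hwe_set)) st else marker_stats(kept, hwe_set)
    miss_rate <- 1 - st$call_rate
    hwe_p <- mapply(hwe_exact_p, st_hwe$n_0, st_hwe$n_1, st_hwe$n_2)
    fail_miss <- miss_rate > thresholds$marker_missing_max
    fail_maf <- !fail_miss & (st$undefined | st$maf < thresholds$maf_min)
    fail_hwe <- !fail_miss & !fail_maf & hwe_p < thresholds$hwe_p_min
    keep_marker <- !(fail_miss | fail_maf | fail_hwe)
    bad_id <- c(st$id[fail_miss], st$id[fail_maf], st$id[fail_hwe])
    reason <- c(rep("missing", sum(fail_miss)),
                rep("maf", sum(fail_maf)),
                rep("hwe", sum(fail_hwe)))
    value <- c(miss_rate[fail_miss], st$maf[fail_maf], hwe_p[fail_hwe])
  }
  removed_markers <- data.frame(id = bad_id, reason = reason, value = value,
                                stringsAsFactors = FALSE)
  out <- subset_panel(kept, markers = keep_marker)
  structure(list(panel = out,
                 removed_individuals = removed_individuals,
                 removed_markers = removed_markers,
                 thresholds = thresholds,
                 empty = length(out$sample_ids) == 0L ||
                   nrow(out$markers) == 0L),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("Genotype QC:\n")
  cat("  removed individuals:", nrow(x$removed_individuals), "\n")
  if (nrow(x$removed_markers)) {
    tab <- table(x$removed_markers$reason)
    cat("  removed markers:", nrow(x$removed_markers),
        paste0("(", paste(names(tab), tab, sep = "=", collapse = ", "), ")\n"))
  } else cat("  removed markers: 0\n")
  cat("  surviving:", length(x$panel$sample_ids), "samples x",
      nrow(x$panel$markers), "markers\n")
  if (x$empty) cat("  WARNING: QC removed everything\n")
  invisible(x)
}
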