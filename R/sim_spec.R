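#' Default simulated genome
#'
#' Two chromosomes of 100 Mb with a uniform 1 cM/Mb recombination rate,
#' i.e. 100 cM (one Morgan) each.
#'
#' @return data.frame with columns \code{name}, \code{length_bp},
#'   \code{cm_per_mb}.
#' @export
default_chromosomes <- function() {
  data.frame(name = c("1", "2"),
             length_bp = c(1e8, 1e8),
             cm_per_mb = c(1, 1),
             stringsAsFactors = FALSE)
}

#' Simulation specification
#'
#' All parameters of the synthetic cohort generator in one validated
#' object. The defaults are the calibration used throughout the package's
#' validation: 50 cases and 50 controls on a two-chromosome, two-Morgan
#' genome with 250 evenly spaced markers per chromosome; IBD segment
#' lengths Pareto(shape 2.5, scale 0.65 cM) so the mean length
#' \eqn{\alpha x_m/(\alpha-1) = 1.083} cM sits slightly above 1 cM; a
#' per-pair segment rate of 1.5 per Morgan so a marker is spanned by about
#' 20 case-case segments.
#'
#' @param n_cases,n_controls sample sizes.
#' @param chromosomes data.frame with \code{name}, \code{length_bp},
#'   \code{cm_per_mb} (uniform recombination rate per chromosome).
#' @param n_markers_per_chrom evenly spaced markers per chromosome.
#' @param maf_range range of the uniform minor-allele-frequency
#'   distribution for simulated markers, inside (0, 0.5).
#' @param missing_rate per-call missingness probability for clean markers.
#' @param base_share_rate expected IBD segments per sample pair per Morgan.
#' @param pareto_shape Pareto tail index \eqn{\alpha > 1} for segment
#'   lengths (cM).
#' @param pareto_scale Pareto minimum \eqn{x_m > 0} in cM.
#' @param planted_locus NULL, or \code{list(chrom =, bp =)} marking the
#'   risk locus at which case-case sharing is enriched.
#' @param enrichment multiplicative factor >= 1 on case-case segment mass
#'   at the planted locus; 1 means the null (pair classes exchangeable).
#' @param telomere_width_cm width of the terminal window with depleted
#'   segment detection.
#' @param telomere_retention probability that a segment whose midpoint
#'   falls in a terminal window is retained; 1 disables depletion.
#' @param lod_low_frac fraction of segments given a LOD drawn uniformly in
#'   (0, 3) instead of 3 + Exp(mean 2); use > 0 to exercise the LOD filter.
#' @param seed integer seed; identical specs with identical seeds generate
#'   identical data.
#' @return an object of class \code{sim_spec}.
#' @export
sim_spec <- function(n_cases = 50, n_controls = 50,
                     chromosomes = default_chromosomes(),
                     n_markers_per_chrom = 250,
                     maf_range = c(0.15, 0.45),
                     missing_rate = 0.01,
                     base_share_rate = 1.5,
                     pareto_shape = 2.5,
                     pareto_scale = 0.65,
                     planted_locus = NULL,
                     enrichment = 1,
                     telomere_width_cm = 5,
                     telomere_retention = 1,
                     lod_low_frac = 0,
                     seed = 1L) {
  stopifnot(n_cases >= 1, n_controls >= 1, n_markers_per_chrom >= 1,
            is.data.frame(chromosomes),
            all(c("name", "length_bp", "cm_per_mb") %in% names(chromosomes)),
            all(chromosomes$length_bp > 0), all(chromosomes$cm_per_mb > 0),
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] < 0.5,
            maf_range[1] <= maf_range[2],
            missing_rate >= 0, missing_rate < 1,
            base_share_rate >= 0,
            pareto_scale > 0,
            enrichment >= 1,
            telomere_width_cm >= 0,
            telomere_retention >= 0, telomere_retention <= 1,
            lod_low_frac >= 0, lod_low_frac <= 1)
  if (pareto_shape <= 1)
    stop2("pareto_shape must be > 1 so the mean length is finite")
  chromosomes$name <- as.character(chromosomes$name)
  if (!is.null(planted_locus)) {
    stopifnot(is.list(planted_locus),
              all(c("chrom", "bp") %in% names(planted_locus)))
    planted_locus$chrom <- as.character(planted_locus$chrom)
    i <- match(planted_locus$chrom, chromosomes$name)
    if (is.na(i)) stop2("planted locus chromosome not in the genome")
    if (planted_locus$bp < 1 || planted_locus$bp > chromosomes$length_bp[i])
      stop2("planted locus position outside chromosome ", planted_locus$chrom)
  }
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 chromosomes = chromosomes,
                 n_markers_per_chrom = n_markers_per_chrom,
                 maf_range = maf_range, missing_rate = missing_rate,
                 base_share_rate = base_share_rate,
                 pareto_shape = pareto_shape, pareto_scale = pareto_scale,
                 planted_locus = planted_locus, enrichment = enrichment,
                 telomere_width_cm = telomere_width_cm,
                 telomere_retention = telomere_retention,
                 lod_low_frac = lod_low_frac,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' @export
print.sim_spec <- function(x, ...) {
  cat("Simulation spec:", x$n_cases, "cases +", x$n_controls, "controls;",
      nrow(x$chromosomes), "chromosomes x", x$n_markers_per_chrom,
      "markers\n")
  cat(sprintf("  segment lengths ~ Pareto(shape %.3g, scale %.3g cM), mean %.3f cM\n",
              x$pareto_shape, x$pareto_scale,
              x$pareto_shape * x$pareto_scale / (x$pareto_shape - 1)))
  cat(sprintf("  share rate %.3g segments/pair/Morgan; enrichment %.3g%s\n",
              x$base_share_rate, x$enrichment,
              if (is.null(x$planted_locus)) "" else
                sprintf(" at %s:%d", x$planted_locus$chrom,
                        as.integer(x$planted_locus$bp))))
  cat(sprintf("  telomere depletion: width %.3g cM, retention %.3g; seed %d\n",
              x$telomere_width_cm, x$telomere_retention, x$seed))
  invisible(x)
}

#' Sample ids and phenotypes implied by a simulation spec
#'
#' @param spec a \code{sim_spec}.
#' @return named character vector (sample id -> "case"/"control").
#' @export
sim_phenotypes <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  ids <- c(sprintf("case_%03d", seq_len(spec$n_cases)),
           sprintf("ctrl_%03d", seq_len(spec$n_controls)))
  stats::setNames(rep(c("case", "control"), c(spec$n_cases, spec$n_controls)),
                  ids)
}

#' Marker table implied by a simulation spec
#'
#' Markers evenly spaced along each chromosome.
#'
#' @param spec a \code{sim_spec}.
#' @return data.frame with \code{id}, \code{chrom}, \code{bp}.
#' @export
sim_markers <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  out <- lapply(seq_len(nrow(spec$chromosomes)), function(i) {
    ch <- spec$chromosomes[i, ]
    m <- spec$n_markers_per_chrom
    bp <- round(seq_len(m) * ch$length_bp / (m + 1))
    data.frame(id = sprintf("m%s_%04d", ch$name, seq_len(m)),
               chrom = ch$name, bp = as.numeric(bp),
               stringsAsFactors = FALSE)
  })
  check_markers(do.call(rbind, out))
}
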