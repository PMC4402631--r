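#' Simulate pairwise IBD segments
#'
#' For every unordered sample pair the number of shared segments is
#' Poisson with mean \code{base_share_rate} times the genome length in
#' Morgans. Segment midpoints are uniform in genetic distance, lengths are
#' i.i.d. Pareto(shape, scale) in cM, and physical coordinates follow from
#' each chromosome's uniform cM/Mb rate with truncation at the chromosome
#' ends. Optional features: telomeric depletion (segments whose midpoint
#' falls within \code{telomere_width_cm} of a chromosome end are dropped
#' with probability 1 - \code{telomere_retention}) and a planted risk
#' locus (case-case segments spanning it are replicated so their expected
#' mass is multiplied by \code{enrichment}, leaving the marginal length
#' distribution unchanged). Each segment carries haplotype indices and a
#' LOD score (3 + Exp(mean 2), or Uniform(0, 3) for a
#' \code{lod_low_frac} fraction).
#'
#' @param spec a \code{\link{sim_spec}}.
#' @param phenotypes named character vector (sample id -> "case"/"control");
#'   defaults to \code{\link{sim_phenotypes}(spec)}.
#' @return list with \code{segments} (data.frame: sample1, hap1, sample2,
#'   hap2, chrom, start_bp, end_bp, lod, in canonical pair order) and
#'   \code{truth} (planted locus, pair totals, number of enrichment
#'   copies).
#' @export
simulate_ibd_segments <- function(spec, phenotypes = sim_phenotypes(spec)) {
  stopifnot(inherits(spec, "sim_spec"))
  phenotypes <- check_phenotypes(phenotypes, allow_unknown = FALSE)
  ids <- names(phenotypes)
  n <- length(ids)
  if (n < 2) stop2("need at least two samples")
  chroms <- spec$chromosomes
  len_cm <- chroms$length_bp * chroms$cm_per_mb / 1e6
  genome_morgans <- sum(len_cm) / 100

  set.seed(spec$seed)
  # unordered pairs, ids in canonical order by construction
  pr <- utils::combn(n, 2)
  n_pairs <- ncol(pr)
  counts <- stats::rpois(n_pairs, spec$base_share_rate * genome_morgans)
  total <- sum(counts)
  pair_of <- rep.int(seq_len(n_pairs), counts)

  chrom_i <- sample.int(nrow(chroms), total, replace = TRUE,
                        prob = len_cm)
  mid_cm <- stats::runif(total) * len_cm[chrom_i]
  length_cm <- rpareto(total, spec$pareto_shape, spec$pareto_scale)
  start_cm <- pmax(0, mid_cm - length_cm / 2)
  end_cm <- pmin(len_cm[chrom_i], mid_cm + length_cm / 2)

  # telomeric detection depletion on the segment midpoint
  if (spec$telomere_retention < 1 && spec$telomere_width_cm > 0) {
    near_end <- mid_cm < spec$telomere_width_cm |
      mid_cm > len_cm[chrom_i] - spec$telomere_width_cm
    keep <- !near_end | stats::runif(total) < spec$telomere_retention
  } else keep <- rep(TRUE, total)

  hap1 <- sample(1:2, total, replace = TRUE)
  hap2 <- sample(1:2, total, replace = TRUE)
  lod <- 3 + stats::rexp(total, rate = 0.5)
  if (spec$lod_low_frac > 0) {
    low <- stats::runif(total) < spec$lod_low_frac
    lod[low] <- stats::runif(total, 0, 3)[low]
  }

  seg <- data.frame(sample1 = ids[pr[1, pair_of]],
                    hap1 = hap1,
                    sample2 = ids[pr[2, pair_of]],
                    hap2 = hap2,
                    chrom = chroms$name[chrom_i],
                    start_cm = start_cm, end_cm = end_cm,
                    lod = lod,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]

  n_enriched <- 0L
  if (!is.null(spec$planted_locus) && spec$enrichment > 1) {
    i <- match(spec$planted_locus$chrom, chroms$name)
    locus_cm <- spec$planted_locus$bp * chroms$cm_per_mb[i] / 1e6
    is_cc <- phenotypes[seg$sample1] == "case" &
      phenotypes[seg$sample2] == "case"
    covers <- seg$chrom == chroms$name[i] &
      seg$start_cm <= locus_cm & seg$end_cm >= locus_cm
    hit <- which(is_cc & covers)
    if (length(hit)) {
      extra <- spec$enrichment - 1
      n_copies <- rep.int(floor(extra), length(hit)) +
        (stats::runif(length(hit)) < extra - floor(extra))
      dup <- rep.int(hit, n_copies)
      n_enriched <- length(dup)
      if (n_enriched > 0) {
        copies <- seg[dup, , drop = FALSE]
        copies$lod <- 3 + stats::rexp(n_enriched, rate = 0.5)
        seg <- rbind(seg, copies)
      }
    }
  }

  # physical coordinates from the chromosome's uniform rate, 1-based
  rate <- chroms$cm_per_mb[match(seg$chrom, chroms$name)]
  len_bp <- chroms$length_bp[match(seg$chrom, chroms$name)]
  seg$start_bp <- pmax(1, pmin(round(seg$start_cm / rate * 1e6), len_bp - 1))
  seg$end_bp <- pmax(seg$start_bp + 1,
                     pmin(round(seg$end_cm / rate * 1e6), len_bp))
  rownames(seg) <- NULL
  seg <- canonicalise_pairs(seg)
  seg <- seg[, c("sample1", "hap1", "sample2", "hap2", "chrom",
                 "start_bp", "end_bp", "lod")]

  cls <- pair_class(phenotypes[seg$sample1], phenotypes[seg$sample2])
  list(segments = seg,
       truth = list(planted_locus = spec$planted_locus,
                    enrichment = spec$enrichment,
                    n_enriched_copies = n_enriched,
                    n_segments = stats::setNames(
                      as.integer(table(factor(cls, c("cc", "cn", "nn")))),
                      c("cc", "cn", "nn"))))
}

# pair class codes: cc (case-case), cn (case-control), nn (control-control)
pair_class <- function(ph1, ph2) {
  ncase <- (ph1 == "case") + (ph2 == "case")
  c("nn", "cn", "cc")[ncase + 1L]
}
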