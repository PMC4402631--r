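#' Segment filter parameters
#'
#' IBD segments are screened before mapping: the defaults keep segments
#' with LOD >= 3 and genetic length >= 1 cM. Under the default
#' \code{rule = "either"} a segment failing either criterion is excluded;
#' \code{rule = "both"} excludes only segments failing both.
#'
#' @param lod_min minimum LOD score.
#' @param length_min_cm minimum genetic length in cM.
#' @param rule exclusion rule, \code{"either"} (default) or \code{"both"}.
#' @return an object of class \code{segment_filter_params}.
#' @export
segment_filter_params <- function(lod_min = 3, length_min_cm = 1.0,
                                  rule = c("either", "both")) {
  rule <- match.arg(rule)
  stopifnot(lod_min >= 0, length_min_cm >= 0)
  structure(list(lod_min = lod_min, length_min_cm = length_min_cm,
                 rule = rule),
            class = "segment_filter_params")
}

#' Filter IBD segments on LOD and genetic length
#'
#' @param segments annotated segment data.frame (must carry
#'   \code{length_cm}; see \code{\link{annotate_segments}}).
#' @param params a \code{\link{segment_filter_params}}.
#' @return list with \code{segments} (kept rows) and \code{report}
#'   (exclusion counts: \code{n_lod}, \code{n_length}, \code{n_excluded},
#'   \code{n_kept}).
#' @export
filter_segments <- function(segments, params = segment_filter_params()) {
  stopifnot(inherits(params, "segment_filter_params"))
  if (is.null(segments$length_cm) || anyNA(segments$length_cm))
    stop2("segments must be annotated with length_cm before filtering")
  fail_lod <- segments$lod < params$lod_min
  fail_len <- segments$length_cm < params$length_min_cm
  drop <- if (params$rule == "either") fail_lod | fail_len
          else fail_lod & fail_len
  list(segments = segments[!drop, , drop = FALSE],
       report = list(n_lod = sum(fail_lod), n_length = sum(fail_len),
                     n_excluded = sum(drop), n_kept = sum(!drop)))
}

# Internal: map segments onto marker-index ranges (global indices into the
# marker table). Returns first/last (1-based, first > last when a segment
# spans no marker) for each segment.
segment_marker_ranges <- function(segments, markers) {
  markers <- check_markers(markers)
  first <- integer(nrow(segments)); last <- integer(nrow(segments))
  for (ch in unique(segments$chrom)) {
    mi <- which(markers$chrom == ch)
    i <- which(segments$chrom == ch)
    if (length(mi) == 0L) { first[i] <- 1L; last[i] <- 0L; next }
    bp <- markers$bp[mi]
    off <- mi[1] - 1L
    first[i] <- off + findInterval(segments$start_bp[i] - 1, bp) + 1L
    last[i] <- off + findInterval(segments$end_bp[i], bp)
  }
  list(first = first, last = last)
}

# Internal: per-marker spanning counts for segments selected by `mask`,
# via difference arrays over the precomputed index ranges.
range_counts <- function(first, last, n_markers, mask = NULL) {
  if (!is.null(mask)) { first <- first[mask]; last <- last[mask] }
  ok <- first <= last
  cumsum(tabulate(first[ok], n_markers)) -
    cumsum(tabulate(last[ok] + 1L, n_markers))
}

#' Per-marker spanning counts by pair class
#'
#' A segment spans marker m when \code{start_bp <= bp(m) <= end_bp} on
#' the same chromosome. Counts are accumulated per marker into the pair
#' class of the two samples (case-case, case-control, control-control)
#' using a sorted sweep over segment endpoints. Multiple segments of the
#' same pair each count once per segment.
#'
#' @param segments segment data.frame (every sample must have a label).
#' @param markers marker table.
#' @param phenotypes named character vector or data.frame
#'   (\code{sample_id}, \code{status}); values case/control.
#' @return an object of class \code{sharing_profile}: per-marker integer
#'   vectors \code{count_cc}, \code{count_cn}, \code{count_nn},
#'   \code{coverage} (all pairs), pair totals \code{N_cc}, \code{N_cn},
#'   \code{N_nn}, and the \code{markers} table.
#' @export
spanning_counts <- function(segments, markers, phenotypes) {
  markers <- check_markers(markers)
  ph <- check_phenotypes(phenotypes, allow_unknown = FALSE)
  miss <- setdiff(unique(c(segments$sample1, segments$sample2)), names(ph))
  if (length(miss))
    stop2("segment sample(s) without a phenotype label: ",
          paste(utils::head(miss, 3), collapse = ", "))
  nm <- nrow(markers)
  rng <- segment_marker_ranges(segments, markers)
  cls <- pair_class(ph[segments$sample1], ph[segments$sample2])
  n_case <- sum(ph == "case"); n_ctrl <- sum(ph == "control")
  structure(list(
    count_cc = range_counts(rng$first, rng$last, nm, cls == "cc"),
    count_cn = range_counts(rng$first, rng$last, nm, cls == "cn"),
    count_nn = range_counts(rng$first, rng$last, nm, cls == "nn"),
    coverage = range_counts(rng$first, rng$last, nm),
    N_cc = choose(n_case, 2), N_cn = n_case * n_ctrl,
    N_nn = choose(n_ctrl, 2),
    n_cases = n_case, n_controls = n_ctrl,
    markers = markers), class = "sharing_profile")
}

#' @export
print.sharing_profile <- function(x, ...) {
  cat("Sharing profile:", nrow(x$markers), "markers;",
      x$n_cases, "cases /", x$n_controls, "controls\n")
  cat(sprintf("  mean spanning counts: cc %.2f, cn %.2f, nn %.2f\n",
              mean(x$count_cc), mean(x$count_cn), mean(x$count_nn)))
  invisible(x)
}

#' Genome-wide average case-case sharing rate
#'
#' The normaliser of the mapping statistic: the mean over markers of the
#' per-marker case-case sharing rate \code{count_cc(m) / N_cc}.
#'
#' @param profile a \code{\link{spanning_counts}} profile.
#' @return the genome-wide average rate (0 for an all-zero profile, in
#'   which case the statistic is undefined downstream).
#' @export
genomewide_average <- function(profile) {
  stopifnot(inherits(profile, "sharing_profile"))
  if (nrow(profile$markers) < 1) stop2("profile has no markers")
  if (profile$N_cc == 0) stop2("no case-case pairs (N_cc = 0)")
  mean(profile$count_cc / profile$N_cc)
}

#' Normalised case-case sharing statistic
#'
#' \eqn{s(m) = (count_{cc}(m)/N_{cc}) / \bar g}, the per-marker case-case
#' sharing rate relative to the genome-wide average \eqn{\bar g}. Scale
#' invariant: doubling all counts (and hence the average) leaves s
#' unchanged.
#'
#' @param profile a \code{\link{spanning_counts}} profile.
#' @param gw_avg the genome-wide average rate, normally
#'   \code{\link{genomewide_average}(profile)}.
#' @return numeric vector of per-marker statistics.
#' @export
mapping_statistic <- function(profile, gw_avg = genomewide_average(profile)) {
  stopifnot(inherits(profile, "sharing_profile"))
  if (gw_avg <= 0) stop2("genome-wide average sharing is zero; statistic undefined")
  (profile$count_cc / profile$N_cc) / gw_avg
}

#' Low-coverage marker mask from spanning counts
#'
#' Masks markers whose total spanning-segment count falls strictly below
#' the \code{fraction} quantile (linear interpolation between order
#' statistics) of the per-marker counts. With an all-equal count profile
#' nothing is masked.
#'
#' @param counts per-marker total spanning counts (all pairs).
#' @param fraction quantile level in (0, 1); default 0.10.
#' @return logical mask, TRUE = low coverage; attribute \code{q} holds
#'   the count threshold.
#' @export
low_coverage_mask <- function(counts, fraction = 0.10) {
  if (length(counts) == 0L) stop2("no markers")
  if (fraction <= 0 || fraction >= 1) stop2("fraction must be in (0, 1)")
  q <- unname(stats::quantile(counts, fraction, type = 7))
  structure(counts < q, q = q)
}

#' Low-IBD-coverage marker filter
#'
#' Flags markers lying in regions of generally low IBD detection: the
#' total number of kept segments spanning each marker (over all sample
#' pairs) is computed, and markers strictly below the \code{fraction}
#' quantile of that distribution are masked. Near chromosome ends IBD
#' detection is systematically lower and apparent case-case sharing
#' excess there is artefact-prone, which is what this filter removes.
#'
#' @param segments kept segment data.frame.
#' @param markers marker table.
#' @param fraction quantile level in (0, 1); default 0.10.
#' @return logical per-marker mask (TRUE = low coverage), with attributes
#'   \code{q} (count threshold) and \code{counts}.
#' @export
coverage_filter <- function(segments, markers, fraction = 0.10) {
  markers <- check_markers(markers)
  rng <- segment_marker_ranges(segments, markers)
  counts <- range_counts(rng$first, rng$last, nrow(markers))
  m <- low_coverage_mask(counts, fraction)
  attr(m, "counts") <- counts
  m
}

#' Mapping run parameters
#'
#' @param n_permutations number of case/control label permutations.
#'   The published analysis used five million; the default is desk-scale.
#' @param fwer_level genome-wide (family-wise) significance level.
#' @param coverage_fraction quantile level of the low-coverage filter.
#' @param seed integer seed for the permutation stream.
#' @param gw_rule how genome-wide significance is declared:
#'   \code{"max_stat"} (default) uses the permutation distribution of the
#'   genome-wide maximum statistic at level \code{fwer_level};
#'   \code{"p_quantile"} thresholds pointwise permutation p-values at
#'   their \code{fwer_level / 100} quantile (the literal percentile-of-
#'   p-values reading).
#' @return an object of class \code{mapping_params}.
#' @export
mapping_params <- function(n_permutations = 10000, fwer_level = 0.05,
                           coverage_fraction = 0.10, seed = 1L,
                           gw_rule = c("max_stat", "p_quantile")) {
  gw_rule <- match.arg(gw_rule)
  if (n_permutations < 1) stop2("n_permutations must be >= 1")
  stopifnot(fwer_level > 0, fwer_level < 1,
            coverage_fraction > 0, coverage_fraction < 1)
  structure(list(n_permutations = as.integer(n_permutations),
                 fwer_level = fwer_level,
                 coverage_fraction = coverage_fraction,
                 seed = as.integer(seed), gw_rule = gw_rule),
            class = "mapping_params")
}
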