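#' Fit an IBD case-control sharing map
#'
#' The core mapping procedure: per-marker case-case sharing statistics
#' normalised by the genome-wide average sharing, permutation-based
#' pointwise and genome-wide significance, and a low-IBD-coverage marker
#' mask.
#'
#' For the observed labels and for each of \code{n_permutations} random
#' relabelings of case/control status (preserving class sizes), the
#' per-marker case-case spanning count \eqn{c(m)} is computed and turned
#' into the statistic \eqn{s(m) = c(m) / \bar c}, each permutation
#' normalised by its own genome-wide average \eqn{\bar c}. The pointwise
#' p-value is the add-one estimator
#' \eqn{p(m) = (1 + \#\{s_{perm}(m) \ge s_{obs}(m)\}) / (B + 1)}.
#' Genome-wide significance follows the max-statistic (Westfall-Young)
#' construction: the genome-wide p-value of marker m compares
#' \eqn{s_{obs}(m)} with the permutation distribution of
#' \eqn{\max_m s_{perm}(m)}, and markers with genome-wide p at most
#' \code{fwer_level} are significant. All statistic comparisons are done
#' by integer cross-multiplication (count times total), so ties are exact.
#' The reported \code{significant} flag additionally requires a marker
#' not to be masked by the low-coverage filter; the raw permutation call
#' is kept in \code{gw_significant}.
#'
#' @param segments kept (filtered) IBD segment data.frame; pass
#'   \code{filter_params} to filter here instead.
#' @param phenotypes named character vector or data.frame
#'   (\code{sample_id}, \code{status}); at least two cases and two
#'   controls.
#' @param markers marker table (\code{id}, \code{chrom}, \code{bp}).
#' @param params a \code{\link{mapping_params}} object.
#' @param filter_params optional \code{\link{segment_filter_params}};
#'   when supplied, \code{\link{filter_segments}} is applied first (the
#'   segments must then carry \code{length_cm}).
#' @return an object of class \code{ibd_mapping}; see Details. The
#'   \code{results} data.frame has one row per marker with the spanning
#'   counts, statistic, pointwise and genome-wide p-values, low-coverage
#'   and significance flags.
#' @seealso \code{\link{significant_markers}},
#'   \code{\link{coverage_filter}}, \code{\link{spanning_counts}}
#' @export
ibd_map <- function(segments, phenotypes, markers,
                    params = mapping_params(), filter_params = NULL) {
  stopifnot(inherits(params, "mapping_params"))
  cl <- match.call()
  if (!is.null(filter_params)) {
    flt <- filter_segments(segments, filter_params)
    segments <- flt$segments
    filter_report <- flt$report
  } else filter_report <- NULL
  markers <- check_markers(markers)
  ph <- check_phenotypes(phenotypes, allow_unknown = FALSE)
  n_case <- sum(ph == "case"); n_ctrl <- sum(ph == "control")
  if (n_case < 2 || n_ctrl < 2)
    stop2("need at least 2 cases and 2 controls (got ", n_case, "/", n_ctrl,
          ")")
  nm <- nrow(markers)
  if (nm < 1) stop2("empty marker table")

  profile <- spanning_counts(segments, markers, ph)
  cnt_obs <- profile$count_cc
  S_obs <- sum(cnt_obs)
  if (S_obs == 0)
    stop2("no case-case segment spans any marker; statistic undefined")
  gw_avg <- genomewide_average(profile)
  s_obs <- mapping_statistic(profile, gw_avg)

  # precompute marker ranges and sample indices once for the permutations
  rng <- segment_marker_ranges(segments, markers)
  span <- rng$first <= rng$last
  first <- rng$first[span]; last <- rng$last[span]
  sample_ids <- names(ph)
  s1 <- match(segments$sample1, sample_ids)[span]
  s2 <- match(segments$sample2, sample_ids)[span]
  is_case <- ph == "case"

  B <- params$n_permutations
  set.seed(params$seed)
  ge_point <- integer(nm)   # permutations with s_perm(m) >= s_obs(m)
  ge_max <- integer(nm)     # permutations with max-stat >= s_obs(m)
  max_cnt <- numeric(B); S_perm_v <- numeric(B)
  for (b in seq_len(B)) {
    perm <- sample(is_case)
    cc <- perm[s1] & perm[s2]
    cnt <- range_counts(first, last, nm, cc)
    S_perm <- sum(cnt)
    # s_perm(m) >= s_obs(m)  <=>  cnt(m) * S_obs >= cnt_obs(m) * S_perm
    ge_point <- ge_point + (cnt * S_obs >= cnt_obs * S_perm)
    mx <- max(cnt)
    ge_max <- ge_max + (mx * S_obs >= cnt_obs * S_perm)
    max_cnt[b] <- mx; S_perm_v[b] <- S_perm
  }
  p_point <- (1 + ge_point) / (B + 1)
  p_gw <- (1 + ge_max) / (B + 1)

  low_cov <- low_coverage_mask(profile$coverage, params$coverage_fraction)
  if (params$gw_rule == "max_stat") {
    gw_sig <- p_gw <= params$fwer_level
    # statistic-scale threshold: the k-th largest permutation max-statistic
    k <- floor(params$fwer_level * (B + 1))
    s_threshold <- if (k >= 1) {
      mstat <- ifelse(S_perm_v > 0, max_cnt / (S_perm_v / nm), Inf)
      sort(mstat, decreasing = TRUE)[min(k, B)]
    } else Inf
    p_threshold <- if (k >= 1) k / (B + 1) else 0
  } else {
    p_threshold <- unname(stats::quantile(p_point, params$fwer_level / 100,
                                          type = 7))
    gw_sig <- p_point <= p_threshold
    s_threshold <- NA_real_
  }
  significant <- gw_sig & !low_cov

  results <- data.frame(
    id = markers$id, chrom = markers$chrom, bp = markers$bp,
    count_cc = as.integer(profile$count_cc),
    count_cn = as.integer(profile$count_cn),
    count_nn = as.integer(profile$count_nn),
    coverage = as.integer(profile$coverage),
    statistic = s_obs, p_point = p_point, p_gw = p_gw,
    low_coverage = as.logical(low_cov),
    gw_significant = gw_sig, significant = significant,
    stringsAsFactors = FALSE, row.names = NULL)

  structure(list(results = results, profile = profile,
                 gw_avg = gw_avg,
                 s_threshold = s_threshold, p_threshold = p_threshold,
                 coverage_q = attr(low_cov, "q"),
                 n_permutations = B, fwer_level = params$fwer_level,
                 coverage_fraction = params$coverage_fraction,
                 gw_rule = params$gw_rule, seed = params$seed,
                 n_cases = n_case, n_controls = n_ctrl,
                 n_segments = nrow(segments),
                 filter_report = filter_report,
                 call = cl),
            class = "ibd_mapping")
}

#' @rdname ibd_map
#' @export
permutation_mapping <- ibd_map

#' Genome-wide significant, coverage-passing markers
#'
#' The reported hit set: markers declared genome-wide significant by the
#' permutation procedure and not masked by the low-coverage filter.
#'
#' @param result an \code{\link{ibd_map}} fit.
#' @return data.frame (possibly empty) with chrom, bp, id, statistic and
#'   p-values of the reported markers.
#' @export
significant_markers <- function(result) {
  stopifnot(inherits(result, "ibd_mapping"))
  r <- result$results
  r[r$significant, c("chrom", "bp", "id", "count_cc", "statistic",
                     "p_point", "p_gw"), drop = FALSE]
}

#' @export
print.ibd_mapping <- function(x, ...) {
  cat("IBD case-control sharing map\n")
  cat(sprintf("  %d markers, %d segments, %d cases / %d controls\n",
              nrow(x$results), x$n_segments, x$n_cases, x$n_controls))
  cat(sprintf("  %d permutations, FWER level %.3g (%s rule)\n",
              x$n_permutations, x$fwer_level, x$gw_rule))
  cat(sprintf("  genome-wide average case-case sharing rate: %.4g\n",
              x$gw_avg))
  cat(sprintf("  low-coverage mask: %d markers (< %.4g spanning segments)\n",
              sum(x$results$low_coverage), x$coverage_q))
  hits <- significant_markers(x)
  if (nrow(hits)) {
    cat("  significant markers (after coverage filter):\n")
    print(hits, row.names = FALSE)
  } else cat("  no genome-wide significant marker survives the filters\n")
  invisible(x)
}

#' @export
summary.ibd_mapping <- function(object, n_top = 5, ...) {
  r <- object$results
  top <- r[order(-r$statistic), ][seq_len(min(n_top, nrow(r))), ]
  out <- list(n_markers = nrow(r), n_segments = object$n_segments,
              gw_avg = object$gw_avg,
              s_threshold = object$s_threshold,
              n_low_coverage = sum(r$low_coverage),
              n_gw_significant = sum(r$gw_significant),
              n_significant = sum(r$significant),
              top_markers = top[, c("chrom", "bp", "id", "statistic",
                                    "p_point", "p_gw", "low_coverage",
                                    "significant")])
  class(out) <- "summary.ibd_mapping"
  out
}

#' @export
print.summary.ibd_mapping <- function(x, ...) {
  cat("IBD mapping summary:", x$n_markers, "markers,",
      x$n_segments, "segments\n")
  cat(sprintf("  genome-wide average rate %.4g; statistic threshold %.3f\n",
              x$gw_avg, x$s_threshold))
  cat(sprintf("  %d low-coverage, %d genome-wide significant, %d reported\n",
              x$n_low_coverage, x$n_gw_significant, x$n_significant))
  cat("  top markers by statistic:\n")
  print(x$top_markers, row.names = FALSE)
  invisible(x)
}

#' Plot an IBD sharing map
#'
#' Per-chromosome track of the normalised case-case sharing statistic
#' with the genome-wide significance threshold (dashed) and low-coverage
#' markers greyed out; significant markers are highlighted.
#'
#' @param x an \code{\link{ibd_map}} fit.
#' @param ... passed to \code{plot.default}.
#' @return the fit, invisibly.
#' @export
plot.ibd_mapping <- function(x, ...) {
  r <- x$results
  chroms <- unique(r$chrom)
  offs <- c(0, cumsum(tapply(r$bp, factor(r$chrom, chroms), max)))
  pos <- r$bp + offs[match(r$chrom, chroms)]
  col <- ifelse(r$low_coverage, "grey70",
                ifelse(match(r$chrom, chroms) %% 2 == 1, "steelblue4",
                       "steelblue2"))
  graphics::plot(pos, r$statistic, col = col, pch = 16, cex = 0.5,
                 xlab = "genome position (bp, chromosomes concatenated)",
                 ylab = "normalised case-case sharing s(m)", ...)
  if (is.finite(x$s_threshold))
    graphics::abline(h = x$s_threshold, lty = 2, col = "red3")
  sig <- r$significant
  if (any(sig))
    graphics::points(pos[sig], r$statistic[sig], col = "red3", pch = 16,
                     cex = 0.9)
  invisible(x)
}
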