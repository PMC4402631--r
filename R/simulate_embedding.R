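#' Simulate a PC embedding with planted outliers
#'
#' Core samples form a spherical Gaussian cloud of scale
#' \code{core_scale} around the origin; outliers are placed at distance
#' \code{outlier_offset} from the origin in uniformly random directions.
#' With the default geometry (offset 10x the core scale) the planted
#' outliers are unambiguous under the two-stage nearest-neighbour removal.
#'
#' @param n_core number of core samples (at least 11, so a 10-NN
#'   neighbourhood is defined).
#' @param n_outliers number of planted outliers.
#' @param dims embedding dimensionality (default 6, matching the analysis
#'   default).
#' @param core_scale standard deviation of the core cloud per coordinate.
#' @param outlier_offset distance of the planted outliers from the origin;
#'   must be positive.
#' @param seed integer seed.
#' @return list with \code{embedding} (a \code{pc_embedding}) and
#'   \code{truth} (character vector, \code{"core"}/\code{"outlier"} per
#'   sample, named by sample id).
#' @export
simulate_embedding <- function(n_core, n_outliers = 0, dims = 6,
                               core_scale = 0.03, outlier_offset = 0.3,
                               seed = 1L) {
  stopifnot(dims >= 1, n_outliers >= 0, core_scale > 0)
  if (n_core < 11) stop2("n_core must be >= 11 (10-NN undefined otherwise)")
  if (outlier_offset <= 0) stop2("outlier_offset must be > 0")
  set.seed(as.integer(seed))
  core <- matrix(stats::rnorm(n_core * dims, sd = core_scale),
                 nrow = n_core)
  out <- matrix(0, n_outliers, dims)
  if (n_outliers > 0) {
    dir <- matrix(stats::rnorm(n_outliers * dims), nrow = n_outliers)
    dir <- dir / sqrt(rowSums(dir^2))
    out <- dir * outlier_offset
  }
  ids <- c(sprintf("core_%04d", seq_len(n_core)),
           if (n_outliers > 0) sprintf("out_%04d", seq_len(n_outliers)))
  truth <- stats::setNames(rep(c("core", "outlier"), c(n_core, n_outliers)),
                           ids)
  list(embedding = pc_embedding(rbind(core, out), ids), truth = truth)
}
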