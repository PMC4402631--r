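#' Parameters for two-stage nearest-neighbour outlier removal
#'
#' Defaults follow the published procedure: the first six PCs, average
#' distance to the 10 nearest neighbours, density cutoff 0.15, and the
#' requirement that 9 of 10 nearest neighbours lie inside the dense
#' cluster. The 0.15 cutoff is on the scale of unit-norm eigenvector
#' coordinates (see \code{\link{compute_pcs}}); it is not scale-free.
#'
#' @param n_neighbors number of nearest neighbours (k).
#' @param density_cutoff stage-1 threshold on the mean k-NN distance.
#' @param interior_min stage-2 minimum number of the k nearest neighbours
#'   that must be stage-1 members; must be <= \code{n_neighbors}.
#' @param n_pcs embedding dimensionality the parameters presume.
#' @param stage2_neighbors whether stage-2 neighbours are looked up in the
#'   full sample set (default) or recomputed among stage-1 survivors.
#' @return an object of class \code{outlier_params}.
#' @export
outlier_params <- function(n_neighbors = 10, density_cutoff = 0.15,
                           interior_min = 9, n_pcs = 6,
                           stage2_neighbors = c("all", "stage1")) {
  stage2_neighbors <- match.arg(stage2_neighbors)
  if (interior_min > n_neighbors)
    stop2("interior_min must be <= n_neighbors")
  stopifnot(n_neighbors >= 1, density_cutoff >= 0, n_pcs >= 1)
  structure(list(n_neighbors = n_neighbors, density_cutoff = density_cutoff,
                 interior_min = interior_min, n_pcs = n_pcs,
                 stage2_neighbors = stage2_neighbors),
            class = "outlier_params")
}

# k nearest neighbour indices per sample (excluding self), ties broken by
# sample order (stable). Returns an n x k integer matrix.
knn_indices <- function(coords, k) {
  n <- nrow(coords)
  if (n < k + 1) stop2("need at least k + 1 = ", k + 1, " samples")
  D <- as.matrix(stats::dist(coords))
  diag(D) <- Inf
  t(apply(D, 1, function(d) order(d)[seq_len(k)]))
}

#' Mean distance to the k nearest neighbours
#'
#' For each sample, the mean Euclidean distance to its k nearest other
#' samples in PC space — a local density measure. Ties in neighbour rank
#' are broken by sample order.
#'
#' @param embedding a \code{pc_embedding} (or bare coordinate matrix).
#' @param k neighbourhood size.
#' @return named numeric vector of per-sample mean k-NN distances.
#' @export
mean_knn_distance <- function(embedding, k = 10) {
  coords <- if (inherits(embedding, "pc_embedding")) embedding$coords
            else as.matrix(embedding)
  n <- nrow(coords)
  if (n < k + 1) stop2("need at least k + 1 = ", k + 1, " samples")
  D <- as.matrix(stats::dist(coords))
  diag(D) <- Inf
  out <- apply(D, 1, function(d) mean(sort(d, partial = seq_len(k))[seq_len(k)]))
  names(out) <- rownames(coords)
  out
}

#' Two-stage nearest-neighbour outlier removal in PC space
#'
#' Stage 1 keeps samples whose mean distance to their k nearest neighbours
#' is at most \code{density_cutoff} — a local-density definition of the
#' main cluster(s). Stage 2 keeps a stage-1 sample only if at least
#' \code{interior_min} of its k nearest neighbours are themselves stage-1
#' members, trimming samples near the cluster boundary. A single pass of
#' both stages is run.
#'
#' @param embedding a \code{pc_embedding}.
#' @param params an \code{outlier_params} object; the embedding must have
#'   \code{params$n_pcs} columns.
#' @return an object of class \code{outlier_result}: \code{kept} (sample
#'   ids surviving both stages), \code{diagnostics} (per-sample data.frame
#'   with mean k-NN distance, stage-1 membership, interior-neighbour count,
#'   stage-2 membership) and \code{params}.
#' @export
two_stage_outlier_removal <- function(embedding, params = outlier_params()) {
  stopifnot(inherits(embedding, "pc_embedding"),
            inherits(params, "outlier_params"))
  coords <- embedding$coords
  if (ncol(coords) != params$n_pcs)
    stop2("embedding has ", ncol(coords), " PCs but params expect ",
          params$n_pcs)
  k <- params$n_neighbors
  mkd <- mean_knn_distance(embedding, k)
  stage1 <- mkd <= params$density_cutoff

  nn <- if (params$stage2_neighbors == "all") {
    knn_indices(coords, k)
  } else {
    if (sum(stage1) < k + 1)
      stop2("fewer than k + 1 stage-1 survivors; cannot recompute neighbours")
    idx1 <- which(stage1)
    sub <- knn_indices(coords[idx1, , drop = FALSE], k)
    matrix(idx1[sub], nrow = nrow(sub))[match(seq_len(nrow(coords)), idx1), ,
                                        drop = FALSE]
  }
  n_interior <- vapply(seq_len(nrow(coords)), function(i) {
    if (params$stage2_neighbors == "stage1" && !stage1[i]) return(NA_integer_)
    sum(stage1[nn[i, ]])
  }, integer(1))
  stage2 <- stage1 & !is.na(n_interior) & n_interior >= params$interior_min

  diagnostics <- data.frame(sample_id = embedding$sample_ids,
                            mean_knn = unname(mkd),
                            stage1 = unname(stage1),
                            n_interior = n_interior,
                            stage2 = unname(stage2),
                            stringsAsFactors = FALSE)
  structure(list(kept = embedding$sample_ids[stage2],
                 diagnostics = diagnostics,
                 params = params),
            class = "outlier_result")
}

#' @export
print.outlier_result <- function(x, ...) {
  d <- x$diagnostics
  cat("Two-stage PC-space outlier removal:\n")
  cat("  samples:", nrow(d),
      " stage 1 kept:", sum(d$stage1),
      " stage 2 kept:", length(x$kept), "\n")
  cat(sprintf("  removed: %d (%.1f%%)\n", nrow(d) - length(x$kept),
              100 * (nrow(d) - length(x$kept)) / nrow(d)))
  invisible(x)
}
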