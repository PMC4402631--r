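#' Construct a principal-component embedding
#'
#' @param coords numeric matrix, samples in rows, PC coordinates in columns.
#' @param sample_ids character vector, one id per row.
#' @return an object of class \code{pc_embedding}.
#' @export
pc_embedding <- function(coords, sample_ids) {
  coords <- as.matrix(coords)
  if (nrow(coords) != length(sample_ids))
    stop2("coords rows must match sample ids")
  if (anyDuplicated(sample_ids)) stop2("duplicate sample ids")
  rownames(coords) <- sample_ids
  colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  structure(list(sample_ids = as.character(sample_ids), coords = coords),
            class = "pc_embedding")
}

#' @export
print.pc_embedding <- function(x, ...) {
  cat("PC embedding:", nrow(x$coords), "samples,",
      ncol(x$coords), "components\n")
  invisible(x)
}

#' Genotype principal components
#'
#' Computes sample principal components of a genotype panel using the
#' standard genotype normalisation: each marker is centred at twice its
#' allele frequency estimate and scaled by \eqn{\sqrt{\hat p(1-\hat p)}};
#' missing calls are mean-imputed (zero after centring). Coordinates are
#' the unit-norm sample eigenvectors of the resulting covariance, the same
#' scaling convention as smartPCA output, with the sign fixed so the
#' largest-magnitude entry of each component is positive.
#'
#' @param panel a \code{genotype_panel} (normally post-QC).
#' @param n_components number of components, at most
#'   \code{min(samples, markers)}.
#' @return a \code{pc_embedding}; attribute \code{zero_variance} is TRUE
#'   when the panel had no marker variance (all coordinates zero).
#' @export
compute_pcs <- function(panel, n_components = 6) {
  stopifnot(inherits(panel, "genotype_panel"))
  n <- length(panel$sample_ids)
  m <- nrow(panel$markers)
  if (n_components < 1 || n_components > min(n, m))
    stop2("n_components must be in 1..min(samples, markers)")
  X <- panel$calls
  phat <- colMeans(X, na.rm = TRUE) / 2
  phat[is.nan(phat)] <- 0
  sd_ <- sqrt(phat * (1 - phat))
  W <- sweep(X, 2, 2 * phat, "-")
  W <- sweep(W, 2, ifelse(sd_ > 0, sd_, 1), "/")
  W[is.na(W) | !is.finite(W)] <- 0
  W[, sd_ == 0] <- 0
  if (all(W == 0)) {
    emb <- pc_embedding(matrix(0, n, n_components), panel$sample_ids)
    attr(emb, "zero_variance") <- TRUE
    return(emb)
  }
  sv <- svd(W, nu = n_components, nv = 0)
  U <- sv$u
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  emb <- pc_embedding(U, panel$sample_ids)
  attr(emb, "zero_variance") <- FALSE
  emb
}
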