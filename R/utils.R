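`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
stop2 <- function(...) stop(..., call. = FALSE)

# Put an unordered sample pair into canonical (sorted id) order, carrying the
# haplotype indices along with their samples.
canonicalise_pairs <- function(df) {
  swap <- df$sample1 > df$sample2
  if (any(swap)) {
    s1 <- df$sample1[swap]; h1 <- df$hap1[swap]
    df$sample1[swap] <- df$sample2[swap]
    df$hap1[swap] <- df$hap2[swap]
    df$sample2[swap] <- s1
    df$hap2[swap] <- h1
  }
  df
}

# Validate a phenotype vector: named character, values case/control (optionally
# unknown). Returns it normalised to a named character vector.
check_phenotypes <- function(phenotypes, allow_unknown = TRUE) {
  if (is.data.frame(phenotypes)) {
    stopifnot(all(c("sample_id", "status") %in% names(phenotypes)))
    phenotypes <- stats::setNames(as.character(phenotypes$status),
                                  as.character(phenotypes$sample_id))
  }
  ph <- as.character(phenotypes)
  names(ph) <- names(phenotypes)
  if (is.null(names(ph)) || anyNA(names(ph)) || any(names(ph) == ""))
    stop2("phenotypes must be named by sample id")
  ok <- c("case", "control", if (allow_unknown) "unknown")
  if (!all(ph %in% ok))
    stop2("phenotype values must be one of: ", paste(ok, collapse = ", "))
  ph
}

# Validate a marker table: data.frame with id, chrom, bp; bp strictly
# increasing within chromosome. Returns with chrom as character.
check_markers <- function(markers) {
  stopifnot(is.data.frame(markers),
            all(c("id", "chrom", "bp") %in% names(markers)))
  markers$chrom <- as.character(markers$chrom)
  markers$id <- as.character(markers$id)
  for (ch in unique(markers$chrom)) {
    bp <- markers$bp[markers$chrom == ch]
    if (any(diff(bp) <= 0))
      stop2("marker bp must be strictly increasing within chromosome ", ch)
  }
  markers
}

# Draw from a Pareto distribution by inverse-CDF.

#' Pareto random deviates
#'
#' Draws from the Pareto distribution with density
#' \eqn{f(x) = \alpha x_m^\alpha / x^{\alpha+1}} for \eqn{x \ge x_m},
#' used for IBD segment lengths in centiMorgans. The mean is
#' \eqn{\alpha x_m / (\alpha - 1)} for \eqn{\alpha > 1}.
#'
#' @param n number of draws.
#' @param shape tail index \eqn{\alpha > 0}.
#' @param scale minimum value \eqn{x_m > 0}.
#' @return numeric vector of length \code{n}.
#' @examples
#' set.seed(1)
#' mean(rpareto(1e4, 2.5, 0.65))  # close to 2.5 * 0.65 / 1.5
#' @export
rpareto <- function(n, shape, scale) {
  stopifnot(shape > 0, scale > 0)
  scale * stats::runif(n)^(-1 / shape)
}
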