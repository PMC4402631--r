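#' Construct a genetic map
#'
#' A genetic map is a set of per-chromosome anchor lists (physical
#' position in bp, map position in cM) used for linear interpolation of
#' centiMorgan coordinates.
#'
#' @param anchors data.frame with columns \code{chrom}, \code{bp},
#'   \code{cm}; within each chromosome \code{bp} must be strictly
#'   increasing and \code{cm} non-decreasing.
#' @return an object of class \code{genetic_map} (a named list of anchor
#'   data.frames, one per chromosome).
#' @export
genetic_map <- function(anchors) {
  stopifnot(is.data.frame(anchors),
            all(c("chrom", "bp", "cm") %in% names(anchors)))
  anchors$chrom <- as.character(anchors$chrom)
  out <- lapply(split(anchors[c("bp", "cm")], anchors$chrom), function(a) {
    a <- a[order(a$bp), , drop = FALSE]
    if (any(diff(a$bp) <= 0)) stop2("map bp must be strictly increasing")
    if (any(diff(a$cm) < 0)) stop2("map cM must be non-decreasing")
    rownames(a) <- NULL
    a
  })
  structure(out, class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("Genetic map:", length(x), "chromosomes;",
      sum(vapply(x, nrow, integer(1))), "anchors\n")
  invisible(x)
}

#' Read / write a genetic map
#'
#' Tab-separated text with a header line and columns \code{chrom},
#' \code{bp}, \code{cm}.
#'
#' @param path file path.
#' @return \code{read_genetic_map}: a \code{genetic_map};
#'   \code{write_genetic_map}: the path, invisibly.
#' @export
read_genetic_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "numeric", "numeric"),
                          col.names = c("chrom", "bp", "cm"))
  genetic_map(df)
}

#' @rdname read_genetic_map
#' @param map a \code{genetic_map}.
#' @export
write_genetic_map <- function(map, path) {
  stopifnot(inherits(map, "genetic_map"))
  df <- do.call(rbind, lapply(names(map), function(ch)
    data.frame(chrom = ch, bp = map[[ch]]$bp, cm = map[[ch]]$cm,
               stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Genetic map implied by a simulation spec
#'
#' Two anchors per chromosome (start and end) encoding the uniform
#' cM/Mb rate of the simulated genome.
#'
#' @param spec a \code{\link{sim_spec}}.
#' @return a \code{genetic_map}.
#' @export
sim_genetic_map <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  genetic_map(data.frame(
    chrom = rep(spec$chromosomes$name, each = 2),
    bp = as.vector(rbind(0, spec$chromosomes$length_bp)),
    cm = as.vector(rbind(0, spec$chromosomes$length_bp *
                           spec$chromosomes$cm_per_mb / 1e6)),
    stringsAsFactors = FALSE))
}

#' Interpolate centiMorgan positions
#'
#' Linear interpolation between the bracketing map anchors; beyond the
#' terminal anchors, linear extrapolation at the terminal interval's rate,
#' floored at 0 cM. Exact at anchors and monotone non-decreasing in bp.
#'
#' @param bp physical position(s), 1-based; vectorised.
#' @param map a \code{genetic_map}.
#' @param chrom chromosome name (single value).
#' @return numeric vector of cM positions.
#' @export
interpolate_cm <- function(bp, map, chrom) {
  stopifnot(inherits(map, "genetic_map"))
  chrom <- as.character(chrom)
  a <- map[[chrom]]
  if (is.null(a)) stop2("chromosome ", chrom, " absent from the genetic map")
  if (nrow(a) < 2) stop2("need >= 2 anchors for chromosome ", chrom)
  k <- nrow(a)
  # bracketing interval index, clamped so terminal intervals extrapolate
  i <- pmin(pmax(findInterval(bp, a$bp), 1L), k - 1L)
  slope <- (a$cm[i + 1] - a$cm[i]) / (a$bp[i + 1] - a$bp[i])
  pmax(0, a$cm[i] + (bp - a$bp[i]) * slope)
}

#' Annotate IBD segments with genetic-map coordinates
#'
#' Fills \code{start_cm}, \code{end_cm} and \code{length_cm} for each
#' segment by map interpolation.
#'
#' @param segments IBD segment data.frame (see
#'   \code{\link{read_refined_ibd}}).
#' @param map a \code{genetic_map} covering every segment chromosome.
#' @return the segment data.frame with \code{start_cm}, \code{end_cm},
#'   \code{length_cm} columns added; \code{length_cm >= 0} by map
#'   monotonicity.
#' @export
annotate_segments <- function(segments, map) {
  stopifnot(is.data.frame(segments), inherits(map, "genetic_map"))
  segments$start_cm <- NA_real_
  segments$end_cm <- NA_real_
  for (ch in unique(segments$chrom)) {
    i <- segments$chrom == ch
    segments$start_cm[i] <- interpolate_cm(segments$start_bp[i], map, ch)
    segments$end_cm[i] <- interpolate_cm(segments$end_bp[i], map, ch)
  }
  segments$length_cm <- segments$end_cm - segments$start_cm
  segments
}
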