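#' Read refined-IBD segment text
#'
#' Parses tab-separated refined-IBD output with columns sample1, hap1,
#' sample2, hap2, chromosome, start (bp), end (bp), LOD. Sample pairs are
#' stored in canonical (sorted) order, swapping haplotype indices along
#' with their samples. Malformed lines raise an error naming the line.
#'
#' @param path file path (or connection) to the segment text; no header.
#' @return data.frame with columns \code{sample1}, \code{hap1},
#'   \code{sample2}, \code{hap2}, \code{chrom}, \code{start_bp},
#'   \code{end_bp}, \code{lod} and attribute \code{line} giving each
#'   record's source line number.
#' @export
read_refined_ibd <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    out <- data.frame(sample1 = character(0), hap1 = integer(0),
                      sample2 = character(0), hap2 = integer(0),
                      chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), lod = numeric(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 8L))
    stop2("line ", which(nf != 8L)[1], ": expected 8 tab-separated fields, got ",
          nf[nf != 8L][1])
  m <- matrix(unlist(fields), ncol = 8, byrow = TRUE)
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v))
      stop2("line ", which(is.na(v))[1], ": non-numeric ", what)
    v
  }
  hap1 <- num(2, "hap1"); hap2 <- num(4, "hap2")
  if (!all(hap1 %in% c(1, 2)) || !all(hap2 %in% c(1, 2)))
    stop2("line ", which(!(hap1 %in% c(1, 2) & hap2 %in% c(1, 2)))[1],
          ": haplotype index must be 1 or 2")
  start_bp <- num(6, "start position")
  end_bp <- num(7, "end position")
  if (any(start_bp >= end_bp))
    stop2("line ", which(start_bp >= end_bp)[1],
          ": start position must be < end position")
  out <- data.frame(sample1 = m[, 1], hap1 = as.integer(hap1),
                    sample2 = m[, 3], hap2 = as.integer(hap2),
                    chrom = m[, 5], start_bp = start_bp, end_bp = end_bp,
                    lod = num(8, "LOD"),
                    stringsAsFactors = FALSE)
  out <- canonicalise_pairs(out)
  attr(out, "line") <- seq_len(nrow(out))
  out
}

#' Write refined-IBD segment text
#'
#' Inverse of \code{\link{read_refined_ibd}}: tab-separated, no header,
#' columns sample1, hap1, sample2, hap2, chrom, start_bp, end_bp, lod.
#'
#' @param segments IBD segment data.frame.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_refined_ibd <- function(segments, path) {
  cols <- c("sample1", "hap1", "sample2", "hap2", "chrom",
            "start_bp", "end_bp", "lod")
  stopifnot(all(cols %in% names(segments)))
  df <- segments[cols]
  df$start_bp <- format(df$start_bp, scientific = FALSE, trim = TRUE)
  df$end_bp <- format(df$end_bp, scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Convert refined-IBD segments to fastIBD-style marker-index records
#'
#' Re-expresses each segment in the coordinate system of a marker table:
#' (sample1, sample2, index of the first marker at or after the segment
#' start, index of the last marker at or before the segment end, score =
#' LOD). Marker indices are 0-based within each chromosome. Segments
#' spanning no marker are dropped and counted.
#'
#' @param segments IBD segment data.frame.
#' @param markers marker table (\code{id}, \code{chrom}, \code{bp}),
#'   sorted by position within chromosome.
#' @return list with \code{records} (data.frame sample1, sample2, chrom,
#'   start_index, end_index, score) and \code{n_dropped}.
#' @export
convert_to_fastibd <- function(segments, markers) {
  markers <- check_markers(markers)
  unknown <- setdiff(unique(segments$chrom), unique(markers$chrom))
  if (length(unknown))
    stop2("segment chromosome not in marker table: ",
          paste(unknown, collapse = ", "))
  first <- integer(nrow(segments)); last <- integer(nrow(segments))
  for (ch in unique(segments$chrom)) {
    i <- segments$chrom == ch
    bp <- markers$bp[markers$chrom == ch]
    first[i] <- findInterval(segments$start_bp[i] - 1, bp) + 1L
    last[i] <- findInterval(segments$end_bp[i], bp)
  }
  keep <- first <= last & last >= 1
  rec <- data.frame(sample1 = segments$sample1[keep],
                    sample2 = segments$sample2[keep],
                    chrom = segments$chrom[keep],
                    start_index = first[keep] - 1L,  # 0-based
                    end_index = last[keep] - 1L,
                    score = segments$lod[keep],
                    stringsAsFactors = FALSE)
  list(records = rec, n_dropped = sum(!keep))
}

#' Write fastIBD-style records
#'
#' Tab-separated with comment header lines documenting the 0-based
#' per-chromosome marker index convention.
#'
#' @param records the \code{records} element of
#'   \code{\link{convert_to_fastibd}}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_fastibd <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# fastIBD-style segment records",
               "# marker indices are 0-based within each chromosome",
               paste(c("sample1", "sample2", "chrom", "start_index",
                       "end_index", "score"), collapse = "\t")), con)
  utils::write.table(records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
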