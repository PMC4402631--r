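#' Construct a genotype panel
#'
#' A genotype panel holds diploid biallelic genotypes coded as the dose
#' (0/1/2) of the coded allele, with \code{NA} for missing calls, together
#' with sample identifiers, case/control phenotypes and a marker table.
#'
#' @param calls integer matrix, samples in rows and markers in columns;
#'   entries 0, 1, 2 or \code{NA}.
#' @param sample_ids character vector of unique sample identifiers, one per
#'   row of \code{calls}.
#' @param phenotype character vector per sample: \code{"case"},
#'   \code{"control"} or \code{"unknown"}.
#' @param markers data.frame with columns \code{id}, \code{chrom}, \code{bp}
#'   (1-based, strictly increasing within chromosome) and optionally
#'   \code{cm}; one row per column of \code{calls}.
#' @return an object of class \code{genotype_panel}.
#' @export
genotype_panel <- function(calls, sample_ids, phenotype, markers) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  markers <- check_markers(markers)
  if (nrow(calls) != length(sample_ids))
    stop2("calls has ", nrow(calls), " rows but ", length(sample_ids),
          " sample ids")
  if (ncol(calls) != nrow(markers))
    stop2("calls has ", ncol(calls), " columns but ", nrow(markers),
          " markers")
  if (anyDuplicated(sample_ids)) stop2("duplicate sample ids")
  phenotype <- as.character(phenotype)
  if (length(phenotype) != length(sample_ids))
    stop2("phenotype length must match sample count")
  if (!all(phenotype %in% c("case", "control", "unknown")))
    stop2("phenotype values must be case/control/unknown")
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop2("genotype calls must be 0, 1, 2 or NA")
  rownames(calls) <- sample_ids
  colnames(calls) <- markers$id
  structure(list(calls = calls,
                 sample_ids = as.character(sample_ids),
                 phenotype = phenotype,
                 markers = markers),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("Genotype panel:", length(x$sample_ids), "samples x",
      nrow(x$markers), "markers\n")
  tab <- table(factor(x$phenotype, c("case", "control", "unknown")))
  cat("  phenotype:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  chromosomes:", paste(unique(x$markers$chrom), collapse = ", "), "\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing call rate: %.4f\n", miss))
  invisible(x)
}

#' Subset a genotype panel
#'
#' @param panel a \code{genotype_panel}.
#' @param samples sample ids (or logical/integer index) to keep; NULL keeps all.
#' @param markers marker ids (or logical/integer index) to keep; NULL keeps all.
#' @return the subsetted \code{genotype_panel}.
#' @export
subset_panel <- function(panel, samples = NULL, markers = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  si <- seq_along(panel$sample_ids)
  mi <- seq_len(nrow(panel$markers))
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, panel$sample_ids) else si[samples]
    if (anyNA(si)) stop2("unknown sample id in subset")
  }
  if (!is.null(markers)) {
    mi <- if (is.character(markers)) match(markers, panel$markers$id) else mi[markers]
    if (anyNA(mi)) stop2("unknown marker id in subset")
  }
  genotype_panel(panel$calls[si, mi, drop = FALSE],
                 panel$sample_ids[si],
                 panel$phenotype[si],
                 panel$markers[mi, , drop = FALSE])
}

#' Phenotypes of a panel as a named vector
#'
#' @param panel a \code{genotype_panel}.
#' @return named character vector (sample id -> status).
#' @export
panel_phenotypes <- function(panel) {
  stats::setNames(panel$phenotype, panel$sample_ids)
}
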