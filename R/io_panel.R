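#' Write a genotype panel as PLINK-style .ped/.map text
#'
#' The two alleles are written as \code{A} (reference) and \code{B}
#' (coded), with \code{0 0} for missing calls; dose d becomes d copies of
#' \code{B}. The .ped columns are FID, IID, PAT, MAT, SEX, PHENO (2 =
#' case, 1 = control, 0 = unknown) followed by two alleles per marker;
#' the .map columns are chrom, id, cM (0 when absent), bp.
#'
#' @param panel a \code{genotype_panel}.
#' @param prefix path prefix; \code{prefix.ped} and \code{prefix.map} are
#'   written.
#' @return the prefix, invisibly.
#' @export
write_ped <- function(panel, prefix) {
  stopifnot(inherits(panel, "genotype_panel"))
  geno_str <- c("A A", "A B", "B B")
  gm <- matrix("0 0", nrow(panel$calls), ncol(panel$calls))
  ok <- !is.na(panel$calls)
  gm[ok] <- geno_str[panel$calls[ok] + 1L]
  pheno <- c(case = 2L, control = 1L, unknown = 0L)[panel$phenotype]
  lines <- paste(panel$sample_ids, panel$sample_ids, 0L, 0L, 0L, pheno,
                 apply(gm, 1, paste, collapse = " "))
  writeLines(lines, paste0(prefix, ".ped"))
  mk <- panel$markers
  map <- data.frame(chrom = mk$chrom, id = mk$id,
                    cm = if ("cm" %in% names(mk)) mk$cm else 0,
                    bp = format(mk$bp, scientific = FALSE, trim = TRUE))
  utils::write.table(map, paste0(prefix, ".map"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a PLINK-style .ped/.map pair into a genotype panel
#'
#' Counterpart of \code{\link{write_ped}}; genotype dose is the count of
#' the \code{B} allele.
#'
#' @param prefix path prefix of the \code{.ped}/\code{.map} pair.
#' @return a \code{genotype_panel}.
#' @export
read_ped <- function(prefix) {
  map <- utils::read.table(paste0(prefix, ".map"), sep = "\t",
                           col.names = c("chrom", "id", "cm", "bp"),
                           colClasses = c("character", "character",
                                          "numeric", "numeric"))
  ped <- strsplit(readLines(paste0(prefix, ".ped")), "[ \t]+")
  nmk <- nrow(map)
  want <- 6 + 2 * nmk
  bad <- which(lengths(ped) != want)
  if (length(bad))
    stop2(".ped line ", bad[1], ": expected ", want, " fields, got ",
          lengths(ped)[bad[1]])
  m <- matrix(unlist(ped), ncol = want, byrow = TRUE)
  a1 <- m[, 6 + 2 * seq_len(nmk) - 1, drop = FALSE]
  a2 <- m[, 6 + 2 * seq_len(nmk), drop = FALSE]
  dose <- (a1 == "B") + (a2 == "B")
  dose[a1 == "0" | a2 == "0"] <- NA_integer_
  pheno <- c("0" = "unknown", "1" = "control", "2" = "case")[m[, 6]]
  genotype_panel(dose, m[, 2], unname(pheno),
                 data.frame(id = map$id, chrom = map$chrom, bp = map$bp,
                            cm = map$cm, stringsAsFactors = FALSE))
}

#' Write a genotype panel as VCF text
#'
#' Minimal uncompressed VCFv4.2 with GT-only diploid records (REF A,
#' ALT B); phenotypes are not representable in VCF and must travel in a
#' separate phenotype file.
#'
#' @param panel a \code{genotype_panel}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_vcf_panel <- function(panel, path) {
  stopifnot(inherits(panel, "genotype_panel"))
  gt_str <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(panel$calls), ncol(panel$calls))
  ok <- !is.na(panel$calls)
  gt[ok] <- gt_str[panel$calls[ok] + 1L]
  body <- paste(panel$markers$chrom,
                format(panel$markers$bp, scientific = FALSE, trim = TRUE),
                panel$markers$id, "A", "B", ".", "PASS", ".", "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$sample_ids), collapse = "\t"),
               body), path)
  invisible(path)
}

#' Read a VCF into a genotype panel
#'
#' Parses diploid GT records with \pkg{vcfR}; the dose is the ALT allele
#' count. Phenotypes are taken from \code{phenotypes} when given,
#' otherwise every sample is \code{"unknown"}.
#'
#' @param path VCF file path.
#' @param phenotypes optional named vector or data.frame
#'   (\code{sample_id}, \code{status}).
#' @return a \code{genotype_panel}.
#' @export
read_vcf_panel <- function(path, phenotypes = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)  # markers x samples
  dose <- matrix(NA_integer_, nrow(gt), ncol(gt))
  dose[gt %in% c("0/0", "0|0")] <- 0L
  dose[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dose[gt %in% c("1/1", "1|1")] <- 2L
  fix <- vcfR::getFIX(v)
  ids <- colnames(gt)
  pheno <- rep("unknown", length(ids))
  if (!is.null(phenotypes)) {
    ph <- check_phenotypes(phenotypes)
    hit <- match(ids, names(ph))
    pheno[!is.na(hit)] <- ph[hit[!is.na(hit)]]
  }
  genotype_panel(t(dose), ids, pheno,
                 data.frame(id = fix[, "ID"], chrom = fix[, "CHROM"],
                            bp = as.numeric(fix[, "POS"]),
                            stringsAsFactors = FALSE))
}

#' Read / write a phenotype file
#'
#' Tab-separated with a header: \code{sample_id}, \code{status}
#' (case/control/unknown).
#'
#' @param path file path.
#' @return \code{read_phenotypes}: named character vector;
#'   \code{write_phenotypes}: the path, invisibly.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  check_phenotypes(df)
}

#' @rdname read_phenotypes
#' @param phenotypes named character vector (sample id -> status).
#' @export
write_phenotypes <- function(phenotypes, path) {
  ph <- check_phenotypes(phenotypes)
  utils::write.table(data.frame(sample_id = names(ph), status = unname(ph)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
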