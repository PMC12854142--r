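#' Construct a hybrid genotype table
#'
#' A genotype table holds biallelic SNP calls for a candidate population of
#' hybrids. Calls are stored as character codes \code{"AA"} (major-allele
#' homozygote), \code{"AB"} (heterozygote) and \code{"BB"} (minor-allele
#' homozygote). Integer input in \code{{0, 1, 2}} is accepted and mapped as
#' 2 = AA, 1 = AB, 0 = BB (2 counts of the major allele).
#'
#' Missing calls are not allowed: genotype imputation and quality filtering
#' are assumed to have happened upstream, and the constructor fails loudly
#' if any cell is \code{NA} or an unknown symbol.
#'
#' @param calls character or integer matrix, hybrids in rows, markers in
#'   columns.
#' @param hybrid_ids,marker_ids optional identifier vectors; taken from
#'   \code{dimnames(calls)} when present, otherwise generated.
#' @return An object of class \code{genotype_table}: a list with elements
#'   \code{calls} (character matrix), \code{hybrid_ids} and
#'   \code{marker_ids}.
#' @examples
#' g <- genotype_table(matrix(c("AA", "AB", "BB", "AB"), 2, 2))
#' dim(g$calls)
#' @export
genotype_table <- function(calls, hybrid_ids = NULL, marker_ids = NULL) {
  if (!is.matrix(calls)) stop("`calls` must be a matrix")
  if (is.numeric(calls)) {
    bad <- which(!(calls %in% c(0L, 1L, 2L)) | is.na(calls))
    if (length(bad)) {
      rc <- arrayInd(bad[1L], dim(calls))
      stop(sprintf("invalid genotype code %s at row %d, column %d",
                   deparse(calls[bad[1L]]), rc[1L], rc[2L]))
    }
    calls <- matrix(c("BB", "AB", "AA")[calls + 1L], nrow(calls), ncol(calls),
                    dimnames = dimnames(calls))
  }
  storage.mode(calls) <- "character"
  bad <- which(!(calls %in% c("AA", "AB", "BB")) | is.na(calls))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(calls))
    stop(sprintf("invalid genotype call %s at row %d, column %d",
                 deparse(calls[bad[1L]]), rc[1L], rc[2L]))
  }
  if (nrow(calls) < 2L) stop("need at least 2 hybrids")
  if (ncol(calls) < 1L) stop("need at least 1 marker")
  hybrid_ids <- hybrid_ids %||% rownames(calls) %||%
    sprintf("H%03d", seq_len(nrow(calls)))
  marker_ids <- marker_ids %||% colnames(calls) %||%
    sprintf("M%05d", seq_len(ncol(calls)))
  dimnames(calls) <- list(hybrid_ids, marker_ids)
  structure(list(calls = calls, hybrid_ids = hybrid_ids,
                 marker_ids = marker_ids),
            class = "genotype_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d hybrids x %d markers\n",
              nrow(x$calls), ncol(x$calls)))
  invisible(x)
}

#' Read a genotype matrix from a delimited file
#'
#' Expects a header row of marker ids and one row per hybrid whose first
#' column is the hybrid id; the remaining cells are calls in
#' \code{{AA, AB, BB}} or \code{{0, 1, 2}}. The delimiter (tab or comma)
#' is auto-detected from the header line.
#'
#' @param path file path.
#' @return A [genotype_table()].
#' @export
read_genotypes <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character",
                          check.names = FALSE, row.names = 1L)
  m <- as.matrix(df)
  if (all(grepl("^[012]$", m))) storage.mode(m) <- "integer"
  genotype_table(m)
}

#' Read hybrid genotypes from a minimal biallelic VCF
#'
#' Uses only the GT subfield. Diploid genotypes are mapped with the REF
#' allele treated as the major allele: \code{0/0} to AA, \code{0/1} or
#' \code{1/0} to AB, \code{1/1} to BB (phased separators accepted).
#' Multi-allelic records are rejected and their count reported; missing
#' genotypes are an error.
#'
#' @param path path to an (uncompressed or bgzipped) VCF file.
#' @return A [genotype_table()] with markers in rows of the VCF mapped to
#'   columns.
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- v@fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    message(sprintf("dropping %d multi-allelic record(s)", sum(multi)))
    v <- v[!multi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (nrow(gt) == 0L) stop("no biallelic records in VCF")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  map <- c("0/0" = "AA", "0/1" = "AB", "1/0" = "AB", "1/1" = "BB")
  calls <- matrix(map[gt], nrow(gt), ncol(gt))
  if (anyNA(calls)) {
    bad <- which(is.na(calls))[1L]
    rc <- arrayInd(bad, dim(calls))
    stop(sprintf("missing or unsupported GT %s at record %d, sample %d",
                 deparse(unname(gt[bad])), rc[1L], rc[2L]))
  }
  marker_ids <- v@fix[, "ID"]
  no_id <- is.na(marker_ids) | marker_ids == "."
  marker_ids[no_id] <- paste0(v@fix[no_id, "CHROM"], ":", v@fix[no_id, "POS"])
  genotype_table(t(calls), hybrid_ids = colnames(gt), marker_ids = marker_ids)
}
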