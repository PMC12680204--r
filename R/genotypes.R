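# GenotypeMatrix: markers x accessions diploid calls coded
# 0 = hom-ref, 1 = het, 2 = hom-alt, -1 = missing.

#' Construct a genotype matrix
#'
#' @param calls integer matrix (markers in rows, accessions in columns)
#'   with codes `0/1/2/-1`; `NA` is accepted and recoded to `-1`.
#' @param marker_ids,accession_ids row/column identifiers.
#' @return an object of class `GenotypeMatrix`.
#' @export
genotype_matrix <- function(calls, marker_ids = rownames(calls),
                            accession_ids = colnames(calls)) {
  calls <- as.matrix(calls)
  mode(calls) <- "integer"
  calls[is.na(calls)] <- -1L
  if (!all(calls %in% c(-1L, 0L, 1L, 2L))) {
    stop("genotype codes must be in {0, 1, 2, -1/NA}")
  }
  if (is.null(marker_ids) || is.null(accession_ids)) {
    stop("marker_ids and accession_ids are required")
  }
  if (nrow(calls) != length(marker_ids) ||
      ncol(calls) != length(accession_ids)) {
    stop("calls matrix shape does not match id vectors")
  }
  dimnames(calls) <- list(marker_ids, accession_ids)
  structure(list(marker_ids = as.character(marker_ids),
                 accession_ids = as.character(accession_ids),
                 calls = calls),
            class = "GenotypeMatrix")
}

#' Load a genotype matrix from TSV or VCF
#'
#' TSV mode expects markers in rows (first column `id`), accessions in
#' the remaining columns, codes `0/1/2` and `NA` (or `-1`) for missing.
#' VCF mode converts `GT` fields (`0/0`, `0/1`, `1/1`, `./.`; phased
#' separators accepted).
#'
#' @param path input file.
#' @param format `"auto"`, `"tsv"` or `"vcf"`.
#' @return a [genotype_matrix()].
#' @export
load_genotypes <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    genotype_matrix(m, marker_ids = ids, accession_ids = colnames(m))
  } else {
    vcf <- VariantAnnotation::readVcf(path)
    gt <- VariantAnnotation::geno(vcf)$GT
    code <- matrix(-1L, nrow(gt), ncol(gt))
    norm <- gsub("|", "/", gt, fixed = TRUE)
    code[norm %in% c("0/0")] <- 0L
    code[norm %in% c("0/1", "1/0")] <- 1L
    code[norm %in% c("1/1")] <- 2L
    genotype_matrix(code, marker_ids = rownames(gt),
                    accession_ids = colnames(gt))
  }
}

#' Write a genotype matrix as TSV
#'
#' @param gm a `GenotypeMatrix`.
#' @param path output file; missing calls written as `NA`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path) {
  m <- gm$calls
  m[m == -1L] <- NA_integer_
  df <- data.frame(id = gm$marker_ids, m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat("GenotypeMatrix: ", length(x$marker_ids), " markers x ",
      length(x$accession_ids), " accessions (",
      sum(x$calls == -1L), " missing calls)\n", sep = "")
  invisible(x)
}
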