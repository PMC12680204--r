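# Marker table I/O.  A marker is an array SNP with a source-assembly
# coordinate and an allele pair; internally positions are 0-based
# (`pos0`), while the TSV/VCF representations are 1-based.

#' Build a marker table
#'
#' @param id marker identifiers (unique).
#' @param chrom source sequence names.
#' @param pos0 0-based SNP positions.
#' @param ref,alt allele pair, single bases in `{A,C,G,T}`, `ref != alt`.
#' @param region optional source-region labels
#'   (`genic`/`upstream`/`downstream`/`intergenic`/`unknown`).
#' @param genome optional `GenomeAssembly` used to bounds-check `pos0`.
#' @return a `data.frame` with columns `id, chrom, pos0, ref, alt, region`.
#' @export
marker_table <- function(id, chrom, pos0, ref, alt, region = NULL,
                         genome = NULL) {
  id <- as.character(id)
  if (anyDuplicated(id)) {
    stop("duplicate marker id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  if (!all(ref %in% DNA_BASES) || !all(alt %in% DNA_BASES)) {
    stop("alleles must be single bases in {A,C,G,T}")
  }
  same <- ref == alt
  if (any(same)) {
    stop("ref equals alt for marker(s): ", paste(id[same], collapse = ", "))
  }
  pos0 <- as.integer(pos0)
  if (any(pos0 < 0)) stop("negative marker position")
  if (is.null(region)) region <- rep("unknown", length(id))
  region <- as.character(region)
  ok_regions <- c("genic", "upstream", "downstream", "intergenic",
                  "near_genic", "unknown")
  if (!all(region %in% ok_regions)) {
    stop("region labels must be one of: ", paste(ok_regions, collapse = ", "))
  }
  if (!is.null(genome)) {
    miss <- !(chrom %in% names(genome$sequences))
    if (any(miss)) {
      stop("marker chromosome(s) absent from genome: ",
           paste(unique(chrom[miss]), collapse = ", "))
    }
    beyond <- pos0 >= genome$lengths[chrom]
    if (any(beyond)) {
      stop("marker position beyond chromosome end: ",
           paste(id[beyond], collapse = ", "))
    }
  }
  data.frame(id = id, chrom = as.character(chrom), pos0 = pos0,
             ref = ref, alt = alt, region = region,
             stringsAsFactors = FALSE)
}

#' Load markers from a TSV table or a VCF
#'
#' TSV mode expects a header with columns `id, chrom, pos, ref, alt`
#' (optional `region`), with `pos` 1-based.  VCF mode reads
#' `CHROM/POS/ID/REF/ALT` of biallelic SNV records.
#'
#' @param path input file; format inferred from the extension unless
#'   `format` is given.
#' @param genome optional `GenomeAssembly` for coordinate validation.
#' @param format `"auto"`, `"tsv"` or `"vcf"`.
#' @return a marker `data.frame` (see [marker_table()]).
#' @export
load_markers <- function(path, genome = NULL,
                         format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (!file.exists(path)) stop("marker file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE,
                            colClasses = "character")
    need <- c("id", "chrom", "pos", "ref", "alt")
    if (!all(need %in% names(df))) {
      stop("marker table must have columns: ", paste(need, collapse = ", "))
    }
    marker_table(df$id, df$chrom, as.integer(df$pos) - 1L, df$ref, df$alt,
                 region = if ("region" %in% names(df)) df$region else NULL,
                 genome = genome)
  } else {
    vcf <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(vcf)
    alt <- as.character(unlist(rr$ALT))
    marker_table(names(rr),
                 as.character(GenomicRanges::seqnames(rr)),
                 GenomicRanges::start(rr) - 1L,
                 as.character(rr$REF), alt,
                 genome = genome)
  }
}

#' Write markers to the TSV format read by [load_markers()]
#'
#' @param markers marker `data.frame`.
#' @param path output file; positions emitted 1-based.
#' @return `path`, invisibly.
#' @export
write_markers <- function(markers, path) {
  out <- data.frame(id = markers$id, chrom = markers$chrom,
                    pos = markers$pos0 + 1L, ref = markers$ref,
                    alt = markers$alt, region = markers$region)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
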