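# Interval I/O.  Intervals are plain data.frames with 0-based half-open
# coordinates and a `kind` in {gene, te_class_I, te_class_II,
# low_identity, other}; BED input is native 0-based, GFF3 is converted.

#' Build an interval table
#'
#' @param chrom sequence names.
#' @param start0,end0 0-based half-open spans (`start0 < end0`).
#' @param name feature identifiers.
#' @param strand `+`, `-` or `.`.
#' @param kind one of `gene`, `te_class_I`, `te_class_II`,
#'   `low_identity`, `other`.
#' @return a `data.frame` with those columns.
#' @export
interval_table <- function(chrom, start0, end0, name = NA_character_,
                           strand = ".", kind = "other") {
  start0 <- as.integer(start0)
  end0 <- as.integer(end0)
  bad <- start0 < 0 | start0 >= end0
  if (any(bad)) {
    stop("invalid interval(s): start0 must satisfy 0 <= start0 < end0 (",
         sum(bad), " offending row(s))")
  }
  n <- length(chrom)
  data.frame(chrom = as.character(chrom), start0 = start0, end0 = end0,
             name = rep_len(as.character(name), n),
             strand = rep_len(as.character(strand), n),
             kind = rep_len(as.character(kind), n),
             stringsAsFactors = FALSE)
}

# map TE names with an "I"/"II" prefix (or RLX/DTA-style class labels)
# to the two transposon classes; anything unrecognised stays "other"
te_kind_from_name <- function(name) {
  kind <- rep("other", length(name))
  kind[grepl("^I([^I]|$)", name)] <- "te_class_I"
  kind[grepl("^II", name)] <- "te_class_II"
  kind
}

#' Load intervals from BED or GFF3
#'
#' BED (0-based half-open) and GFF3 (1-based inclusive) are read with
#' `rtracklayer::import()` and normalised to the package's 0-based
#' half-open convention.  For GFF3, the feature `type` sets `kind`
#' (`gene` features map to `"gene"`); for BED, the name column is parsed
#' for a transposable-element class prefix (`I`/`II`) when
#' `te_names = TRUE`, otherwise `kind` applies to all rows.
#'
#' @param path BED or GFF3 file.
#' @param kind_filter optional kind to keep (e.g. `"gene"`); rows of
#'   other kinds are dropped.
#' @param kind default kind assigned to BED rows (ignored for GFF3).
#' @param te_names parse TE classes from the BED name column.
#' @param format `"auto"`, `"bed"` or `"gff3"`.
#' @return an interval `data.frame` (possibly with zero rows).
#' @export
load_intervals <- function(path, kind_filter = NULL, kind = "other",
                           te_names = FALSE,
                           format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gff3?|gff)(\\.gz)?$", path)) "gff3" else "bed"
  }
  if (!file.exists(path)) stop("interval file not found: ", path)
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  if (length(gr) == 0) {
    return(interval_table(character(0), integer(0), integer(0))[0, ])
  }
  nm <- if (!is.null(gr$name)) as.character(gr$name)
        else if (!is.null(gr$ID)) as.character(gr$ID)
        else if (!is.null(gr$Name)) as.character(gr$Name)
        else rep(NA_character_, length(gr))
  if (format == "gff3") {
    kinds <- ifelse(as.character(gr$type) == "gene", "gene", "other")
  } else if (te_names) {
    kinds <- te_kind_from_name(nm)
  } else {
    kinds <- rep(kind, length(gr))
  }
  out <- interval_table(as.character(GenomicRanges::seqnames(gr)),
                        GenomicRanges::start(gr) - 1L,
                        GenomicRanges::end(gr),
                        name = nm,
                        strand = as.character(GenomicRanges::strand(gr)),
                        kind = kinds)
  out$strand[out$strand == "*"] <- "."
  if (!is.null(kind_filter)) out <- out[out$kind %in% kind_filter, ]
  rownames(out) <- NULL
  out
}

#' Write intervals as BED6
#'
#' @param intervals interval `data.frame`.
#' @param path output BED file (0-based half-open, as BED requires).
#' @return `path`, invisibly.
#' @export
write_intervals_bed <- function(intervals, path) {
  name <- ifelse(is.na(intervals$name), ".", intervals$name)
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   intervals$chrom, intervals$start0, intervals$end0,
                   name,
                   ifelse(intervals$strand %in% c("+", "-"),
                          intervals$strand, "."))
  writeLines(lines, path)
  invisible(path)
}

# point-in-interval test: logical, one element per (chrom, pos0) pair
point_in_intervals <- function(chrom, pos0, intervals) {
  if (nrow(intervals) == 0) return(rep(FALSE, length(chrom)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos0 + 1L, pos0 + 1L))
  s <- GenomicRanges::GRanges(intervals$chrom,
                              IRanges::IRanges(intervals$start0 + 1L,
                                               intervals$end0))
  IRanges::overlapsAny(q, s)
}
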