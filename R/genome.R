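# GenomeAssembly: an in-memory assembly as uppercase character strings,
# with per-sequence scaffold flags.  All coordinates handled by this
# package are 0-based half-open; conversion to 1-based happens only at
# the FASTA/VCF/GFF boundaries.

#' Construct a genome assembly object
#'
#' @param sequences named character vector of DNA strings (uppercased on
#'   input; alphabet restricted to `A,C,G,T,N`).
#' @param name assembly label.
#' @param scaffolds optional character vector naming the sequences that
#'   are unplaced scaffolds; when `NULL`, any sequence whose name starts
#'   with `"scaffold"` (case-insensitive) is flagged.
#' @return an object of class `GenomeAssembly` with fields `name`,
#'   `sequences`, `lengths` and `is_scaffold`.
#' @export
genome_assembly <- function(sequences, name = "genome", scaffolds = NULL) {
  if (length(sequences) == 0) stop("no records")
  if (is.null(names(sequences)) || anyNA(names(sequences)) ||
      any(names(sequences) == "")) {
    stop("all sequences must be named")
  }
  if (anyDuplicated(names(sequences))) {
    stop("duplicate sequence names: ",
         paste(unique(names(sequences)[duplicated(names(sequences))]),
               collapse = ", "))
  }
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    stop("sequence '", names(sequences)[bad][1],
         "' contains characters outside {A,C,G,T,N}")
  }
  if (is.null(scaffolds)) {
    is_scaf <- grepl("^scaffold", names(sequences), ignore.case = TRUE)
  } else {
    is_scaf <- names(sequences) %in% scaffolds
  }
  structure(
    list(name = name,
         sequences = sequences,
         lengths = setNames(nchar(sequences), names(sequences)),
         is_scaffold = setNames(is_scaf, names(sequences))),
    class = "GenomeAssembly")
}

#' Load a genome assembly from FASTA
#'
#' Reads all records with [Biostrings::readDNAStringSet()], uppercases
#' them and validates the alphabet.  Record names are truncated at the
#' first whitespace, matching `.fai` conventions.
#'
#' @param path FASTA file (optionally gzipped).
#' @inheritParams genome_assembly
#' @return a [genome_assembly()] object.
#' @export
load_genome <- function(path, name = NULL, scaffolds = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) {
                    stop("malformed FASTA '", path, "': ", conditionMessage(e))
                  })
  if (length(set) == 0) stop("no records in FASTA: ", path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  genome_assembly(seqs,
                  name = if (is.null(name)) basename(path) else name,
                  scaffolds = scaffolds)
}

#' Write a genome assembly to FASTA
#'
#' @param genome a `GenomeAssembly`.
#' @param path output file.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, width = 70) {
  set <- Biostrings::DNAStringSet(genome$sequences)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Extract a subsequence in 0-based half-open coordinates
#'
#' @param genome a `GenomeAssembly`.
#' @param chrom sequence name.
#' @param start0,end0 0-based half-open span; clipped to the sequence.
#' @return a character string (possibly empty).
#' @export
genome_subseq <- function(genome, chrom, start0, end0) {
  s <- genome$sequences[[chrom]]
  if (is.null(s)) stop("sequence not in assembly: ", chrom)
  L <- genome$lengths[[chrom]]
  start0 <- max(0L, start0)
  end0 <- min(L, end0)
  if (end0 <= start0) return("")
  substr(s, start0 + 1L, end0)
}

# single base at a 0-based position
genome_base <- function(genome, chrom, pos0) {
  genome_subseq(genome, chrom, pos0, pos0 + 1L)
}

#' @export
print.GenomeAssembly <- function(x, ...) {
  cat("GenomeAssembly '", x$name, "': ", length(x$sequences),
      " sequence(s), ", sum(as.numeric(x$lengths)), " bp (",
      sum(x$is_scaffold), " scaffold)\n", sep = "")
  invisible(x)
}
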