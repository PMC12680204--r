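# VCF emission for lifted markers.  Hand-rolled writer: the contract
# includes a rejects side-file with reason tags, and the records are
# simple biallelic SNVs.

#' Write lifted markers as VCF, failed markers to a rejects file
#'
#' One record per `LIFTED` marker, sorted by target chromosome and
#' position (1-based `POS`).  `REF` is the base the target genome
#' carries at the lifted position and `ALT` the other allele of the
#' strand-oriented pair, so `REF` always agrees with the target — a
#' disagreement after validation raises an internal consistency error.
#' Strand-flipped markers therefore emit the complemented pair.  Failed
#' markers are written to `rejects_path` with their failure reason.
#'
#' @param results liftover result `data.frame` (after validation).
#' @param markers matching marker `data.frame`.
#' @param target the target `GenomeAssembly`.
#' @param path output VCF path.
#' @param rejects_path output TSV for non-lifted markers.
#' @return number of VCF records written.
#' @export
write_lifted_vcf <- function(results, markers, target, path,
                             rejects_path = paste0(path, ".rejects.tsv")) {
  stopifnot(nrow(results) == nrow(markers),
            all(results$marker_id == markers$id))
  lifted <- results$status == "LIFTED"
  rej <- data.frame(marker_id = results$marker_id[!lifted],
                    reason = results$status[!lifted],
                    stringsAsFactors = FALSE)
  utils::write.table(rej, rejects_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##reference=%s", target$name),
               paste0("##INFO=<ID=SRC,Number=1,Type=String,",
                      "Description=\"Source coordinate chrom:pos (1-based)\">"),
               paste0("##INFO=<ID=STRAND,Number=1,Type=String,",
                      "Description=\"Liftover strand\">"),
               paste0("##INFO=<ID=SWAP,Number=0,Type=Flag,",
                      "Description=\"Target carries the alternate allele;",
                      " REF/ALT swapped\">"),
               sprintf("##contig=<ID=%s,length=%d>",
                       names(target$lengths), target$lengths),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (!any(lifted)) return(0L)

  r <- results[lifted, , drop = FALSE]
  m <- markers[lifted, , drop = FALSE]
  la <- lift_alleles_vec(m$ref, m$alt, r$strand)
  tbase <- vapply(seq_len(nrow(r)), function(i) {
    genome_base(target, r$tname[i], r$tpos0[i])
  }, character(1))
  if (!all(tbase == la$lifted_ref | tbase == la$lifted_alt)) {
    bad <- which(!(tbase == la$lifted_ref | tbase == la$lifted_alt))
    stop("internal consistency error: emitted REF would disagree with ",
         "the target genome for marker(s) ",
         paste(r$marker_id[bad], collapse = ", "))
  }
  swap <- tbase == la$lifted_alt
  ref_out <- ifelse(swap, la$lifted_alt, la$lifted_ref)
  alt_out <- ifelse(swap, la$lifted_ref, la$lifted_alt)
  info <- sprintf("SRC=%s:%d;STRAND=%s%s",
                  m$chrom, m$pos0 + 1L, r$strand,
                  ifelse(swap, ";SWAP", ""))
  ord <- order(r$tname, r$tpos0)
  writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s",
                     r$tname[ord], r$tpos0[ord] + 1L, r$marker_id[ord],
                     ref_out[ord], alt_out[ord], info[ord]), con)
  sum(lifted)
}

# vectorised lift_alleles
lift_alleles_vec <- function(ref, alt, strand) {
  flip <- strand == "-"
  list(lifted_ref = ifelse(flip, comp_base(ref), ref),
       lifted_alt = ifelse(flip, comp_base(alt), alt))
}
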