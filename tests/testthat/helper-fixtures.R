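# Shared fixture builders for the test suite.  Everything is generated
# in code; no binary fixtures.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a small random genome assembly
tiny_genome <- function(lengths = c(chr1 = 3000L, chr2 = 2000L),
                        seed = 1, name = "tiny") {
  set.seed(seed)
  genome_assembly(vapply(lengths, rand_dna, character(1)), name = name)
}

# a FlankQuery anchored at (chrom, pos0) of `genome`
flank_query_at <- function(genome, chrom, pos0, id = "m", flank = 50) {
  extract_flank(
    marker_table(id, chrom, pos0,
                 genome_base(genome, chrom, pos0),
                 setdiff(c("A", "C", "G", "T"),
                         genome_base(genome, chrom, pos0))[1],
                 genome = genome)[1, ],
    genome, flank)
}

# fabricate a perfect ungapped Alignment + FlankQuery pair mapping the
# source span [src_start0, src_start0 + len) of `chrom` to the target
# span starting at tgt_start0 on `tname`; used to exercise the chain
# builder without running the aligner
fake_accepted <- function(chrom, src_start0, len, tname, tgt_start0,
                          strand = "+", id = "m", score = len) {
  q <- 0:(len - 1)
  t <- if (strand == "+") tgt_start0 + q else (tgt_start0 + len - 1) - q
  aln <- structure(list(
    marker_id = id, tname = tname,
    tstart0 = min(t), tend0 = max(t) + 1L, strand = strand,
    qstart0 = 0L, qend0 = len,
    matches = len, mismatches = 0L, q_gap_bases = 0L, t_gap_bases = 0L,
    gap_openings = 0L, score = as.numeric(score), identity_pct = 100,
    colmap = cbind(q = q, t = t)), class = "Alignment")
  query <- structure(list(marker_id = id, seq = strrep("A", len),
                          snp_offset = len %/% 2L,
                          up_len = len %/% 2L,
                          down_len = len - len %/% 2L - 1L,
                          chrom = chrom, start0 = as.integer(src_start0)),
                     class = "FlankQuery")
  list(alignment = aln, query = query)
}

# small simulator config used by several module tests
small_sim_config <- function(seed = 3, invert = FALSE) {
  sim_config(seed = seed,
             chrom_lengths = c(chr1 = 120000L, chr2 = 80000L,
                               scaffold_1 = 10000L),
             n_markers = 60,
             fate_quotas = c(LIFTED = 40L, MULTI_MAPPED = 6L,
                             UNMAPPED = 6L, ALLELE_DIVERGENT = 4L,
                             LOW_IDENTITY = 4L),
             n_genes = 12L, n_tes = 10L,
             invert_one_chrom = invert)
}

# minimal VCF text for reader tests
write_mini_vcf <- function(path, rows) {
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=chr1,length=1000>",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               rows), path)
  path
}
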