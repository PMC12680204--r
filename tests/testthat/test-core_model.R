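# core_model: genome / marker / interval / VCF I-O and the coordinate
# conventions (0-based half-open internally, 1-based at VCF/GFF edges).

test_that("load_genome reads, uppercases and validates FASTA", {
  fa <- withr::local_tempfile(fileext = ".fa")
  set.seed(1)
  s1 <- rand_dna(60)
  s2 <- tolower(rand_dna(40))
  writeLines(c(">chr1 assembled", s1, ">chr2", s2), fa)
  g <- load_genome(fa, name = "g")
  expect_equal(unname(g$lengths[c("chr1", "chr2")]), c(60L, 40L))
  expect_identical(g$sequences[["chr1"]], s1)
  expect_identical(g$sequences[["chr2"]], toupper(s2))

  empty <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), empty)
  expect_error(load_genome(empty), "no records")

  expect_error(genome_assembly(c(chr1 = "ACGX")), "outside")
  expect_error(genome_assembly(c(chr1 = "ACG", chr1 = "ACG")),
               "duplicate")
})

test_that("scaffold flags come from name pattern or explicit list", {
  g <- genome_assembly(c(chr1 = "ACGT", Scaffold_9 = "ACGT"))
  expect_equal(unname(g$is_scaffold), c(FALSE, TRUE))
  g2 <- genome_assembly(c(chr1 = "ACGT", unplaced1 = "ACGT"),
                        scaffolds = "unplaced1")
  expect_equal(unname(g2$is_scaffold), c(FALSE, TRUE))
})

test_that("load_markers converts 1-based TSV and validates", {
  g <- tiny_genome(c(chr1 = 100L))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tchrom\tpos\tref\talt", "m1\tchr1\t51\tA\tG"), tsv)
  mk <- load_markers(tsv, genome = NULL)
  expect_equal(mk$pos0, 50L)
  expect_equal(mk$ref, "A")
  expect_equal(mk$alt, "G")

  writeLines(c("id\tchrom\tpos\tref\talt",
               "m1\tchr1\t51\tA\tG", "m1\tchr1\t61\tC\tT"), tsv)
  expect_error(load_markers(tsv), "duplicate")

  writeLines(c("id\tchrom\tpos\tref\talt", "m1\tchr1\t51\tA\tA"), tsv)
  expect_error(load_markers(tsv), "ref equals alt")

  writeLines(c("id\tchrom\tpos\tref\talt", "m1\tchr1\t101\tA\tG"), tsv)
  expect_error(load_markers(tsv, genome = g), "beyond")
})

test_that("VCF and TSV marker input are equivalent", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_mini_vcf(vcf, "chr1\t51\tm1\tA\tG\t.\t.\t.")
  mk <- load_markers(vcf)
  expect_equal(mk$id, "m1")
  expect_equal(mk$chrom, "chr1")
  expect_equal(mk$pos0, 50L)
  expect_equal(mk$ref, "A")
  expect_equal(mk$alt, "G")
})

test_that("load_intervals normalises BED and GFF3 coordinates", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10\t20\tg1\t0\t+", bed)
  iv <- load_intervals(bed)
  expect_equal(iv$start0, 10L)
  expect_equal(iv$end0, 20L)
  expect_equal(iv$strand, "+")

  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t11\t20\t.\t+\t.\tID=g1"), gff)
  iv2 <- load_intervals(gff, kind_filter = "gene")
  expect_equal(iv2$start0, 10L)
  expect_equal(iv2$end0, 20L)
  expect_equal(iv2$kind, "gene")

  writeLines(c("##gff-version 3",
               "chr1\tsrc\tmRNA\t11\t20\t.\t+\t.\tID=t1"), gff)
  expect_equal(nrow(load_intervals(gff, kind_filter = "gene")), 0L)

  expect_error(interval_table("chr1", 20, 10), "start0")
})

test_that("BED round-trip preserves 0-based half-open coordinates", {
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(3:8, 1)
    s0 <- sample.int(1000, n)
    iv <- interval_table(sample(c("chr1", "chr2"), n, replace = TRUE),
                         s0, s0 + sample.int(50, n),
                         name = sprintf("f%d", seq_len(n)),
                         strand = sample(c("+", "-", "."), n,
                                         replace = TRUE))
    bed <- withr::local_tempfile(fileext = ".bed")
    write_intervals_bed(iv, bed)
    back <- load_intervals(bed)
    expect_equal(back$start0, iv$start0)
    expect_equal(back$end0, iv$end0)
    expect_equal(back$name, iv$name)
    expect_equal(back$strand, iv$strand)
  }
})

test_that("write_lifted_vcf emits lifted records, rejects and flips", {
  g <- tiny_genome(c(chr1 = 200L), seed = 5, name = "tgt")
  b60 <- genome_base(g, "chr1", 60)
  b80 <- genome_base(g, "chr1", 80)
  b90 <- genome_base(g, "chr1", 90)
  other <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  markers <- marker_table(c("m1", "m2", "m3", "m4"), "chr1",
                          c(10, 20, 30, 40),
                          c(b60, comp_base(b80), b90, "A"),
                          c(other(b60), comp_base(other(b80)),
                            other(b90), "G"))
  results <- data.frame(
    marker_id = markers$id,
    status = c("LIFTED", "LIFTED", "LIFTED", "UNMAPPED"),
    tname = c("chr1", "chr1", "chr1", NA),
    tpos0 = c(60L, 80L, 90L, NA),
    strand = c("+", "-", "+", NA),
    stringsAsFactors = FALSE)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  n <- write_lifted_vcf(results, markers, g, vcf)
  expect_equal(n, 3L)
  lines <- grep("^#", readLines(vcf), value = TRUE, invert = TRUE)
  expect_length(lines, 3L)
  rej <- read.table(paste0(vcf, ".rejects.tsv"), header = TRUE)
  expect_equal(rej$marker_id, "m4")
  expect_equal(rej$reason, "UNMAPPED")
  # strand-flipped marker m2: REF/ALT come from the complemented pair
  f <- strsplit(lines[2], "\t")[[1]]
  expect_equal(f[4], b80)  # complement of marker ref == target base
  expect_true(grepl("STRAND=-", f[8]))
  # emitted POS is 1-based
  expect_equal(as.integer(f[2]), 81L)

  # empty results: header-only VCF
  vcf2 <- withr::local_tempfile(fileext = ".vcf")
  n0 <- write_lifted_vcf(results[results$status == "NONE", , drop = FALSE],
                         markers[0, , drop = FALSE], g, vcf2)
  expect_equal(n0, 0L)
  expect_length(grep("^#", readLines(vcf2), invert = TRUE, value = TRUE),
                0L)
})

test_that("marker load -> VCF write -> load round-trip is exact", {
  g <- tiny_genome(c(chr1 = 500L), seed = 11)
  pos <- c(100L, 200L, 300L)
  ref <- vapply(pos, function(p) genome_base(g, "chr1", p), character(1))
  alt <- vapply(ref, function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                character(1))
  markers <- marker_table(c("a", "b", "c"), "chr1", pos, ref, alt)
  # identity liftover so REF always equals the target base
  results <- data.frame(marker_id = markers$id, status = "LIFTED",
                        tname = "chr1", tpos0 = pos, strand = "+",
                        stringsAsFactors = FALSE)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_lifted_vcf(results, markers, g, vcf)
  back <- load_markers(vcf)
  back <- back[order(back$pos0), ]
  expect_equal(back$id, markers$id)
  expect_equal(back$pos0, markers$pos0)
  expect_equal(back$ref, markers$ref)
  expect_equal(back$alt, markers$alt)
})
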