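# liftover_engine: hit classification, SNP projection, allele strand
# transfer, chain construction and chain lifting.

test_that("classify_hits applies the margin-0 tie rule", {
  expect_equal(classify_hits(list())$status, "UNMAPPED")
  a1 <- fake_accepted("chr1", 0, 101, "t1", 100)$alignment
  a2 <- fake_accepted("chr1", 0, 101, "t2", 500)$alignment
  expect_equal(classify_hits(list(a1, a2))$status, "MULTI_MAPPED")
  a2b <- a2
  a2b$score <- 100
  cls <- classify_hits(list(a1, a2b))
  expect_equal(cls$status, "UNIQUE")
  expect_equal(cls$alignment$tname, "t1")
})

test_that("map_snp_position walks the column map", {
  fq <- function(off) list(snp_offset = off)
  # ungapped '+', tstart0 1000
  a <- fake_accepted("c", 0, 101, "t", 1000)$alignment
  expect_equal(map_snp_position(a, fq(50L))$tpos0, 1050L)

  # 3 bp target deletion before the SNP: query 0..19 -> 1000..1019,
  # query 20..22 against target gap, query 23.. -> 1020..
  q <- 0:100
  t <- c(1000:1019, rep(NA, 3), 1020 + 0:(100 - 23))
  a2 <- a
  a2$colmap <- cbind(q = q, t = t)
  expect_equal(map_snp_position(a2, fq(50L))$tpos0, 1047L)
  expect_equal(map_snp_position(a2, fq(21L)), "GAP_AT_SITE")
  expect_equal(map_snp_position(a2, fq(200L)), "GAP_AT_SITE")

  # ungapped '-' covering the query, target span [2000, 2101)
  a3 <- fake_accepted("c", 0, 101, "t", 2000, strand = "-")$alignment
  hit <- map_snp_position(a3, fq(50L))
  expect_equal(hit$tpos0, 2050L)
  expect_equal(hit$strand, "-")
})

test_that("lift_alleles is identity on + and complement on -", {
  expect_equal(lift_alleles("A", "G", "+"),
               list(lifted_ref = "A", lifted_alt = "G"))
  expect_equal(lift_alleles("A", "G", "-"),
               list(lifted_ref = "T", lifted_alt = "C"))
  expect_equal(lift_alleles("C", "T", "-"),
               list(lifted_ref = "G", lifted_alt = "A"))
})

test_that("build_chains links collinear blocks and splits on breaks", {
  mk <- function(s0, t0, tname = "t1", strand = "+", chrom = "chr1") {
    fake_accepted(chrom, s0, 101, tname, t0, strand = strand)
  }
  # 3 collinear blocks with ~100 bp gaps -> one chain
  ch <- build_chains(list(mk(0, 1000), mk(200, 1200), mk(400, 1400)))
  expect_length(ch, 1L)
  expect_equal(nrow(ch[[1]]$blocks), 3L)
  expect_equal(ch[[1]]$score, 303)

  # different target chromosomes -> two chains
  ch2 <- build_chains(list(mk(0, 1000), mk(200, 1200, tname = "t2")))
  expect_length(ch2, 2L)

  # 50 kb source gap exceeds max_gap -> two chains
  ch3 <- build_chains(list(mk(0, 1000), mk(50000, 51000)))
  expect_length(ch3, 2L)

  # overlapping queries on one diagonal merge into a single block
  ch4 <- build_chains(list(mk(0, 1000), mk(60, 1060)))
  expect_length(ch4, 1L)
  expect_equal(nrow(ch4[[1]]$blocks), 1L)
  expect_equal(ch4[[1]]$blocks$src_end0, 161)
  expect_equal(ch4[[1]]$blocks$tgt_end0, 1161)
})

test_that("chain block invariants hold on simulator truth chains", {
  cfg <- small_sim_config(seed = 9)
  src <- generate_source(cfg)
  der <- derive_target(src, cfg)
  for (ch in der$truth_chain) {
    bl <- ch$blocks
    expect_true(all(diff(bl$src_start0) > 0))
    expect_true(all(bl$src_end0 - bl$src_start0 ==
                      bl$tgt_end0 - bl$tgt_start0))
    expect_true(all(bl$tname_src == bl$tname_src[1]))
    expect_true(all(bl$strand == bl$strand[1]))
    if (nrow(bl) > 1) {
      expect_true(all(bl$src_start0[-1] >= bl$src_end0[-nrow(bl)]))
    }
  }
})

test_that("lift_by_chain projects inside blocks and refuses gaps", {
  blocks <- data.frame(
    tname_src = "chr1", src_start0 = c(10L, 40L), src_end0 = c(30L, 60L),
    tname_tgt = "t1", tgt_start0 = c(110L, 140L), tgt_end0 = c(130L, 160L),
    strand = "+", score = 20, stringsAsFactors = FALSE)
  chains <- list(list(id = 1L, blocks = blocks, score = 40))
  expect_equal(lift_by_chain("chr1", 15L, chains)$tpos0, 115L)
  expect_equal(lift_by_chain("chr1", 35L, chains), "UNMAPPED")
  expect_equal(lift_by_chain("chr2", 15L, chains), "UNMAPPED")

  neg <- list(list(id = 1L, blocks = data.frame(
    tname_src = "chr1", src_start0 = 10L, src_end0 = 30L,
    tname_tgt = "t1", tgt_start0 = 200L, tgt_end0 = 220L,
    strand = "-", score = 20, stringsAsFactors = FALSE), score = 20))
  expect_equal(lift_by_chain("chr1", 15L, neg)$tpos0, 214L)

  # overlapping chains resolved by chain score
  hi <- list(list(id = 1L, blocks = blocks, score = 40),
             list(id = 2L, blocks = transform(blocks,
                                              tgt_start0 = tgt_start0 + 1000L,
                                              tgt_end0 = tgt_end0 + 1000L),
                  score = 90))
  expect_equal(lift_by_chain("chr1", 15L, hi)$tpos0, 1115L)
})

test_that("chain lifting agrees with direct projection where both apply", {
  cfg <- small_sim_config(seed = 13)
  fix <- simulate_fixture(cfg)
  out <- run_liftover(fix$markers, fix$source, fix$target)
  r <- out$results
  direct <- which(r$provenance == "direct_alignment")
  checked <- 0L
  for (i in direct) {
    hit <- lift_by_chain(fix$markers$chrom[i], fix$markers$pos0[i],
                         out$chains)
    if (is.list(hit)) {
      expect_equal(hit$tpos0, r$tpos0[i])
      expect_equal(hit$tname, r$tname[i])
      expect_equal(hit$strand, r$strand[i])
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 0L)
})

test_that("the chain writer emits exact UCSC records", {
  src <- genome_assembly(c(chr1 = strrep("A", 100)), "src")
  tgt <- genome_assembly(c(t1 = strrep("A", 300)), "tgt")
  blocks <- data.frame(
    tname_src = "chr1", src_start0 = c(10L, 40L), src_end0 = c(30L, 60L),
    tname_tgt = "t1", tgt_start0 = c(110L, 145L), tgt_end0 = c(130L, 165L),
    strand = "+", score = c(20, 20), stringsAsFactors = FALSE)
  chains <- list(list(id = 7L, blocks = blocks, score = 40))
  f <- withr::local_tempfile(fileext = ".chain")
  write_chain_file(chains, src, tgt, f)
  expect_equal(readLines(f),
               c("chain 40 chr1 100 + 10 60 t1 300 + 110 165 7",
                 "20\t10\t15", "20", ""))

  # '-' chain: q coordinates flip to the reverse strand
  nblocks <- data.frame(
    tname_src = "chr1", src_start0 = 10L, src_end0 = 30L,
    tname_tgt = "t1", tgt_start0 = 200L, tgt_end0 = 220L,
    strand = "-", score = 20, stringsAsFactors = FALSE)
  f2 <- withr::local_tempfile(fileext = ".chain")
  write_chain_file(list(list(id = 1L, blocks = nblocks, score = 20)),
                   src, tgt, f2)
  expect_equal(readLines(f2),
               c("chain 20 chr1 100 + 10 30 t1 300 - 80 100 1",
                 "20", ""))
})
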