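# synthetic_genomes: determinism, edit construction, truth-chain
# validity, fixture round trips.

test_that("the simulator is deterministic under a fixed seed", {
  cfg <- small_sim_config(seed = 8)
  a <- simulate_fixture(cfg)
  b <- simulate_fixture(cfg)
  expect_identical(a$source$sequences, b$source$sequences)
  expect_identical(a$target$sequences, b$target$sequences)
  expect_identical(a$markers, b$markers)
  expect_identical(a$truth, b$truth)
  expect_identical(a$genotypes_a$calls, b$genotypes_a$calls)
  c <- simulate_fixture(small_sim_config(seed = 9))
  expect_false(identical(a$source$sequences, c$source$sequences))
})

test_that("annotations are placed without overlap inside the genome", {
  cfg <- small_sim_config(seed = 10)
  src <- generate_source(cfg)
  ann <- rbind(src$genes, src$tes)
  expect_true(all(ann$end0 <= src$genome$lengths[ann$chrom]))
  expect_true(sum(ann$end0 - ann$start0) <=
                sum(as.numeric(src$genome$lengths)))
  for (chrom in unique(ann$chrom)) {
    a <- ann[ann$chrom == chrom, ]
    a <- a[order(a$start0), ]
    if (nrow(a) > 1) {
      expect_true(all(a$start0[-1] >= a$end0[-nrow(a)]))
    }
  }
  expect_equal(sum(src$tes$kind == "te_class_I") +
                 sum(src$tes$kind == "te_class_II"), nrow(src$tes))
})

test_that("an edit-free config reproduces the source exactly", {
  cfg <- sim_config(seed = 12,
                    chrom_lengths = c(chr1 = 50000L, chr2 = 30000L),
                    n_markers = 20,
                    fate_quotas = c(LIFTED = 20L, MULTI_MAPPED = 0L,
                                    UNMAPPED = 0L, ALLELE_DIVERGENT = 0L,
                                    LOW_IDENTITY = 0L),
                    background_sub_rate = 0, n_genes = 4L, n_tes = 4L,
                    anchor_scaffold = FALSE)
  src <- generate_source(cfg)
  der <- derive_target(src, cfg)
  expect_identical(der$genome$sequences, src$genome$sequences)
  for (ch in der$truth_chain) {
    expect_equal(nrow(ch$blocks), 1L)
    expect_equal(ch$blocks$src_start0, ch$blocks$tgt_start0)
  }
})

test_that("deletions leave source-side chain gaps; dups leave target gaps", {
  cfg <- small_sim_config(seed = 14)
  src <- generate_source(cfg)
  der <- derive_target(src, cfg)
  log <- der$edits_log
  # every deleted interval is absent from the block map
  for (i in seq_len(nrow(log$dels))) {
    d <- log$dels[i, ]
    mid <- (d$start0 + d$end0) %/% 2L
    expect_equal(lift_by_chain(d$chrom, mid, der$truth_chain),
                 "UNMAPPED")
  }
  # duplicated source segments still lift (backbone copy only)
  for (i in seq_len(nrow(log$dups))) {
    d <- log$dups[i, ]
    mid <- (d$src_start0 + d$src_end0) %/% 2L
    expect_true(is.list(lift_by_chain(d$chrom, mid, der$truth_chain)))
  }
  # target genome grew by the duplications and N gap, shrank by deletions
  expect_equal(sum(as.numeric(der$genome$lengths)),
               sum(as.numeric(src$genome$lengths)) +
                 nrow(log$dups) * cfg$dup_length -
                 nrow(log$dels) * cfg$deletion_length + 100)
})

test_that("an inverted chromosome flips all its truth blocks", {
  cfg <- small_sim_config(seed = 15, invert = TRUE)
  src <- generate_source(cfg)
  der <- derive_target(src, cfg)
  inv <- der$edits_log$inverted_chrom
  expect_equal(inv, "chr2")
  for (ch in der$truth_chain) {
    bl <- ch$blocks
    on_inv <- bl$tname_tgt == inv
    expect_true(all(bl$strand[on_inv] == "-"))
    expect_true(all(bl$strand[!on_inv] == "+"))
  }
})

test_that("truth chains reproduce every LIFTED marker's coordinate", {
  cfg <- small_sim_config(seed = 16)
  fix <- simulate_fixture(cfg)
  lifted <- fix$truth[fix$truth$expected_status == "LIFTED", ]
  mk <- fix$markers[match(lifted$marker_id, fix$markers$id), ]
  for (i in seq_len(nrow(lifted))) {
    hit <- lift_by_chain(mk$chrom[i], mk$pos0[i], fix$truth_chain)
    expect_equal(hit$tname, lifted$expected_tname[i])
    expect_equal(hit$tpos0, lifted$expected_tpos0[i])
    expect_equal(hit$strand, lifted$expected_strand[i])
    # and the planted base really is the marker's ref allele
    expect_equal(genome_base(fix$source, mk$chrom[i], mk$pos0[i]),
                 mk$ref[i])
  }
})

test_that("fate quotas are honoured and markers stay in bounds", {
  cfg <- small_sim_config(seed = 18)
  fix <- simulate_fixture(cfg)
  expect_equal(nrow(fix$markers), cfg$n_markers)
  tab <- table(fix$truth$expected_status)
  expect_equal(as.integer(tab[names(cfg$fate_quotas)]),
               as.integer(cfg$fate_quotas))
  expect_true(all(fix$markers$pos0 >= 0 &
                    fix$markers$pos0 <
                      fix$source$lengths[fix$markers$chrom]))
  expect_true(all(fix$markers$ref != fix$markers$alt))
})

test_that("a written fixture directory round-trips through the readers", {
  cfg <- small_sim_config(seed = 19)
  fix <- simulate_fixture(cfg)
  dir <- withr::local_tempdir()
  write_fixture_dir(fix, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "source.fa", "target.fa", "markers.tsv", "genes.gff3", "tes.bed",
    "truth.tsv", "truth.chain", "genotypes_a.tsv", "genotypes_b.tsv",
    "config.json")))))
  src <- load_genome(file.path(dir, "source.fa"))
  expect_identical(src$sequences, fix$source$sequences)
  mk <- load_markers(file.path(dir, "markers.tsv"), genome = src)
  expect_equal(mk$id, fix$markers$id)
  expect_equal(mk$pos0, fix$markers$pos0)
  genes <- load_intervals(file.path(dir, "genes.gff3"),
                          kind_filter = "gene")
  expect_equal(nrow(genes), nrow(fix$genes))
  expect_equal(genes$start0, fix$genes$start0)
  tes <- load_intervals(file.path(dir, "tes.bed"), te_names = TRUE)
  expect_equal(tes$kind, fix$tes$kind)
  gm <- load_genotypes(file.path(dir, "genotypes_a.tsv"))
  expect_identical(gm$calls, fix$genotypes_a$calls)
})

test_that("n_genes = 0 makes every marker intergenic", {
  cfg <- sim_config(seed = 22,
                    chrom_lengths = c(chr1 = 40000L),
                    n_markers = 10,
                    fate_quotas = c(LIFTED = 10L, MULTI_MAPPED = 0L,
                                    UNMAPPED = 0L, ALLELE_DIVERGENT = 0L,
                                    LOW_IDENTITY = 0L),
                    n_genes = 0L, n_tes = 0L, anchor_scaffold = FALSE)
  src <- generate_source(cfg)
  der <- derive_target(src, cfg)
  pl <- plant_markers(src, der, cfg)
  lab <- classify_region(pl$markers$chrom, pl$markers$pos0, src$genes)
  expect_true(all(lab$label == "intergenic"))
})
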