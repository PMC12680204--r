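# validation_filters: allele screen, strand-aware flank identity,
# cross-version comparison, cascade partition invariants.

res_row <- function(tname = "chr1", tpos0 = 0L, strand = "+",
                    status = "LIFTED") {
  data.frame(marker_id = "m", status = status, tname = tname,
             tpos0 = tpos0, strand = strand,
             target_base = NA_character_,
             observed_allele = NA_character_,
             identity_pct = NA_real_, stringsAsFactors = FALSE)
}

test_that("check_allele keeps on-pair bases and flags divergence", {
  tgt <- genome_assembly(c(chr1 = "AAGAA", chr2 = "AACAA", chr3 = "AANAA"),
                         "tgt")
  mk <- marker_table("m", "chr1", 2, "A", "G")[1, ]

  r <- check_allele(res_row("chr1", 2L, "+"), mk, tgt)
  expect_equal(r$status, "LIFTED")
  expect_equal(r$observed_allele, "G")
  expect_equal(r$target_base, "G")

  # '-' strand: target T reads as A after complementing -> on pair
  tgt2 <- genome_assembly(c(chr1 = "AATAA"), "tgt2")
  r2 <- check_allele(res_row("chr1", 2L, "-"), mk, tgt2)
  expect_equal(r2$status, "LIFTED")
  expect_equal(r2$observed_allele, "A")

  r3 <- check_allele(res_row("chr2", 2L, "+"), mk, tgt)
  expect_equal(r3$status, "ALLELE_DIVERGENT")

  # N matches nothing
  r4 <- check_allele(res_row("chr3", 2L, "+"), mk, tgt)
  expect_equal(r4$status, "ALLELE_DIVERGENT")
})

test_that("flank identity is 100 on a faithful copy and drops on edits", {
  set.seed(31)
  src <- tiny_genome(c(chr1 = 1000L), seed = 31, name = "src")
  pos <- 400L
  mk <- marker_table("m", "chr1", pos, genome_base(src, "chr1", pos),
                     setdiff(c("A", "C", "G", "T"),
                             genome_base(src, "chr1", pos))[1])[1, ]

  r <- validate_flank_identity(res_row("chr1", pos), mk, src, src)
  expect_equal(r$status, "LIFTED")
  expect_equal(r$identity_pct, 100)

  # one substitution in the target flank: 99/100 -> LOW_IDENTITY at 100%
  b <- strsplit(src$sequences[["chr1"]], "")[[1]]
  b[pos + 1 - 20] <- setdiff(c("A", "C", "G", "T"), b[pos + 1 - 20])[1]
  tgt <- genome_assembly(c(chr1 = paste(b, collapse = "")), "tgt")
  r2 <- validate_flank_identity(res_row("chr1", pos), mk, src, tgt)
  expect_equal(r2$status, "LOW_IDENTITY")
  expect_equal(r2$identity_pct, 99)

  # the same marker passes a 99% threshold
  r3 <- validate_flank_identity(res_row("chr1", pos), mk, src, tgt,
                                validation_params(identity_threshold_pct = 99))
  expect_equal(r3$status, "LIFTED")

  # reverse-complemented target chromosome: '-' orientation restores 100
  L <- src$lengths[["chr1"]]
  rc <- genome_assembly(c(chr1 = revcomp(src$sequences[["chr1"]])), "rc")
  r4 <- validate_flank_identity(res_row("chr1", L - 1L - pos, "-"),
                                mk, src, rc)
  expect_equal(r4$status, "LIFTED")
  expect_equal(r4$identity_pct, 100)
})

test_that("the SNP base is excluded by default but can be included", {
  src <- tiny_genome(c(chr1 = 500L), seed = 33, name = "src")
  pos <- 200L
  ref <- genome_base(src, "chr1", pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  mk <- marker_table("m", "chr1", pos, ref, alt)[1, ]
  # target carries the alternate allele, flanks untouched
  b <- strsplit(src$sequences[["chr1"]], "")[[1]]
  b[pos + 1] <- alt
  tgt <- genome_assembly(c(chr1 = paste(b, collapse = "")), "tgt")

  r <- validate_flank_identity(res_row("chr1", pos), mk, src, tgt)
  expect_equal(r$identity_pct, 100)
  expect_equal(r$status, "LIFTED")

  r2 <- validate_flank_identity(
    res_row("chr1", pos), mk, src, tgt,
    validation_params(exclude_snp_base = FALSE))
  expect_equal(r2$identity_pct, 100 * 100 / 101, tolerance = 1e-12)
  expect_equal(r2$status, "LOW_IDENTITY")
})

test_that("truncated flanks compare over the realised overlap only", {
  src <- tiny_genome(c(chr1 = 300L), seed = 35, name = "src")
  pos <- 10L  # only 10 bases of upstream flank exist
  ref <- genome_base(src, "chr1", pos)
  mk <- marker_table("m", "chr1", pos, ref,
                     setdiff(c("A", "C", "G", "T"), ref)[1])[1, ]
  r <- validate_flank_identity(res_row("chr1", pos), mk, src, src)
  expect_equal(r$identity_pct, 100)
  expect_equal(r$status, "LIFTED")
})

test_that("compare_versions and venn_counts partition the universe", {
  mkres <- function(ids, lifted) {
    data.frame(marker_id = ids,
               status = ifelse(lifted, "LIFTED", "UNMAPPED"),
               stringsAsFactors = FALSE)
  }
  ids <- sprintf("m%02d", 1:10)
  all_a <- mkres(ids, rep(TRUE, 10))
  expect_equal(as.vector(compare_versions(all_a, all_a)),
               c(10L, 0L, 0L, 0L))

  a <- mkres(ids, c(rep(TRUE, 3), rep(FALSE, 7)))
  b <- mkres(ids, c(rep(FALSE, 3), TRUE, TRUE, rep(FALSE, 5)))
  cv <- compare_versions(a, b, "v4", "v6")
  expect_equal(unname(cv["only_a"]), 3L)
  expect_equal(unname(cv["only_b"]), 2L)
  expect_equal(unname(cv["both"]), 0L)
  expect_equal(unname(cv["neither"]), 5L)
  expect_equal(sum(cv), 10L)

  set.seed(44)
  three <- list(v2 = mkres(ids, runif(10) < 0.5),
                v4 = mkres(ids, runif(10) < 0.5),
                v6 = mkres(ids, runif(10) < 0.5))
  vc <- venn_counts(three)
  expect_equal(nrow(vc), 8L)
  expect_equal(sum(vc$count), 10L)

  expect_error(compare_versions(a, mkres(sprintf("x%02d", 1:10), TRUE)),
               "universes")
})

test_that("the cascade yields exactly one final status per marker", {
  cfg <- small_sim_config(seed = 17)
  fix <- simulate_fixture(cfg)
  out <- run_liftover(fix$markers, fix$source, fix$target)
  r <- out$results
  expect_equal(nrow(r), nrow(fix$markers))
  expect_true(all(r$status %in% c("LIFTED", "UNMAPPED", "MULTI_MAPPED",
                                  "ALLELE_DIVERGENT", "LOW_IDENTITY",
                                  "GAP_AT_SITE")))
  expect_equal(sum(table(r$status)), nrow(fix$markers))
  # a marker that passed full validation has exactly equal windows
  ok <- which(r$status == "LIFTED" & r$identity_pct == 100 &
                r$strand == "+")[1]
  m <- fix$markers[ok, ]
  f <- 50L
  sw <- genome_subseq(fix$source, m$chrom, m$pos0 - f, m$pos0 + f + 1L)
  tw <- genome_subseq(fix$target, r$tname[ok], r$tpos0[ok] - f,
                      r$tpos0[ok] + f + 1L)
  # SNP base may legitimately differ; flanks must be identical
  expect_equal(substr(sw, 1, f), substr(tw, 1, f))
  expect_equal(substr(sw, f + 2, 2 * f + 1), substr(tw, f + 2, 2 * f + 1))
})
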