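# Pipeline orchestration: extract -> align -> classify -> lift ->
# validate, with chain-based rescue of markers lacking their own
# accepted alignment, plus the file-level driver used by the CLI.

#' Run the liftover cascade for a marker set
#'
#' For each marker: extract the flank query, align it, classify the
#' hits.  Uniquely aligned markers are lifted through their own column
#' map.  Collinear chains built from all uniquely accepted alignments
#' then rescue markers with no accepted hit (and markers whose SNP
#' column fell in an alignment gap); multi-mapped markers stay
#' `MULTI_MAPPED` — rescuing them would erase the ambiguity the status
#' reports.  Lifted markers finally pass the allele-divergence screen
#' and the strand-aware flank-identity validation, in that order.
#'
#' @param markers marker `data.frame`.
#' @param source,target `GenomeAssembly` objects.
#' @param align_p an [align_params()].
#' @param valid_p a [validation_params()].
#' @param max_gap chain gap bound (bp), see [build_chains()].
#' @param chain_fallback enable chain rescue (default `TRUE`).
#' @param index optional prebuilt [build_index()] of the target.
#' @return list with `results` (one row per marker: `marker_id`,
#'   `status`, `tname`, `tpos0`, `strand`, `lifted_ref`, `lifted_alt`,
#'   `target_base`, `observed_allele`, `identity_pct`, `provenance`),
#'   `chains`, and `log` (stage in/out counts).
#' @export
run_liftover <- function(markers, source, target,
                         align_p = align_params(),
                         valid_p = validation_params(),
                         max_gap = 10000, chain_fallback = TRUE,
                         index = NULL) {
  n <- nrow(markers)
  if (is.null(index)) index <- build_index(target, align_p$k)
  flank <- valid_p$flank

  res <- data.frame(
    marker_id = markers$id,
    status = rep("UNMAPPED", n),
    tname = NA_character_, tpos0 = NA_integer_, strand = NA_character_,
    lifted_ref = NA_character_, lifted_alt = NA_character_,
    target_base = NA_character_, observed_allele = NA_character_,
    identity_pct = NA_real_,
    provenance = NA_character_,
    stringsAsFactors = FALSE)

  queries <- vector("list", n)
  accepted <- list()
  for (i in seq_len(n)) {
    q <- extract_flank(markers[i, ], source, flank)
    queries[[i]] <- q
    alns <- align_flank(q, index, target, align_p)
    cls <- classify_hits(alns, align_p)
    if (cls$status == "MULTI_MAPPED") {
      res$status[i] <- "MULTI_MAPPED"
    } else if (cls$status == "UNIQUE") {
      accepted[[length(accepted) + 1L]] <-
        list(alignment = cls$alignment, query = q)
      hit <- map_snp_position(cls$alignment, q)
      if (is.list(hit)) {
        res$status[i] <- "LIFTED"
        res$tname[i] <- hit$tname
        res$tpos0[i] <- hit$tpos0
        res$strand[i] <- hit$strand
        res$provenance[i] <- "direct_alignment"
      } else {
        res$status[i] <- "GAP_AT_SITE"
      }
    }
  }
  log <- list(total = n,
              direct_lifted = sum(res$status == "LIFTED"),
              multi_mapped = sum(res$status == "MULTI_MAPPED"),
              gap_at_site = sum(res$status == "GAP_AT_SITE"),
              unaligned = sum(res$status == "UNMAPPED"))

  chains <- build_chains(accepted, max_gap = max_gap)
  if (chain_fallback) {
    rescue <- which(res$status %in% c("UNMAPPED", "GAP_AT_SITE"))
    for (i in rescue) {
      hit <- lift_by_chain(markers$chrom[i], markers$pos0[i], chains)
      if (is.list(hit)) {
        res$status[i] <- "LIFTED"
        res$tname[i] <- hit$tname
        res$tpos0[i] <- hit$tpos0
        res$strand[i] <- hit$strand
        res$provenance[i] <- "chain"
      }
    }
  }
  log$chain_rescued <- sum(res$provenance == "chain", na.rm = TRUE)
  log$initial_lifted <- sum(res$status == "LIFTED")

  lifted_rows <- which(res$status == "LIFTED")
  for (i in lifted_rows) {
    la <- lift_alleles(markers$ref[i], markers$alt[i], res$strand[i])
    res$lifted_ref[i] <- la$lifted_ref
    res$lifted_alt[i] <- la$lifted_alt
    r <- check_allele(res[i, ], markers[i, ], target)
    if (r$status == "LIFTED") {
      r <- validate_flank_identity(r, markers[i, ], source, target,
                                   valid_p)
    }
    res[i, ] <- r
  }
  log$allele_divergent <- sum(res$status == "ALLELE_DIVERGENT")
  log$low_identity <- sum(res$status == "LOW_IDENTITY")
  log$final_lifted <- sum(res$status == "LIFTED")

  list(results = res, chains = chains, log = log)
}

#' Compare pipeline results against simulator truth
#'
#' @param results results from [run_liftover()].
#' @param truth truth `data.frame` from [plant_markers()].
#' @return list with per-fate accuracy, overall accuracy, and the
#'   subset of mismatching marker ids.
#' @export
truth_recovery <- function(results, truth) {
  stopifnot(all(results$marker_id == truth$marker_id))
  ok_status <- results$status == truth$expected_status
  lift <- truth$expected_status == "LIFTED"
  ok_coord <- rep(NA, nrow(truth))
  ok_coord[lift] <- results$tname[lift] == truth$expected_tname[lift] &
    results$tpos0[lift] == truth$expected_tpos0[lift] &
    results$strand[lift] == truth$expected_strand[lift]
  by_fate <- vapply(split(ok_status, truth$expected_status), mean,
                    numeric(1))
  list(overall = mean(ok_status),
       by_fate = by_fate,
       coord_exact = mean(ok_coord[lift] & ok_status[lift]),
       mismatches = results$marker_id[!ok_status])
}

#' File-level pipeline driver
#'
#' Reads a JSON config (paths to source/target FASTA, marker table,
#' optional gene/TE annotations and genotype matrices, plus parameter
#' overrides), runs the cascade and writes every artefact: lifted VCF +
#' rejects, chain file, validation report TSV, summary JSON/TSV, and a
#' stage-count log.
#'
#' @param config path to a JSON file or an equivalent named list.
#' @param out_dir output directory.
#' @return the [run_liftover()] result list, invisibly (with `summary`
#'   attached).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  need <- c("source_fasta", "target_fasta", "markers")
  miss <- setdiff(need, names(config))
  if (length(miss) > 0) {
    stop("config is missing required field(s): ",
         paste(miss, collapse = ", "))
  }
  for (f in need) {
    if (!file.exists(config[[f]])) {
      stop("input file not found: ", config[[f]])
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  source <- load_genome(config$source_fasta, name = "source")
  target <- load_genome(config$target_fasta, name = "target")
  markers <- load_markers(config$markers, genome = source)
  getp <- function(name, default) {
    if (!is.null(config[[name]])) config[[name]] else default
  }
  align_p <- align_params(
    k = getp("k", 12), min_score = getp("min_score", 100),
    min_identity_pct = getp("min_identity", 98),
    mask_snp_base = getp("mask_snp_base", TRUE))
  valid_p <- validation_params(
    flank = getp("flank", 50),
    identity_threshold_pct = getp("validate_identity", 100))

  lift <- run_liftover(markers, source, target, align_p, valid_p,
                       max_gap = getp("max_gap", 10000))
  res <- lift$results

  write_lifted_vcf(res, markers, target,
                   file.path(out_dir, "lifted.vcf"),
                   file.path(out_dir, "rejects.tsv"))
  write_chain_file(lift$chains, source, target,
                   file.path(out_dir, "alignments.chain"))
  utils::write.table(res, file.path(out_dir, "validation_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  summary <- summarize_liftover(res, markers, source,
                                version_label = target$name)
  check_summary_consistency(summary, res, markers, source)
  utils::write.table(summary$table,
                     file.path(out_dir, "summary_by_chromosome.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  extras <- list()
  if (!is.null(config$genes) && file.exists(config$genes)) {
    genes <- load_intervals(config$genes, kind_filter = "gene")
    lab <- classify_region(markers$chrom, markers$pos0, genes,
                           near_window = getp("near_window", 5000))
    extras$regions <- summarize_regions(lab$label,
                                        total_markers = nrow(markers))
    utils::write.table(extras$regions,
                       file.path(out_dir, "regions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(config$tes) && file.exists(config$tes)) {
    tes <- load_intervals(config$tes, te_names = TRUE)
    failed <- res$status != "LIFTED"
    causes <- classify_failure(markers[failed, , drop = FALSE],
                               res[failed, , drop = FALSE], tes)
    extras$failure_causes <- summarize_failure_causes(causes)
    utils::write.table(extras$failure_causes,
                       file.path(out_dir, "failure_causes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(config$genotypes) && file.exists(config$genotypes)) {
    gm <- load_genotypes(config$genotypes)
    lifted_ids <- intersect(res$marker_id[res$status == "LIFTED"],
                            gm$marker_ids)
    extras$maf <- maf_table(gm, lifted_ids)
    utils::write.table(extras$maf, file.path(out_dir, "maf_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  jsonlite::write_json(
    list(log = lift$log,
         failures = as.list(summary$failures),
         strands = as.list(summary$strands)),
    file.path(out_dir, "pipeline_log.json"), auto_unbox = TRUE)

  lift$summary <- summary
  lift$extras <- extras
  invisible(lift)
}
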