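# Seeded simulator of source/target assembly pairs with a known edit
# structure, planted markers with truth fates, annotations and genotype
# matrices.  This is the test bed for the whole pipeline: every edit is
# placed disjointly (rejection sampling with generous margins) so each
# planted marker's fate has a single, unambiguous cause.
#
# Fate construction, given the pipeline's fixed thresholds
# (101 bp flank queries, min_score 100, SNP column masked):
#   LIFTED           untouched 101 bp window          -> unique perfect hit
#   MULTI_MAPPED     window inside a duplicated segment -> two tied hits
#   UNMAPPED         window inside a deleted segment    -> no hit, chain gap
#   ALLELE_DIVERGENT target SNP base mutated off-pair   -> lifted, then
#                    caught by the allele screen (flanks stay perfect)
#   LOW_IDENTITY     marker at a diverged-window edge, covered by a
#                    planted clean helper marker's chain block; the
#                    forced edge substitution sits inside the marker's
#                    +/-50 bp validation window but outside the helper's
#
# A marker strictly inside a diverged window could never be lifted at
# all (any target mismatch voids every accepted 101 bp query covering
# it), which is why LOW_IDENTITY fates use the edge geometry above.

#' Simulator configuration
#'
#' Defaults describe a desk-scale genome: three chromosomes (300, 200
#' and 150 kb) plus one 20 kb unplaced scaffold, 500 markers, and edit
#' quotas covering all five fates.
#'
#' @param seed root seed; all stages derive fixed sub-seeds from it.
#' @param chrom_lengths named integer vector of sequence lengths.
#' @param n_markers total planted markers.
#' @param fate_quotas named counts per fate
#'   (`LIFTED`, `MULTI_MAPPED`, `UNMAPPED`, `ALLELE_DIVERGENT`,
#'   `LOW_IDENTITY`); must sum to `n_markers`.
#' @param background_sub_rate per-base substitution probability outside
#'   edit footprints and marker windows.
#' @param dup_length segmental duplication length (bp).
#' @param deletion_length deletion length (bp).
#' @param diverged_window_length,diverged_sub_rate length and per-base
#'   substitution probability of diverged windows.
#' @param n_genes,n_tes annotation feature counts.
#' @param invert_one_chrom reverse-complement one target chromosome
#'   (`chr2`) for strand testing.
#' @param anchor_scaffold concatenate the scaffold into a chromosome
#'   (100 bp N gap) in the target, emulating a scaffold-free upgrade.
#' @param edge_margin keep edits this far from chromosome ends (bp).
#' @param flank flank half-width used by the pipeline (affects clearance
#'   margins).
#' @return a list of class `SimConfig`.
#' @export
sim_config <- function(seed = 1,
                       chrom_lengths = c(chr1 = 300000L, chr2 = 200000L,
                                         chr3 = 150000L,
                                         scaffold_1 = 20000L),
                       n_markers = 500,
                       fate_quotas = c(LIFTED = 400L, MULTI_MAPPED = 30L,
                                       UNMAPPED = 30L,
                                       ALLELE_DIVERGENT = 20L,
                                       LOW_IDENTITY = 20L),
                       background_sub_rate = 5e-4,
                       dup_length = 2000L,
                       deletion_length = 3000L,
                       diverged_window_length = 1000L,
                       diverged_sub_rate = 0.03,
                       n_genes = 60L, n_tes = 40L,
                       invert_one_chrom = FALSE,
                       anchor_scaffold = TRUE,
                       edge_margin = 500L,
                       flank = 50L) {
  stopifnot(sum(fate_quotas) <= n_markers)
  structure(list(seed = as.integer(seed),
                 chrom_lengths = chrom_lengths,
                 n_markers = as.integer(n_markers),
                 fate_quotas = fate_quotas,
                 background_sub_rate = background_sub_rate,
                 dup_length = as.integer(dup_length),
                 deletion_length = as.integer(deletion_length),
                 diverged_window_length = as.integer(diverged_window_length),
                 diverged_sub_rate = diverged_sub_rate,
                 n_genes = as.integer(n_genes), n_tes = as.integer(n_tes),
                 invert_one_chrom = isTRUE(invert_one_chrom),
                 anchor_scaffold = isTRUE(anchor_scaffold),
                 edge_margin = as.integer(edge_margin),
                 flank = as.integer(flank)),
            class = "SimConfig")
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# sample a length-`len` interval on one of `chroms`, at least `margin`
# away from every interval already in `reserved` (a list of two-column
# matrices per chrom) and `edge` from the ends; returns c(chrom_i, s0)
sample_slot <- function(lengths, reserved, len, margin, edge,
                        max_tries = 10000) {
  for (try in seq_len(max_tries)) {
    ci <- sample(length(lengths), 1, prob = as.numeric(lengths))
    L <- lengths[[ci]]
    if (L < len + 2 * edge) next
    s0 <- sample.int(L - len - 2 * edge, 1) + edge
    res <- reserved[[ci]]
    if (!is.null(res) && nrow(res) > 0) {
      clash <- any(s0 - margin < res[, 2] & res[, 1] < s0 + len + margin)
      if (clash) next
    }
    return(c(ci, s0))
  }
  stop("could not place an edit of length ", len,
       "; genome too crowded for the requested quotas")
}

#' Generate the source assembly with annotations
#'
#' Uniform-random DNA; gene and transposable-element intervals placed
#' without overlap on the chromosomes (classes I and II alternating for
#' TEs).  Fully reproducible from the config seed.
#'
#' @param config a [sim_config()].
#' @return list with `genome`, `genes`, `tes`.
#' @export
generate_source <- function(config) {
  set.seed(stage_seed(config$seed, 1L))
  seqs <- vapply(config$chrom_lengths, random_dna, character(1))
  genome <- genome_assembly(seqs, name = "source")
  chroms <- names(genome$sequences)[!genome$is_scaffold]
  lens <- config$chrom_lengths[chroms]
  reserved <- setNames(vector("list", length(chroms)), chroms)
  place <- function(n, len_range, maker) {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      len <- sample(len_range[1]:len_range[2], 1)
      slot <- sample_slot(lens, reserved, len, margin = 10L, edge = 100L)
      ci <- slot[1]; s0 <- slot[2]
      reserved[[ci]] <<- rbind(reserved[[ci]], c(s0, s0 + len))
      out[[i]] <- maker(chroms[ci], s0, s0 + len, i)
    }
    do.call(rbind, out)
  }
  genes <- if (config$n_genes > 0) {
    place(config$n_genes, c(500L, 3000L), function(chrom, s0, s1, i) {
      interval_table(chrom, s0, s1, name = sprintf("gene%03d", i),
                     strand = sample(c("+", "-"), 1), kind = "gene")
    })
  } else interval_table(character(0), integer(0), integer(0))[0, ]
  tes <- if (config$n_tes > 0) {
    place(config$n_tes, c(200L, 1000L), function(chrom, s0, s1, i) {
      cls <- if (i %% 2 == 1) "I" else "II"
      interval_table(chrom, s0, s1,
                     name = sprintf("%s_te%03d", cls, i),
                     kind = if (cls == "I") "te_class_I" else "te_class_II")
    })
  } else interval_table(character(0), integer(0), integer(0))[0, ]
  list(genome = genome, genes = genes, tes = tes)
}

#' Derive the target assembly by applying a planned edit structure
#'
#' Applies, in pairwise-disjoint regions: background substitutions;
#' segmental duplications (exact copies inserted elsewhere) sized to the
#' `MULTI_MAPPED` quota; deletions sized to the `UNMAPPED` quota;
#' off-pair single-base substitutions at designated marker sites
#' (`ALLELE_DIVERGENT` quota); diverged windows with forced edge
#' substitutions (`LOW_IDENTITY` quota); optional scaffold anchoring
#' into a chromosome (100 bp N gap) and optional whole-chromosome
#' reverse complement.
#'
#' @param source result of [generate_source()].
#' @param config the same [sim_config()].
#' @return list with `genome` (target), `truth_chain` (list of chains
#'   recording the exact collinear source-to-target block map; the
#'   duplicate copy of each duplication is deliberately not part of it),
#'   and `edits_log` (every planned edit, consumed by
#'   [plant_markers()]).
#' @export
derive_target <- function(source, config) {
  set.seed(stage_seed(config$seed, 2L))
  genome <- source$genome
  q <- config$fate_quotas
  flank <- config$flank
  margin <- 3L * flank + 10L   # clearance around every planned footprint
  chroms <- names(genome$sequences)[!genome$is_scaffold]
  lens <- genome$lengths[chroms]
  reserved <- setNames(vector("list", length(chroms)), chroms)
  reserve <- function(ci, s0, s1) {
    reserved[[ci]] <<- rbind(reserved[[ci]], c(s0, s1))
  }
  take_slot <- function(len) {
    slot <- sample_slot(lens, reserved, len, margin = margin,
                        edge = config$edge_margin)
    reserve(slot[1], slot[2], slot[2] + len)
    slot
  }

  # -- duplications (MULTI quota) ------------------------------------
  dup_cap <- max(1L, (config$dup_length - 2L * (flank + 2L)) %/% 101L)
  n_dup_markers <- as.integer(q[["MULTI_MAPPED"]])
  dups <- NULL
  remaining <- n_dup_markers
  while (remaining > 0) {
    slot <- take_slot(config$dup_length)
    ins <- take_slot(1L)   # insertion boundary, with full margin around
    take <- min(dup_cap, remaining)
    dups <- rbind(dups, data.frame(
      chrom = chroms[slot[1]], src_start0 = slot[2],
      src_end0 = slot[2] + config$dup_length,
      ins_chrom = chroms[ins[1]], ins_pos0 = ins[2],
      n_markers = take, stringsAsFactors = FALSE))
    remaining <- remaining - take
  }

  # -- deletions (UNMAPPED quota) ------------------------------------
  del_cap <- max(1L, (config$deletion_length - 2L * (flank + 2L)) %/% 101L)
  n_del_markers <- as.integer(q[["UNMAPPED"]])
  dels <- NULL
  remaining <- n_del_markers
  while (remaining > 0) {
    slot <- take_slot(config$deletion_length)
    take <- min(del_cap, remaining)
    dels <- rbind(dels, data.frame(
      chrom = chroms[slot[1]], start0 = slot[2],
      end0 = slot[2] + config$deletion_length,
      n_markers = take, stringsAsFactors = FALSE))
    remaining <- remaining - take
  }

  # -- diverged windows (LOW_IDENTITY quota; 2 edge markers each) ----
  n_low <- as.integer(q[["LOW_IDENTITY"]])
  n_div <- ceiling(n_low / 2)
  divs <- NULL
  low_left <- 0L
  if (n_div > 0) {
    for (i in seq_len(n_div)) {
      slot <- take_slot(config$diverged_window_length)
      use <- min(2L, n_low - (i - 1L) * 2L)
      divs <- rbind(divs, data.frame(
        chrom = chroms[slot[1]], start0 = slot[2],
        end0 = slot[2] + config$diverged_window_length,
        n_markers = use, stringsAsFactors = FALSE))
    }
  }

  # -- allele-divergent sites ----------------------------------------
  n_ad <- as.integer(q[["ALLELE_DIVERGENT"]])
  ad_sites <- NULL
  if (n_ad > 0) {
    for (i in seq_len(n_ad)) {
      slot <- take_slot(1L)
      ad_sites <- rbind(ad_sites, data.frame(
        chrom = chroms[slot[1]], pos0 = slot[2],
        stringsAsFactors = FALSE))
    }
  }

  # -- substitutions --------------------------------------------------
  subs <- list()
  other_base <- function(b, exclude = character(0)) {
    vapply(seq_along(b), function(i) {
      sample(setdiff(DNA_BASES, c(b[i], exclude)), 1)
    }, character(1))
  }
  # background: anywhere outside reserved footprints (+ margin)
  for (ci in seq_along(chroms)) {
    L <- lens[[ci]]
    pos <- which(runif(L) < config$background_sub_rate) - 1L
    res <- reserved[[ci]]
    if (!is.null(res) && length(pos) > 0) {
      keep <- !vapply(pos, function(p) {
        any(p >= res[, 1] - margin & p < res[, 2] + margin)
      }, logical(1))
      pos <- pos[keep]
    }
    pos <- pos[pos >= config$edge_margin & pos < L - config$edge_margin]
    if (length(pos) > 0) {
      from <- str_bases(genome$sequences[[chroms[ci]]])[pos + 1L]
      subs[[length(subs) + 1L]] <- data.frame(
        chrom = chroms[ci], pos0 = pos, from = from,
        to = other_base(from), kind = "background",
        stringsAsFactors = FALSE)
    }
  }
  # diverged windows: random interior plus forced first/last base
  if (!is.null(divs)) {
    for (i in seq_len(nrow(divs))) {
      d0 <- divs$start0[i]; d1 <- divs$end0[i]
      pos <- d0 + which(runif(d1 - d0) < config$diverged_sub_rate) - 1L
      pos <- sort(unique(c(pos, d0, d1 - 1L)))
      from <- str_bases(genome$sequences[[divs$chrom[i]]])[pos + 1L]
      subs[[length(subs) + 1L]] <- data.frame(
        chrom = divs$chrom[i], pos0 = pos, from = from,
        to = other_base(from), kind = "diverged",
        stringsAsFactors = FALSE)
    }
  }
  # allele-divergent sites: mutate to any base other than the source
  # base (the marker's alt allele is later chosen to avoid it too)
  if (!is.null(ad_sites)) {
    from <- vapply(seq_len(nrow(ad_sites)), function(i) {
      genome_base(genome, ad_sites$chrom[i], ad_sites$pos0[i])
    }, character(1))
    ad_sites$target_base <- other_base(from)
    subs[[length(subs) + 1L]] <- data.frame(
      chrom = ad_sites$chrom, pos0 = ad_sites$pos0, from = from,
      to = ad_sites$target_base, kind = "allele",
      stringsAsFactors = FALSE)
  }
  subs <- if (length(subs)) do.call(rbind, subs) else
    data.frame(chrom = character(0), pos0 = integer(0),
               from = character(0), to = character(0),
               kind = character(0), stringsAsFactors = FALSE)

  # -- assemble the target -------------------------------------------
  tgt_seqs <- list()
  truth_chain <- list()
  for (chrom in names(genome$sequences)) {
    raw <- charToRaw(genome$sequences[[chrom]])
    s <- subs[subs$chrom == chrom, , drop = FALSE]
    if (nrow(s) > 0) raw[s$pos0 + 1L] <- charToRaw(paste(s$to, collapse = ""))
    ev <- NULL
    if (!is.null(dels)) {
      d <- dels[dels$chrom == chrom, , drop = FALSE]
      if (nrow(d) > 0) {
        ev <- rbind(ev, data.frame(pos = d$start0, end = d$end0,
                                   type = "del", content = "",
                                   stringsAsFactors = FALSE))
      }
    }
    if (!is.null(dups)) {
      d <- dups[dups$ins_chrom == chrom, , drop = FALSE]
      if (nrow(d) > 0) {
        content <- vapply(seq_len(nrow(d)), function(i) {
          genome_subseq(genome, d$chrom[i], d$src_start0[i], d$src_end0[i])
        }, character(1))
        ev <- rbind(ev, data.frame(pos = d$ins_pos0, end = d$ins_pos0,
                                   type = "ins", content = content,
                                   stringsAsFactors = FALSE))
      }
    }
    parts <- character(0)
    blocks <- NULL
    cur_src <- 0L
    cur_tgt <- 0L
    L <- genome$lengths[[chrom]]
    if (!is.null(ev)) ev <- ev[order(ev$pos), , drop = FALSE]
    emit_segment <- function(upto) {
      if (upto > cur_src) {
        len <- upto - cur_src
        parts <<- c(parts, rawToChar(raw[(cur_src + 1L):upto]))
        blocks <<- rbind(blocks, data.frame(
          tname_src = chrom, src_start0 = cur_src, src_end0 = upto,
          tname_tgt = chrom, tgt_start0 = cur_tgt,
          tgt_end0 = cur_tgt + len, strand = "+", score = len,
          stringsAsFactors = FALSE))
        cur_tgt <<- cur_tgt + len
        cur_src <<- upto
      }
    }
    if (!is.null(ev)) {
      for (i in seq_len(nrow(ev))) {
        emit_segment(ev$pos[i])
        if (ev$type[i] == "del") {
          cur_src <- ev$end[i]
        } else {
          parts <- c(parts, ev$content[i])
          cur_tgt <- cur_tgt + nchar(ev$content[i])
        }
      }
    }
    emit_segment(L)
    tgt_seqs[[chrom]] <- paste(parts, collapse = "")
    truth_chain[[chrom]] <- list(id = length(truth_chain) + 1L,
                                 blocks = blocks, score = sum(blocks$score))
  }

  # -- scaffold anchoring --------------------------------------------
  anchor <- NULL
  scaffolds <- names(genome$sequences)[genome$is_scaffold]
  if (config$anchor_scaffold && length(scaffolds) > 0) {
    host <- chroms[length(chroms)]
    for (sc in scaffolds) {
      offset <- nchar(tgt_seqs[[host]]) + 100L
      tgt_seqs[[host]] <- paste0(tgt_seqs[[host]], strrep("N", 100L),
                                 tgt_seqs[[sc]])
      # rebase the scaffold's blocks onto the host chromosome
      bl <- truth_chain[[sc]]$blocks
      shift <- offset - 0L
      bl$tname_tgt <- host
      bl$tgt_start0 <- bl$tgt_start0 + shift
      bl$tgt_end0 <- bl$tgt_end0 + shift
      truth_chain[[sc]]$blocks <- bl
      tgt_seqs[[sc]] <- NULL
      anchor <- rbind(anchor, data.frame(scaffold = sc, host = host,
                                         offset = offset,
                                         stringsAsFactors = FALSE))
    }
  }

  # -- optional whole-chromosome inversion ---------------------------
  inverted <- NULL
  if (config$invert_one_chrom) {
    inverted <- chroms[min(2L, length(chroms))]
    Lt <- nchar(tgt_seqs[[inverted]])
    tgt_seqs[[inverted]] <- revcomp(tgt_seqs[[inverted]])
    for (nm in names(truth_chain)) {
      bl <- truth_chain[[nm]]$blocks
      flip <- bl$tname_tgt == inverted
      if (any(flip)) {
        t0 <- bl$tgt_start0[flip]; t1 <- bl$tgt_end0[flip]
        bl$tgt_start0[flip] <- Lt - t1
        bl$tgt_end0[flip] <- Lt - t0
        bl$strand[flip] <- ifelse(bl$strand[flip] == "+", "-", "+")
        truth_chain[[nm]]$blocks <- bl
      }
    }
  }

  target <- genome_assembly(unlist(tgt_seqs), name = "target")
  edits_log <- list(subs = subs, dups = dups, dels = dels, divs = divs,
                    ad_sites = ad_sites, anchor = anchor,
                    inverted_chrom = inverted, margin = margin)
  list(genome = target, truth_chain = unname(truth_chain),
       edits_log = edits_log)
}

#' Plant markers with known truth fates
#'
#' Places markers so that each fate has a single cause (see the file
#' header for the construction), assigns `ref` = source base and a
#' random distinct `alt`, and records one `TruthRecord` per marker with
#' the expected fate (and, for `LIFTED`, the expected target coordinate
#' obtained through the truth chain).
#'
#' @param source result of [generate_source()].
#' @param derived result of [derive_target()].
#' @param config the same [sim_config()].
#' @return list with `markers` (marker `data.frame`) and `truth`
#'   (data.frame: `marker_id`, `expected_status`, `expected_tname`,
#'   `expected_tpos0`, `expected_strand`).
#' @export
plant_markers <- function(source, derived, config) {
  set.seed(stage_seed(config$seed, 3L))
  genome <- source$genome
  log <- derived$edits_log
  flank <- config$flank
  q <- config$fate_quotas

  # dirty mask per chromosome: positions a clean marker window may not
  # touch (any substitution, any structural footprint or junction)
  dirty <- lapply(genome$sequences, function(s) logical(nchar(s)))
  mark <- function(chrom, lo, hi) {  # 0-based inclusive bounds, clipped
    L <- genome$lengths[[chrom]]
    lo <- max(0L, lo); hi <- min(L - 1L, hi)
    if (hi >= lo) dirty[[chrom]][(lo + 1L):(hi + 1L)] <<- TRUE
  }
  if (nrow(log$subs) > 0) {
    for (i in seq_len(nrow(log$subs))) {
      mark(log$subs$chrom[i], log$subs$pos0[i], log$subs$pos0[i])
    }
  }
  if (!is.null(log$dups)) {
    for (i in seq_len(nrow(log$dups))) {
      mark(log$dups$chrom[i], log$dups$src_start0[i] - 1L,
           log$dups$src_end0[i])
      mark(log$dups$ins_chrom[i], log$dups$ins_pos0[i] - 1L,
           log$dups$ins_pos0[i])
    }
  }
  if (!is.null(log$dels)) {
    for (i in seq_len(nrow(log$dels))) {
      mark(log$dels$chrom[i], log$dels$start0[i] - 1L, log$dels$end0[i])
    }
  }
  if (!is.null(log$divs)) {
    for (i in seq_len(nrow(log$divs))) {
      mark(log$divs$chrom[i], log$divs$start0[i], log$divs$end0[i] - 1L)
    }
  }

  rows <- list()
  truth <- list()
  add_marker <- function(chrom, pos0, status, alt_exclude = character(0),
                         claim_window = TRUE) {
    ref <- genome_base(genome, chrom, pos0)
    alt <- sample(setdiff(DNA_BASES, c(ref, alt_exclude)), 1)
    exp_t <- NA_character_; exp_p <- NA_integer_; exp_s <- NA_character_
    if (status == "LIFTED") {
      hit <- lift_by_chain(chrom, pos0, derived$truth_chain)
      stopifnot(is.list(hit))
      exp_t <- hit$tname; exp_p <- hit$tpos0; exp_s <- hit$strand
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = chrom, pos0 = pos0, ref = ref, alt = alt,
      stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <<- data.frame(
      expected_status = status, expected_tname = exp_t,
      expected_tpos0 = exp_p, expected_strand = exp_s,
      stringsAsFactors = FALSE)
    if (claim_window) mark(chrom, pos0 - flank - 1L, pos0 + flank + 1L)
  }

  spread_positions <- function(s0, s1, n) {
    # n positions with full flanks inside [s0, s1)
    lo <- s0 + flank + 1L
    hi <- s1 - flank - 2L
    stopifnot(hi >= lo, n >= 1)
    as.integer(round(seq(lo, hi, length.out = n)))
  }

  if (!is.null(log$dups)) {
    for (i in seq_len(nrow(log$dups))) {
      for (p in spread_positions(log$dups$src_start0[i],
                                 log$dups$src_end0[i],
                                 log$dups$n_markers[i])) {
        add_marker(log$dups$chrom[i], p, "MULTI_MAPPED",
                   claim_window = FALSE)
      }
    }
  }
  if (!is.null(log$dels)) {
    for (i in seq_len(nrow(log$dels))) {
      for (p in spread_positions(log$dels$start0[i], log$dels$end0[i],
                                 log$dels$n_markers[i])) {
        add_marker(log$dels$chrom[i], p, "UNMAPPED", claim_window = FALSE)
      }
    }
  }
  if (!is.null(log$ad_sites)) {
    for (i in seq_len(nrow(log$ad_sites))) {
      add_marker(log$ad_sites$chrom[i], log$ad_sites$pos0[i],
                 "ALLELE_DIVERGENT",
                 alt_exclude = log$ad_sites$target_base[i])
    }
  }
  n_helpers <- 0L
  if (!is.null(log$divs)) {
    for (i in seq_len(nrow(log$divs))) {
      d0 <- log$divs$start0[i]; d1 <- log$divs$end0[i]
      chrom <- log$divs$chrom[i]
      # left edge: helper's window [d0-101, d0-1] is clean; the marker
      # sits inside the helper's block with the forced d0 substitution
      # inside its own +/-50 bp window
      add_marker(chrom, d0 - flank - 1L, "LIFTED")            # helper
      add_marker(chrom, d0 - flank %/% 2L, "LOW_IDENTITY",
                 claim_window = FALSE)
      n_helpers <- n_helpers + 1L
      if (log$divs$n_markers[i] >= 2L) {
        add_marker(chrom, d1 + flank, "LIFTED")               # helper
        add_marker(chrom, d1 + flank %/% 2L, "LOW_IDENTITY",
                   claim_window = FALSE)
        n_helpers <- n_helpers + 1L
      }
    }
  }

  # remaining LIFTED markers at random clean positions
  n_lifted_left <- as.integer(q[["LIFTED"]]) - n_helpers
  stopifnot(n_lifted_left >= 0)
  lens <- genome$lengths
  placed <- 0L
  tries <- 0L
  while (placed < n_lifted_left) {
    tries <- tries + 1L
    if (tries > 100L * n_lifted_left) {
      stop("could not place clean markers; genome too crowded")
    }
    ci <- sample(length(lens), 1, prob = as.numeric(lens))
    chrom <- names(lens)[ci]
    L <- lens[[ci]]
    p <- sample.int(L - 2L * (flank + 2L), 1) + flank + 1L
    win <- (p - flank):(p + flank) + 1L
    if (any(dirty[[chrom]][win])) next
    add_marker(chrom, p, "LIFTED")
    placed <- placed + 1L
  }

  mk <- do.call(rbind, rows)
  tr <- do.call(rbind, truth)
  ord <- order(mk$chrom, mk$pos0)
  mk <- mk[ord, , drop = FALSE]
  tr <- tr[ord, , drop = FALSE]
  ids <- sprintf("M%05d", seq_len(nrow(mk)))
  markers <- marker_table(ids, mk$chrom, mk$pos0, mk$ref, mk$alt,
                          genome = genome)
  truth <- data.frame(marker_id = ids, tr, stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  list(markers = markers, truth = truth)
}

#' Simulate diploid genotype matrices with a prescribed MAF spectrum
#'
#' Each marker draws a bin from `maf_spectrum`, a true MAF uniformly
#' within the bin (`Monomorphic` fixes 0), orients it to an alternate
#' allele frequency (coin flip), and samples diploid genotypes
#' binomially (2 trials).  A missing rate may knock out calls.
#'
#' @param markers marker `data.frame` (ids are reused).
#' @param n_accessions number of accessions (columns).
#' @param maf_spectrum named weights over the bins of [maf_bins()];
#'   the default mirrors a diversity-collection spectrum dominated by
#'   rare and monomorphic markers.
#' @param seed RNG seed.
#' @param missing_rate per-call missing probability.
#' @return list with `gm` (a [genotype_matrix()]) and `true_maf`.
#' @export
simulate_genotypes <- function(markers, n_accessions = 100,
                               maf_spectrum = NULL, seed = 1,
                               missing_rate = 0.01) {
  set.seed(stage_seed(seed, 4L))
  if (is.null(maf_spectrum)) {
    maf_spectrum <- c(Monomorphic = 0.1833, "<0.01" = 0.1955,
                      "0.01~0.05" = 0.1386, "0.05~0.10" = 0.1031,
                      "0.10~0.20" = 0.1460, "0.20~0.30" = 0.0885,
                      "0.30~0.40" = 0.0769, "0.40>" = 0.0681)
  }
  stopifnot(all(names(maf_spectrum) %in% MAF_BIN_LABELS),
            abs(sum(maf_spectrum) - 1) < 0.01)
  bins <- maf_bins()
  n <- nrow(markers)
  lab <- sample(names(maf_spectrum), n, replace = TRUE,
                prob = maf_spectrum)
  row <- match(lab, bins$label)
  lower <- pmax(bins$lower[row], 1e-3)
  upper <- bins$upper[row]
  true_maf <- ifelse(lab == "Monomorphic", 0,
                     runif(n, lower, pmax(lower, upper - 1e-6)))
  p_alt <- ifelse(runif(n) < 0.5, true_maf, 1 - true_maf)
  calls <- matrix(rbinom(n * n_accessions, 2L,
                         rep(p_alt, n_accessions)),
                  nrow = n, ncol = n_accessions)
  if (missing_rate > 0) {
    calls[runif(n * n_accessions) < missing_rate] <- -1L
  }
  gm <- genotype_matrix(calls, marker_ids = markers$id,
                        accession_ids = sprintf("acc%04d",
                                                seq_len(n_accessions)))
  list(gm = gm, true_maf = true_maf)
}

#' Run the whole simulator
#'
#' Convenience wrapper: source, target, planted markers, truth, and two
#' genotype collections.
#'
#' @param config a [sim_config()].
#' @param n_accessions_a,n_accessions_b collection sizes.
#' @return list with all simulator artefacts.
#' @export
simulate_fixture <- function(config = sim_config(),
                             n_accessions_a = 100,
                             n_accessions_b = 100) {
  src <- generate_source(config)
  der <- derive_target(src, config)
  pl <- plant_markers(src, der, config)
  ga <- simulate_genotypes(pl$markers, n_accessions_a,
                           seed = stage_seed(config$seed, 41L))
  gb <- simulate_genotypes(pl$markers, n_accessions_b,
                           seed = stage_seed(config$seed, 42L))
  list(config = config, source = src$genome, genes = src$genes,
       tes = src$tes, target = der$genome,
       truth_chain = der$truth_chain, edits_log = der$edits_log,
       markers = pl$markers, truth = pl$truth,
       genotypes_a = ga$gm, genotypes_b = gb$gm)
}

#' Write a fixture directory
#'
#' Emits `source.fa`, `target.fa`, `markers.tsv`, `genes.gff3`,
#' `tes.bed`, `truth.tsv`, `truth.chain`, `genotypes_a.tsv`,
#' `genotypes_b.tsv` and `config.json`.
#'
#' @param fix result of [simulate_fixture()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_dir <- function(fix, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genome(fix$source, file.path(dir, "source.fa"))
  write_genome(fix$target, file.path(dir, "target.fa"))
  write_markers(fix$markers, file.path(dir, "markers.tsv"))
  write_gff3_genes(fix$genes, file.path(dir, "genes.gff3"))
  write_intervals_bed(fix$tes, file.path(dir, "tes.bed"))
  utils::write.table(fix$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_chain_file(fix$truth_chain, fix$source, fix$target,
                   file.path(dir, "truth.chain"))
  write_genotypes(fix$genotypes_a, file.path(dir, "genotypes_a.tsv"))
  write_genotypes(fix$genotypes_b, file.path(dir, "genotypes_b.tsv"))
  cfg <- fix$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# minimal GFF3 gene emitter (1-based inclusive, as the format requires)
write_gff3_genes <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes) > 0) {
    writeLines(sprintf("%s\tflanklift\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       genes$chrom, genes$start0 + 1L, genes$end0,
                       ifelse(genes$strand %in% c("+", "-"),
                              genes$strand, "."),
                       genes$name), con)
  }
  invisible(path)
}
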