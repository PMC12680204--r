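---
title: "Methods: flanking-sequence liftover of array markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flanking-sequence liftover of array markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Overview

`flanklift` transfers SNP-array marker coordinates and alleles from a
source genome assembly to a target assembly using only sequence
homology of the markers' flanks.  The design assumption is the one that
makes array liftover different from general coordinate liftover: each
marker is a *point* with a known allele pair, interrogated by a probe
whose specificity lives in roughly ±50 bp of flanking sequence.  If
that window cannot be located uniquely and near-perfectly in the target
assembly, the genotype calls attached to the marker should not be
carried over — a wrong-but-confident coordinate is worse than a
reported failure.  The pipeline therefore classifies every marker into
exactly one fate:

* `LIFTED` — unique location, allele-consistent, flanks 100% identical;
* `MULTI_MAPPED` — two or more equally good target loci;
* `UNMAPPED` — no acceptable target locus and no covering chain block;
* `ALLELE_DIVERGENT` — located, but the target base matches neither
  array allele;
* `LOW_IDENTITY` — located, but the ±50 bp flanks differ from the
  source;
* `GAP_AT_SITE` — the SNP column fell into an alignment gap
  (diagnostic; rare).

## Alignment model

Flank queries are `up + SNP + down` with up to 50 bp per side
(truncated at sequence ends).  The aligner is seed-and-extend:

1. every overlapping k-mer (default `k = 12`, step 1) of the target's
   forward strand is indexed; k-mers containing `N` are skipped;
2. exact seed hits are collected for the query and its reverse
   complement (reverse-strand hits are found by aligning the
   reverse-complemented query against the forward index);
3. seeds sharing target sequence, strand and diagonal (±5 by default)
   are clustered, and each cluster is extended by a banded local
   dynamic program over the implied target window (band half-width 10);
4. alignments are kept when `score ≥ 100` *and* `identity ≥ 98%`, then
   deduplicated at ≥50% reciprocal target-span overlap (higher score
   wins).

Scoring is deliberately simple and PSL-like: match `+1`, mismatch `−1`,
gap opening `−1`, gap extension free; `N` never matches;
`identity = 100 × matches / (matches + mismatches + gap bases)`.
`score` and `identity` are recomputed in R from the alignment column
map, so the compiled kernel cannot silently disagree with the stated
definitions.  On a full 101 bp query, `min_score = 100` admits only a
perfect hit — that is intentional: the thresholds, not the seeding, decide
acceptance, and truncated flank queries (markers near sequence ends)
fail by construction rather than being lifted with reduced evidence.

### The SNP column is masked during alignment

One scoring detail matters more than it looks.  If the SNP base itself
is scored like any other column, a marker whose target assembly carries
the *other* allele — or a diverged base — has at best
`score = 100 − 1 − 1 = 99 < 100` and can never be aligned; worse,
because chain blocks are exactly the spans of accepted 101 bp queries,
no chain built from flank alignments can cover a position within 50 bp
of any target mismatch, so such markers could never be lifted at all
and the allele-divergence screen would be unreachable dead code.  The
aligner therefore scores the query's SNP column as neutral by default
(`mask_snp_base = TRUE` in `align_params()`): it contributes neither
match nor mismatch nor identity denominator, mirroring
`exclude_snp_base` in the validation step.  A clean flank then scores
exactly 100 and passes; the allele screen afterwards decides whether
the target base is on-pair.  Set `mask_snp_base = FALSE` for plain
sequence alignment semantics (a perfect 101 bp query then scores 101).

## Chains and rescue

Ungapped sub-blocks of all uniquely accepted alignments are sorted by
source coordinate and greedily linked into collinear chains: same
source/target sequence and strand, source and target gaps each at most
`max_gap` (10 kb), monotone coordinates.  Overlapping blocks from
overlapping flank queries are merged when they agree on the
source-to-target offset; a conflicting overlap drops the incoming
block.  Chains are written in UCSC chain format so external tools can
consume them.

Markers with no accepted alignment of their own (`UNMAPPED` after
classification, plus `GAP_AT_SITE`) are lifted through a covering chain
block when one exists, highest-scoring chain first.  Two deliberate
choices here:

* **No interpolation.**  A position falling between the blocks of a
  chain has no defined image and stays `UNMAPPED`.
* **`MULTI_MAPPED` is terminal.**  Rescuing multi-mapped markers
  through chains would silently erase the ambiguity the status exists
  to report, so the chain fallback applies only to markers with zero
  accepted hits.  Direct alignment always takes precedence over chain
  projection when both exist.

## Validation

`check_allele` runs first: the target base at the lifted position
(complemented on `−` strand) must be one of the marker's two alleles;
`N` matches nothing.  `validate_flank_identity` then compares up to
50 bp per side base-by-base in the mapped orientation, over the overlap
of the realised flank lengths — truncation at sequence ends is not
penalised, since that would conflate edge effects with divergence.  The
SNP base is excluded by default (the site legitimately differs when the
target carries the alternate allele); the threshold is 100% identity.
Allele screening before identity screening keeps the two failure
categories disjoint and in a fixed order, so stage counts form a clean
cascade: filters only downgrade, never resurrect.

## Annotation and failure causes

Positions are `genic` (inside a gene), `near_genic` (nearest gene
boundary within 5 kb, boundary inclusive; refined to
`upstream`/`downstream` by the nearest gene's strand on request) or
`intergenic`.  Nearest-gene ties break to the smaller start coordinate,
then to `upstream`.  Failure causes are assigned by fixed priority —
retrotransposon (class I) > DNA transposon (class II) > low-identity
window > other — because published failure taxonomies present these as
mutually exclusive counts and retrotransposons are the dominant cause.
Low-identity windows come from tiling the source genome (1 kb windows),
lifting each window midpoint through the chains and computing
base-identity in the mapped orientation; a window qualifies strictly
below the threshold (95% for cause tables, 90% for coarser divergence
tracks), and unliftable windows qualify too.  Marker-vs-interval
overlap uses the marker point by default; a ±flank window is available
via `flank_window`.

## MAF statistics

Allele counting is standard: heterozygote contributes one alternate
allele, missing genotypes leave the denominator,
`MAF = min(f, 1 − f)`.  Spectrum bins follow array-summary convention:
`Monomorphic` is exactly 0, `<0.01` is open `(0, 0.01)`, middle bins
are `[lower, upper)`, and — since the printed convention does not say
where exactly 0.40 belongs — `0.30~0.40` includes its upper bound, so
`0.40>` is `(0.40, 0.5]`.  Table percentages use each collection's own
lifted-marker total as denominator, rounded half-up at two decimals
(base R's banker's rounding would disagree with printed tables at exact
halves).

For estimator calibration the test suite uses the analytic standard
error of a *single* estimate, `sqrt(p(1−p)/(2n))`.  At `p = 0.5` the
folded estimator `min(f, 1−f)` is biased low by `E|f − 0.5|` (about
0.013 at `n = 500`), which is far inside one single-replicate SE but
many SEs of the mean over 200 replicates; calibration against the
single-replicate SE is the meaningful check for a folded estimator at
the boundary.

## What the simulator emulates — and what it does not

`sim_config()` describes a desk-scale genome: three chromosomes
(300/200/150 kb) plus a 20 kb unplaced scaffold, 500 markers, and edits
that each produce exactly one fate: background substitutions at
5×10⁻⁴/bp away from everything else, exact segmental duplications
(2 kb) for `MULTI_MAPPED`, deletions (3 kb) for `UNMAPPED`, off-pair
point substitutions for `ALLELE_DIVERGENT`, 1 kb diverged windows
(3%/bp) for `LOW_IDENTITY`, scaffold-into-chromosome anchoring with a
100 bp `N` gap, and optional whole-chromosome reverse complement for
strand tests.  Edits are placed disjointly by rejection sampling with
generous margins so every truth label has a single cause, and all
randomness derives from one root seed through fixed stage offsets.

Two construction details are worth knowing when reading the tests:

* duplications are *exact* copies, so both loci tie on score and the
  margin-0 rule guarantees `MULTI_MAPPED` deterministically;
* a marker strictly inside a diverged window could never be lifted by
  any path (each of its covering 101 bp queries contains a mismatch),
  so planted `LOW_IDENTITY` markers sit at a window's edge, covered by
  the chain block of a planted clean helper marker, with a forced
  substitution at the window edge inside the marker's ±50 bp validation
  window but outside the helper's.

A green truth-recovery test therefore establishes that the pipeline
implements its stated rules exactly on unambiguous, disjoint events.
It does **not** establish performance on real genomes, where causes
confound: nested repeats, paleopolyploid duplication at 95–99%
identity, indel-rich divergence, gaps in either assembly, and probe
sequences that were never exactly the reference flank.  The simulator's
uniform-random DNA also understates spurious seed hits relative to a
repeat-rich plant genome.

## Numerical and degenerate-input choices

* All internal coordinates are 0-based half-open; conversion happens
  only at I/O boundaries (BED native, VCF/GFF ±1).
* Percentages: half-up rounding at 2 decimals, with a 10⁻⁹ epsilon
  against floating-point representation at exact halves.
* Multi-map margin is 0 (only exact score ties); alignment sort ties
  break by target name then start.
* `N` is allowed in assemblies; it never matches, and a target `N` at
  the SNP site is `ALLELE_DIVERGENT`.
* Zero comparable validation positions → `LOW_IDENTITY` with identity
  0; zero-column alignments are an error.
* The VCF writer emits `REF` as the base the target genome actually
  carries (swapping the pair and flagging `SWAP` when the target holds
  the alternate allele), so emitted records always agree with the
  target FASTA; markers lifted to `−` strand emit the complemented
  pair.
* Scaffold detection defaults to the name prefix `scaffold`
  (case-insensitive), overridable with an explicit list.

## Known limitations

* The aligner is a local aligner with free gap extension; with very
  permissive thresholds a "best" alignment may chain distant segments
  through a single cheap gap.  At the pipeline's defaults
  (`min_score = 100` on 101 bp queries) this cannot influence results,
  and the oracle-equality test exercises the permissive regime
  explicitly with a band wide enough to cover the full window.
* Chains are built from marker flank alignments only; coverage away
  from markers is sparse by construction, and `scan_low_identity` run
  on pipeline chains (rather than a simulator truth chain) reports
  unliftable windows as low-identity.
* Translated/spliced alignment, repeat masking during seeding, and
  net/chain hierarchies are out of scope, as are organelle-genome
  special cases.
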