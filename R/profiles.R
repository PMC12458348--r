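#' Anchor configuration for footprint assignment
#'
#' A footprint is reduced to a single transcript coordinate (its anchor).
#' The ribosomal P-site starts 12 nt and the A-site 15 nt downstream of the
#' footprint 5' end (position 0), so during termination a read whose 5' end
#' sits 15 nt upstream of the stop codon has the stop codon in its A site.
#'
#' @param mode `"five_prime"`, `"psite"`, or `"asite"`.
#' @param psite_offset,asite_offset Offsets in nt from the 5' end to the
#'   first nt of the P-site / A-site codon.
#' @return An `anchor_config` list.
#' @export
anchor_config <- function(mode = c("five_prime", "psite", "asite"),
                          psite_offset = 12L, asite_offset = 15L) {
  mode <- match.arg(mode)
  stopifnot(psite_offset >= 0L, asite_offset >= 0L)
  structure(list(mode = mode, psite_offset = as.integer(psite_offset),
                 asite_offset = as.integer(asite_offset)),
            class = "anchor_config")
}

#' Assign anchor coordinates to reads
#'
#' @param reads Read data.frame (see [load_alignments()]).
#' @param anchor An [anchor_config()].
#' @return Integer vector of anchor coordinates (one per read). Anchors are
#'   not bounds-checked here; [build_profile()] drops anchors that fall
#'   beyond the transcript end.
#' @export
assign_anchor <- function(reads, anchor = anchor_config()) {
  off <- switch(anchor$mode,
                five_prime = 0L,
                psite = anchor$psite_offset,
                asite = anchor$asite_offset)
  as.integer(reads$five_prime) + off
}

#' Per-nucleotide coverage profile
#'
#' @param transcript_id Transcript identifier.
#' @param counts Numeric vector, one entry per transcript nt, all `>= 0`.
#' @param anchor Anchor mode used to build the profile.
#' @param length_range Optional `c(min, max)` read-length filter used.
#' @return A `coverage_profile` object.
#' @export
coverage_profile <- function(transcript_id, counts, anchor = "five_prime",
                             length_range = NULL) {
  stopifnot(all(counts >= 0))
  structure(list(transcript_id = transcript_id, counts = as.numeric(counts),
                 anchor = anchor, length_range = length_range),
            class = "coverage_profile")
}

#' Build a coverage profile from reads
#'
#' Each read passing the optional length filter contributes a single count at
#' its anchor position; anchors that fall outside `[0, length)` of the
#' transcript are dropped (a read whose footprint extends past the 3' end is
#' kept as long as its anchor is in range).
#'
#' @param reads Read data.frame; only rows matching the transcript are used.
#' @param transcript A [transcript_model()].
#' @param anchor An [anchor_config()].
#' @param length_range Optional `c(min, max)` inclusive read-length filter.
#' @return A [coverage_profile()].
#' @export
build_profile <- function(reads, transcript, anchor = anchor_config(),
                          length_range = NULL) {
  reads <- reads[reads$transcript_id == transcript$transcript_id, ,
                 drop = FALSE]
  if (!is.null(length_range)) {
    reads <- reads[reads$length >= length_range[1] &
                     reads$length <= length_range[2], , drop = FALSE]
  }
  pos <- assign_anchor(reads, anchor)
  pos <- pos[pos >= 0L & pos < transcript$length]
  counts <- tabulate(pos + 1L, nbins = transcript$length)
  coverage_profile(transcript$transcript_id, counts, anchor$mode, length_range)
}

#' Transcript-level coverage filter
#'
#' An mRNA enters metagene/pausing analyses only if its CDS carries at least
#' `min_reads` counts and at least a fraction `min_coverage` of CDS positions
#' have non-zero counts. Both thresholds are inclusive (exactly 16 reads and
#' exactly 10% coverage pass under the defaults).
#'
#' @param profile A [coverage_profile()].
#' @param transcript The matching [transcript_model()].
#' @param min_reads Minimum CDS read total (default 16).
#' @param min_coverage Minimum fraction of covered CDS positions (default 0.10).
#' @return Logical scalar.
#' @export
passes_cds_filters <- function(profile, transcript, min_reads = 16,
                               min_coverage = 0.10) {
  cds <- profile$counts[cds_positions(transcript) + 1L]
  sum(cds) >= min_reads && mean(cds > 0) >= min_coverage
}

#' Normalize a profile by its mean CDS density
#'
#' Divides every position by (total CDS counts / CDS length), so the mean of
#' the normalized values over CDS positions is exactly 1. This factors out
#' differential mRNA abundance and translation efficiency before aggregation.
#'
#' @inheritParams passes_cds_filters
#' @return A [coverage_profile()] of normalized densities.
#' @export
normalize_by_cds <- function(profile, transcript) {
  cds <- profile$counts[cds_positions(transcript) + 1L]
  m <- sum(cds) / length(cds)
  if (m == 0) stop("cannot normalize: zero CDS counts on ",
                   transcript$transcript_id)
  out <- profile
  out$counts <- profile$counts / m
  out
}

#' Metagene aggregation around the start or stop codon
#'
#' Averages CDS-normalized densities at fixed distances from an anchor codon
#' across transcripts. The anchor codon's first nt is offset 0: the start
#' codon (`align_to = "start"`) or the stop codon (`align_to = "stop"`).
#' A transcript contributes to offset `d` only when position `anchor + d`
#' lies within its sequence, so per-offset denominators can differ near the
#' edges of short transcripts.
#'
#' @param profiles List of normalized, filter-passing [coverage_profile()]s.
#' @param transcripts Named list of [transcript_model()]s.
#' @param align_to `"start"` or `"stop"`.
#' @param offsets Integer vector of offsets relative to the anchor codon's
#'   first nt (e.g. `-50:50`).
#' @return data.frame with columns `offset`, `mean_density`, `n`; attributes
#'   `align_to`, `n_transcripts`, `anchor`, `length_range`.
#' @export
metagene_aggregate <- function(profiles, transcripts,
                               align_to = c("stop", "start"),
                               offsets = -50:50) {
  align_to <- match.arg(align_to)
  if (length(profiles) == 0) stop("no profiles to aggregate")
  offsets <- as.integer(offsets)
  acc <- numeric(length(offsets))
  n <- integer(length(offsets))
  for (p in profiles) {
    tx <- transcripts[[p$transcript_id]]
    if (is.null(tx)) stop("no transcript model for ", p$transcript_id)
    a <- if (align_to == "start") tx$cds_start else stop_codon_start(tx)
    pos <- a + offsets
    ok <- pos >= 0L & pos < tx$length
    acc[ok] <- acc[ok] + p$counts[pos[ok] + 1L]
    n <- n + ok
  }
  res <- data.frame(offset = offsets,
                    mean_density = ifelse(n > 0, acc / pmax(n, 1L), NA_real_),
                    n = n)
  attr(res, "align_to") <- align_to
  attr(res, "n_transcripts") <- length(profiles)
  attr(res, "anchor") <- profiles[[1]]$anchor
  attr(res, "length_range") <- profiles[[1]]$length_range
  class(res) <- c("metagene_result", "data.frame")
  res
}

#' Reading-frame fractions of a profile region
#'
#' Fraction of region counts whose positions fall in frames 0/1/2 relative to
#' the annotated start codon. CDS reads of elongating ribosomes are strongly
#' phased; 3'UTR reads typically are not.
#'
#' @inheritParams passes_cds_filters
#' @param region `"cds"` or `"utr3"`.
#' @return Named numeric vector `c(f0 = , f1 = , f2 = )` summing to 1.
#' @export
frame_fractions <- function(profile, transcript, region = c("cds", "utr3")) {
  region <- match.arg(region)
  idx <- if (region == "cds") cds_positions(transcript)
         else seq.int(transcript$cds_end, transcript$length - 1L)
  if (length(idx) == 0) stop("empty ", region, " region")
  counts <- profile$counts[idx + 1L]
  if (sum(counts) == 0) stop("zero counts in ", region, " region")
  fr <- frame_of(transcript, idx)
  tot <- vapply(0:2, function(f) sum(counts[fr == f]), numeric(1))
  stats::setNames(tot / sum(tot), c("f0", "f1", "f2"))
}
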