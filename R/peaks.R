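#' Parameters for termination-peak calling
#'
#' @param window_nt Sliding-window width in nt (default 120).
#' @param fold_threshold A site must exceed `fold_threshold` times the window
#'   mean (strict inequality; default 10).
#' @param min_total_reads mRNAs with fewer total reads are excluded entirely
#'   (default 10).
#' @param min_site_count Minimum raw count at a candidate site (default 1).
#' @param flank_nt Flank used for the downstream/upstream density drop ratio
#'   (default 60).
#' @return A `peak_params` list.
#' @export
peak_params <- function(window_nt = 120L, fold_threshold = 10,
                        min_total_reads = 10L, min_site_count = 1L,
                        flank_nt = 60L) {
  stopifnot(window_nt >= 3L, fold_threshold > 1, min_total_reads >= 0L)
  structure(list(window_nt = as.integer(window_nt),
                 fold_threshold = fold_threshold,
                 min_total_reads = as.integer(min_total_reads),
                 min_site_count = as.integer(min_site_count),
                 flank_nt = as.integer(flank_nt)),
            class = "peak_params")
}

#' Call termination peaks on an eRF1-seq profile
#'
#' Scans the transcript with a sliding window centred on each candidate site
#' (width `window_nt`, clipped at transcript ends, mean over the positions
#' actually in range *including* the candidate) and calls a site a peak when
#' its count strictly exceeds `fold_threshold` times the window mean.
#' Transcripts with fewer than `min_total_reads` total counts return no
#' peaks. Runs of candidate sites within 2 nt of each other are collapsed to
#' the maximal-count site (ties: 5'-most); the -15/-12 terminating doublet
#' (3 nt apart) is deliberately not collapsed.
#'
#' Calling is scale-invariant: multiplying the counts by any k > 0 yields
#' the same peak positions (though `min_total_reads`/`min_site_count` act on
#' raw counts).
#'
#' @param profile A 5'-end anchored eRF1 [coverage_profile()] built from
#'   quality-filtered reads.
#' @param transcript The matching [transcript_model()].
#' @param params A [peak_params()].
#' @return data.frame with columns `transcript_id`, `five_prime_pos`,
#'   `fold_enrichment`, sorted by position (possibly 0 rows).
#' @export
call_termination_peaks <- function(profile, transcript, params = peak_params()) {
  if (transcript$length < 3L) stop("transcript shorter than 3 nt")
  counts <- profile$counts
  n <- length(counts)
  empty <- data.frame(transcript_id = character(), five_prime_pos = integer(),
                      fold_enrichment = numeric(), stringsAsFactors = FALSE)
  if (sum(counts) < params$min_total_reads) return(empty)

  half <- params$window_nt %/% 2L
  # window for site i (0-based): [i - half, i + half) clipped to [0, n)
  cs <- c(0, cumsum(counts))
  i0 <- seq_len(n) - 1L
  lo <- pmax(i0 - half, 0L)
  hi <- pmin(i0 + (params$window_nt - half), n)
  wmean <- (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)

  cand <- which(counts >= params$min_site_count &
                  counts > params$fold_threshold * wmean) - 1L
  if (length(cand) == 0) return(empty)

  # collapse candidates within 2 nt to the maximal-count site (tie: 5'-most)
  grp <- cumsum(c(1L, diff(cand) > 2L))
  keep <- vapply(split(cand, grp), function(g) {
    g[which.max(counts[g + 1L])]
  }, integer(1))
  keep <- sort(unname(keep))

  data.frame(transcript_id = transcript$transcript_id,
             five_prime_pos = keep,
             fold_enrichment = counts[keep + 1L] / wmean[keep + 1L],
             stringsAsFactors = FALSE)
}

#' Annotate called termination peaks
#'
#' Completes each peak with its A-site position (`five_prime_pos + 15`),
#' A-site codon, mRNA region, reading frame relative to the annotated start,
#' and flags: at the annotated stop codon; at a supplied uORF stop; and
#' shifted-stop status. A peak is `shifted_stop = "minus1"` when a stop codon
#' starts 1 nt 5' of the A-site codon and `"plus1"` when 1 nt 3' (the label
#' names the ribosome shift that would read the stop: e.g. sense codon CTG
#' overlapping TGA one nt downstream is the -1-frameshifted UGA class, here
#' labelled `plus1` by raw offset with `shift_label` giving the ribosome
#' reading); `minus1` is checked first.
#'
#' @param peaks Output of [call_termination_peaks()].
#' @param transcript The matching [transcript_model()].
#' @param uorf_calls Optional data.frame with a `stop` column of uORF
#'   stop-codon start coordinates (e.g. candidates from
#'   [extract_candidate_uorfs()] or ground truth).
#' @param asite_offset A-site offset from the 5' end (default 15).
#' @return The peaks data.frame with columns `asite_pos`, `asite_codon`,
#'   `region`, `frame`, `in_frame`, `at_annotated_stop`, `shifted_stop`,
#'   `shift_label`, `at_uorf_stop` added; peaks whose A-site codon runs past
#'   the transcript end are flagged `annotatable = FALSE`.
#' @export
annotate_peaks <- function(peaks, transcript, uorf_calls = NULL,
                           asite_offset = 15L) {
  n <- nrow(peaks)
  peaks$asite_pos <- peaks$five_prime_pos + asite_offset
  peaks$annotatable <- peaks$asite_pos + 3L <= transcript$length
  peaks$asite_codon <- NA_character_
  peaks$region <- NA_character_
  peaks$frame <- NA_integer_
  peaks$in_frame <- NA
  peaks$at_annotated_stop <- NA
  peaks$shifted_stop <- NA_character_
  peaks$shift_label <- NA_character_
  peaks$at_uorf_stop <- NA
  uorf_stops <- if (!is.null(uorf_calls)) uorf_calls$stop else integer()
  for (i in seq_len(n)) {
    if (!peaks$annotatable[i]) next
    a <- peaks$asite_pos[i]
    peaks$asite_codon[i] <- subseq0(transcript, a, a + 3L)
    peaks$region[i] <- region_of(transcript, a)
    peaks$frame[i] <- frame_of(transcript, a)
    peaks$at_annotated_stop[i] <- a == stop_codon_start(transcript)
    peaks$in_frame[i] <- (peaks$region[i] == "cds" && peaks$frame[i] == 0L) ||
      peaks$at_annotated_stop[i]
    is_stop_at <- function(p) {
      p >= 0L && p + 3L <= transcript$length &&
        subseq0(transcript, p, p + 3L) %in% STOP_CODONS
    }
    if (is_stop_at(a - 1L)) {
      peaks$shifted_stop[i] <- "minus1"
      peaks$shift_label[i] <- "plus1_frameshift"
    } else if (is_stop_at(a + 1L)) {
      peaks$shifted_stop[i] <- "plus1"
      peaks$shift_label[i] <- "minus1_frameshift"
    } else {
      peaks$shifted_stop[i] <- "none"
      peaks$shift_label[i] <- "none"
    }
    peaks$at_uorf_stop[i] <- a %in% uorf_stops
  }
  peaks
}

#' Ribo-seq density drop across a termination site
#'
#' Mean normalized Ribo-seq density downstream of the peak's A-site codon
#' over the mean upstream, the codon itself excluded from both flanks. True
#' termination sites show lowered downstream density (ratio well below 1).
#'
#' @param asite_pos 0-based first nt of the peak's A-site codon.
#' @param ribo_profile CDS-normalized Ribo-seq [coverage_profile()].
#' @param transcript The matching [transcript_model()].
#' @param flank_nt Flank width (default 60), clipped to transcript bounds.
#' @return Scalar ratio; `NA` when the upstream mean is 0.
#' @export
termination_drop_ratio <- function(asite_pos, ribo_profile, transcript,
                                   flank_nt = 60L) {
  n <- transcript$length
  dn <- seq.int(asite_pos + 3L, min(asite_pos + 3L + flank_nt, n) - 1L)
  dn <- dn[dn >= 0L & dn < n & dn >= asite_pos + 3L]
  up <- seq.int(max(asite_pos - flank_nt, 0L), asite_pos - 1L)
  up <- up[up >= 0L & up < n & up < asite_pos]
  if (length(dn) == 0 && length(up) == 0) stop("both flanks empty")
  if (length(up) == 0 || mean(ribo_profile$counts[up + 1L]) == 0)
    return(NA_real_)
  if (length(dn) == 0) return(NA_real_)
  mean(ribo_profile$counts[dn + 1L]) / mean(ribo_profile$counts[up + 1L])
}

#' Match 5'UTR termination peaks to uORF stop codons
#'
#' A 5'UTR peak matches a uORF when its A-site position equals the uORF
#' stop-codon start (exact by default; `slop_nt` allows +/- slop).
#'
#' @param peaks Annotated peaks (see [annotate_peaks()]); only rows with
#'   `region == "utr5"` are considered.
#' @param uorf_calls data.frame with a `stop` column of uORF stop-codon start
#'   coordinates (same transcript).
#' @param slop_nt Allowed positional slop in nt (default 0).
#' @return List with `fraction_matched` (`NA` when there are no 5'UTR peaks)
#'   and `matches` (logical per 5'UTR peak).
#' @export
match_peaks_to_uorf_stops <- function(peaks, uorf_calls, slop_nt = 0L) {
  utr5 <- peaks[!is.na(peaks$region) & peaks$region == "utr5", , drop = FALSE]
  if (nrow(utr5) == 0)
    return(list(fraction_matched = NA_real_, matches = logical()))
  stops <- uorf_calls$stop
  matches <- vapply(utr5$asite_pos, function(a)
    any(abs(stops - a) <= slop_nt), logical(1))
  list(fraction_matched = mean(matches), matches = matches)
}

#' Histogram of out-of-frame CDS peak positions relative to the stop codon
#'
#' Distance = `asite_pos - (cds_end - 3)`, negative upstream of the annotated
#' stop codon; binned counts over the supplied peaks (intended for
#' out-of-frame CDS peaks).
#'
#' @param peaks Annotated peaks for possibly many transcripts; must carry
#'   `transcript_id` and `asite_pos`.
#' @param transcripts Named list of [transcript_model()]s.
#' @param bin_nt Bin width in nt (default 10).
#' @return data.frame with `bin_start`, `bin_end` (nt, half-open), `count`;
#'   zero rows for an empty peak set.
#' @export
peak_position_histogram <- function(peaks, transcripts, bin_nt = 10L) {
  if (nrow(peaks) == 0)
    return(data.frame(bin_start = integer(), bin_end = integer(),
                      count = integer()))
  d <- vapply(seq_len(nrow(peaks)), function(i) {
    tx <- transcripts[[peaks$transcript_id[i]]]
    peaks$asite_pos[i] - stop_codon_start(tx)
  }, numeric(1))
  b <- floor(d / bin_nt)
  tab <- table(b)
  data.frame(bin_start = as.integer(names(tab)) * bin_nt,
             bin_end = (as.integer(names(tab)) + 1L) * bin_nt,
             count = as.integer(tab))
}
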