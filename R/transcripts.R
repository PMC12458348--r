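#' Transcript model with CDS annotation
#'
#' A transcript in its own coordinate space: the nucleotide sequence plus the
#' coding region. All coordinates in the package are 0-based, half-open, in
#' transcript space, and the CDS *includes* the stop codon, so the stop codon
#' is always `substr(sequence, cds_end - 2, cds_end)` in 1-based R terms.
#'
#' Region partition: 5'UTR = `[0, cds_start)`, CDS = `[cds_start, cds_end)`,
#' 3'UTR = `[cds_end, length)`.
#'
#' @param transcript_id Character scalar identifier.
#' @param sequence Nucleotide string; `U`/lowercase are normalized to `T`/upper.
#' @param cds_start 0-based coordinate of the first nt of the start codon.
#' @param cds_end 0-based half-open end of the CDS including the stop codon.
#' @param permissive If `TRUE`, a missing stop codon at the CDS end is
#'   tolerated (the model is still built); otherwise it is an error.
#' @return An object of class `transcript_model` with fields
#'   `transcript_id`, `sequence`, `cds_start`, `cds_end`, `length`.
#' @export
transcript_model <- function(transcript_id, sequence, cds_start, cds_end,
                             permissive = FALSE) {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L)
  sequence <- chartr("U", "T", toupper(as.character(sequence)))
  n <- nchar(sequence)
  cds_start <- as.integer(cds_start)
  cds_end <- as.integer(cds_end)
  if (grepl("[^ACGT]", sequence))
    stop("transcript ", transcript_id, ": sequence contains non-ACGT characters")
  if (!(cds_start >= 0L && cds_start < cds_end && cds_end <= n))
    stop("transcript ", transcript_id, ": CDS coordinates out of range")
  if ((cds_end - cds_start) %% 3L != 0L)
    stop("transcript ", transcript_id, ": CDS length not a multiple of 3")
  if (cds_end - cds_start < 6L)
    stop("transcript ", transcript_id, ": CDS shorter than two codons")
  stop_codon <- substr(sequence, cds_end - 2L, cds_end)
  if (!stop_codon %in% STOP_CODONS && !permissive)
    stop("transcript ", transcript_id, ": no stop codon at CDS end (found ",
         stop_codon, ")")
  structure(
    list(transcript_id = transcript_id, sequence = sequence,
         cds_start = cds_start, cds_end = cds_end, length = n),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s: %d nt; 5'UTR %d, CDS %d, 3'UTR %d\n",
              x$transcript_id, x$length, x$cds_start,
              x$cds_end - x$cds_start, x$length - x$cds_end))
  invisible(x)
}

#' Region of a transcript position
#'
#' Maps 0-based transcript coordinates onto the 5'UTR / CDS / 3'UTR partition.
#' The partition is exhaustive and disjoint.
#'
#' @param transcript A [transcript_model()].
#' @param position Integer vector of 0-based coordinates.
#' @return Character vector in `{"utr5", "cds", "utr3"}`.
#' @export
region_of <- function(transcript, position) {
  position <- as.integer(position)
  if (any(position < 0L | position >= transcript$length))
    stop("position out of range for transcript ", transcript$transcript_id)
  ifelse(position < transcript$cds_start, "utr5",
         ifelse(position < transcript$cds_end, "cds", "utr3"))
}

#' Reading frame of a transcript position
#'
#' Frame relative to the annotated start codon: `(position - cds_start) mod 3`,
#' always in `{0, 1, 2}` including for positions upstream of the start.
#'
#' @inheritParams region_of
#' @return Integer vector in `{0, 1, 2}`.
#' @export
frame_of <- function(transcript, position) {
  (as.integer(position) - transcript$cds_start) %% 3L
}

#' Extract a subsequence by 0-based half-open coordinates
#' @param transcript A [transcript_model()].
#' @param from,to 0-based half-open interval.
#' @return Character scalar.
#' @export
subseq0 <- function(transcript, from, to) {
  substr(transcript$sequence, from + 1L, to)
}

#' First nucleotide of the annotated stop codon
#' @param transcript A [transcript_model()].
#' @return 0-based coordinate of the stop codon's first nt.
#' @export
stop_codon_start <- function(transcript) transcript$cds_end - 3L

# 0-based CDS position index vector (for internal sums)
cds_positions <- function(transcript) {
  seq.int(transcript$cds_start, transcript$cds_end - 1L)
}
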