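#' Extract candidate uORFs from a transcript
#'
#' Every ATG whose first nt lies in the 5'UTR (`[0, cds_start)`) is paired
#' with the first in-frame stop codon downstream, searching into the CDS if
#' necessary. Candidates without any in-frame stop before the transcript end
#' are dropped; nested and overlapping candidates are all retained.
#'
#' @param transcript A [transcript_model()].
#' @return data.frame with columns `transcript_id`, `start`, `stop` (0-based
#'   first nt of ATG / of the stop codon), `n_codons` (excluding the stop)
#'   and `kind` (`"contained"` when the stop starts in the 5'UTR,
#'   `"overlapping"` otherwise).
#' @export
extract_candidate_uorfs <- function(transcript) {
  seq <- transcript$sequence
  n <- transcript$length
  empty <- data.frame(transcript_id = character(), start = integer(),
                      stop = integer(), n_codons = integer(),
                      kind = character(), stringsAsFactors = FALSE)
  if (transcript$cds_start == 0L) return(empty)
  starts <- gregexpr("ATG", seq, fixed = TRUE)[[1]]
  starts <- starts[starts > 0] - 1L                      # to 0-based
  starts <- starts[starts < transcript$cds_start]
  rows <- list()
  for (s in starts) {
    p <- s + 3L
    stop_at <- NA_integer_
    while (p + 3L <= n) {
      if (substr(seq, p + 1L, p + 3L) %in% STOP_CODONS) { stop_at <- p; break }
      p <- p + 3L
    }
    if (is.na(stop_at)) next
    rows[[length(rows) + 1L]] <- data.frame(
      transcript_id = transcript$transcript_id, start = s, stop = stop_at,
      n_codons = (stop_at - s) %/% 3L,
      kind = if (stop_at < transcript$cds_start) "contained" else "overlapping",
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty)
  do.call(rbind, rows)
}

#' One-sided exact Wilcoxon signed-rank test (greater)
#'
#' Tests whether paired differences `x - y` are shifted above zero. Zero
#' differences are dropped before ranking; ties among |differences| receive
#' midranks. For `n <= max_exact` non-zero differences the p-value is exact:
#' the null distribution of the positive-rank sum over all 2^n sign
#' assignments is computed by dynamic programming on the generating function
#' of the (doubled, hence integral) ranks, which remains exact under
#' midranks. Above `max_exact` a normal approximation with tie-corrected
#' variance and a 0.5 continuity correction is used. If all differences are
#' zero the p-value is 1.
#'
#' @param x,y Paired numeric vectors.
#' @param max_exact Largest n for which the exact distribution is enumerated
#'   (default 25).
#' @return One-sided p-value for `x > y`.
#' @export
wilcoxon_signed_rank_greater <- function(x, y, max_exact = 25L) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= max_exact) {
    r2 <- as.integer(round(2 * r))        # doubled midranks are integers
    total <- sum(r2)
    # coef[s + 1] = number of sign assignments with doubled rank-sum s
    coef <- numeric(total + 1L)
    coef[1L] <- 1
    for (rr in r2) {
      shifted <- c(numeric(rr), coef[seq_len(total + 1L - rr)])
      coef <- coef + shifted
    }
    W2 <- as.integer(round(2 * W))
    sum(coef[(W2 + 1L):(total + 1L)]) / 2^n
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    stats::pnorm((W - mu - 0.5) / sigma, lower.tail = FALSE)
  }
}

#' Per-frame read test for one uORF candidate
#'
#' Using a P-site anchored profile, the in-frame counts of the candidate's
#' codons (positions `start + 3j`) are compared against the +1-frame
#' (`start + 3j + 1`) and +2-frame (`start + 3j + 2`) counts with two paired
#' one-sided Wilcoxon signed-rank tests: translated uORFs show in-frame
#' reads significantly higher than the other two frames.
#'
#' @param candidate One row of [extract_candidate_uorfs()] output.
#' @param profile P-site anchored [coverage_profile()] of the transcript.
#' @return List with `p_frame1`, `p_frame2` (both `NA` when the candidate has
#'   fewer than 2 codons and is untestable).
#' @export
uorf_frame_test <- function(candidate, profile) {
  n <- candidate$n_codons
  if (n < 2L) return(list(p_frame1 = NA_real_, p_frame2 = NA_real_))
  j <- seq_len(n) - 1L
  x <- profile$counts[candidate$start + 3L * j + 1L]
  y <- profile$counts[candidate$start + 3L * j + 2L]
  z <- profile$counts[candidate$start + 3L * j + 3L]
  list(p_frame1 = wilcoxon_signed_rank_greater(x, y),
       p_frame2 = wilcoxon_signed_rank_greater(x, z))
}

#' Combine two one-sided p-values by Stouffer's method
#'
#' `z_i = qnorm(1 - p_i)`; combined p = `1 - pnorm((z1 + z2) / sqrt(2))`,
#' equal weights. p-values of exactly 1 are clipped to `1 - eps` so the
#' normal score stays finite.
#'
#' @param p1,p2 One-sided p-values in (0, 1].
#' @param eps Clipping tolerance (default `1e-12`).
#' @return Combined p-value.
#' @export
stouffer_combine <- function(p1, p2, eps = 1e-12) {
  if (any(c(p1, p2) <= 0)) stop("p-values must be > 0")
  p1 <- min(p1, 1 - eps)
  p2 <- min(p2, 1 - eps)
  z <- stats::qnorm(c(p1, p2), lower.tail = FALSE)
  stats::pnorm(sum(z) / sqrt(2), lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values in input order (wraps the standard BH
#' procedure).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric())
  stats::p.adjust(p_values, method = "BH")
}

#' Call translated uORFs across a transcript set
#'
#' Extracts all AUG-initiated candidates, applies a minimum-read gate within
#' the candidate span, runs the two per-frame Wilcoxon tests on P-site
#' anchored counts, combines them with Stouffer's method, and adjusts across
#' all candidates jointly by Benjamini-Hochberg. Candidates with
#' `q_value < alpha` are flagged as robustly translated.
#'
#' @param transcripts Named list of [transcript_model()]s.
#' @param reads Read data.frame (quality filter applied internally).
#' @param alpha FDR threshold (default 0.05).
#' @param min_codons Minimum codons per testable candidate (default 2).
#' @param min_reads Minimum P-site counts within `[start, stop)` (default 8).
#' @return data.frame of `UorfCall` rows: candidate fields plus `p_frame1`,
#'   `p_frame2`, `z1`, `z2`, `p_combined`, `q_value`, `robust`.
#' @export
call_uorfs <- function(transcripts, reads, alpha = 0.05, min_codons = 2L,
                       min_reads = 8L) {
  reads <- reads[read_passes_filters(reads), , drop = FALSE]
  anchor <- anchor_config("psite")
  rows <- list()
  for (tx in transcripts) {
    cands <- extract_candidate_uorfs(tx)
    if (nrow(cands) == 0) next
    prof <- build_profile(reads, tx, anchor)
    for (i in seq_len(nrow(cands))) {
      cand <- cands[i, ]
      if (cand$n_codons < min_codons) next
      span <- seq.int(cand$start, cand$stop - 1L)
      if (sum(prof$counts[span + 1L]) < min_reads) next
      ps <- uorf_frame_test(cand, prof)
      if (is.na(ps$p_frame1)) next
      cand$p_frame1 <- ps$p_frame1
      cand$p_frame2 <- ps$p_frame2
      cand$z1 <- stats::qnorm(min(ps$p_frame1, 1 - 1e-12), lower.tail = FALSE)
      cand$z2 <- stats::qnorm(min(ps$p_frame2, 1 - 1e-12), lower.tail = FALSE)
      cand$p_combined <- stouffer_combine(ps$p_frame1, ps$p_frame2)
      rows[[length(rows) + 1L]] <- cand
    }
  }
  if (length(rows) == 0)
    return(data.frame(transcript_id = character(), start = integer(),
                      stop = integer(), n_codons = integer(),
                      kind = character(), p_frame1 = numeric(),
                      p_frame2 = numeric(), z1 = numeric(), z2 = numeric(),
                      p_combined = numeric(), q_value = numeric(),
                      robust = logical(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_combined)
  out$robust <- out$q_value < alpha
  rownames(out) <- NULL
  out
}
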