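# Independent oracles and small builders used across test files.

# Transcript with given region lengths; CDS = ATG + sense codons + TAA,
# UTRs default to stop-free filler so candidate scans are predictable.
make_tx <- function(id = "tx", utr5 = 12, cds = 30, utr3 = 12,
                    utr5_seq = NULL, cds_mid = NULL, utr3_seq = NULL) {
  stopifnot(cds %% 3 == 0, cds >= 6)
  if (is.null(utr5_seq)) utr5_seq <- paste(rep("C", utr5), collapse = "")
  if (is.null(utr3_seq)) utr3_seq <- paste(rep("T", utr3), collapse = "")
  n_mid <- cds / 3 - 2
  if (is.null(cds_mid))
    cds_mid <- paste(rep("GGC", n_mid), collapse = "")
  seq <- paste0(utr5_seq, "ATG", cds_mid, "TAA", utr3_seq)
  transcript_model(id, seq, nchar(utr5_seq), nchar(utr5_seq) + cds)
}

read_row <- function(id, fp, len = 30L, nm = 0L, nh = 1L) {
  data.frame(transcript_id = id, five_prime = as.integer(fp),
             length = as.integer(len), n_mismatches = as.integer(nm),
             n_hits = as.integer(nh), stringsAsFactors = FALSE)
}

# Brute-force signed-rank p over all 2^n sign assignments (n <= 12).
brute_signed_rank_greater <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  hits <- 0
  for (m in 0:(2^n - 1)) {
    s <- as.logical(bitwAnd(m, 2^(0:(n - 1))))
    if (sum(r[s]) >= W - 1e-9) hits <- hits + 1
  }
  hits / 2^n
}

# Naive reimplementation of the sliding-window peak caller.
naive_peaks <- function(counts, params = peak_params()) {
  n <- length(counts)
  if (sum(counts) < params$min_total_reads) return(integer())
  half <- params$window_nt %/% 2
  cand <- integer()
  for (i in seq_len(n) - 1L) {
    lo <- max(i - half, 0)
    hi <- min(i + (params$window_nt - half), n)
    wm <- mean(counts[(lo + 1):hi])
    if (counts[i + 1] >= params$min_site_count &&
        counts[i + 1] > params$fold_threshold * wm)
      cand <- c(cand, i)
  }
  if (length(cand) == 0) return(integer())
  keep <- integer()
  grp_start <- 1
  for (j in seq_along(cand)) {
    if (j == length(cand) || cand[j + 1] - cand[j] > 2) {
      g <- cand[grp_start:j]
      keep <- c(keep, g[which.max(counts[g + 1])])
      grp_start <- j + 1
    }
  }
  sort(keep)
}

fixture_path <- function(f) system.file("extdata", f, package = "riboterm")
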