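test_that("peak calling follows the tenfold sliding-window rule", {
  tx <- make_tx(utr5 = 40, cds = 120, utr3 = 80)
  # all-zero profile
  expect_equal(nrow(call_termination_peaks(coverage_profile("t",
    numeric(tx$length)), tx)), 0)

  # single site of 121 in zeros: window mean 121/120, fold ~ 120
  counts <- numeric(tx$length)
  counts[131] <- 121
  pk <- call_termination_peaks(coverage_profile("t", counts), tx)
  expect_equal(pk$five_prime_pos, 130)
  expect_equal(pk$fold_enrichment, 120)

  # strict inequality: site exactly 10x the window mean is not a peak
  counts <- numeric(tx$length)
  counts[161] <- 10             # site 160 (0-based); window [100, 220)
  counts[setdiff(101:220, 161)[1:110]] <- 1   # window sum 120, mean 1
  pk <- call_termination_peaks(coverage_profile("t", counts), tx)
  expect_false(160 %in% pk$five_prime_pos)

  # mRNAs with < 10 total reads are excluded even with a huge spike
  counts <- numeric(tx$length)
  counts[50] <- 9
  expect_equal(nrow(call_termination_peaks(coverage_profile("t", counts),
                                           tx)), 0)
})

test_that("peak calling equals the naive oracle and is scale-invariant", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(120:400, 1)
    counts <- rpois(n, 0.3)
    spikes <- sample(n, sample(0:3, 1))
    counts[spikes] <- counts[spikes] + rpois(length(spikes), 40)
    cds <- 3 * sample(10:15, 1)
    u5 <- sample(12:20, 1)
    tx <- make_tx(utr5 = u5, cds = cds, utr3 = n - u5 - cds)
    stopifnot(tx$length == n)
    prof <- coverage_profile("t", counts)
    got <- call_termination_peaks(prof, tx)
    expect_equal(got$five_prime_pos, naive_peaks(counts))
    scaled <- call_termination_peaks(coverage_profile("t", counts * 3.5), tx,
      peak_params(min_total_reads = 0, min_site_count = 0))
    base <- call_termination_peaks(prof, tx,
      peak_params(min_total_reads = 0, min_site_count = 0))
    expect_equal(scaled$five_prime_pos, base$five_prime_pos)
  }
})

test_that("no false peaks on a flat Poisson(5) background", {
  cfg <- simulation_config(n_transcripts = 100, erf1_site_mean = 0,
                           erf1_background = 5, context_fraction = 0)
  sim <- generate_transcriptome(cfg, 41)
  reads <- simulate_erf1_reads(sim, cfg, 42)
  total <- 0
  for (tx in sim$transcripts) {
    prof <- build_profile(reads, tx, anchor_config("five_prime"))
    total <- total + nrow(call_termination_peaks(prof, tx))
  }
  expect_equal(total, 0)
})

test_that("planted 50-fold termination sites are recovered", {
  cfg <- simulation_config(n_transcripts = 100, erf1_site_mean = 50,
                           erf1_background = 1, context_fraction = 0,
                           uorf_prob = 0.3, utr5_length = c(80, 140),
                           erf1_outframe_prob = 0.3)
  sim <- generate_transcriptome(cfg, 51)
  reads <- simulate_erf1_reads(sim, cfg, 52)
  sites <- sim$truth$erf1_sites
  found <- 0
  for (tx in sim$transcripts) {
    prof <- build_profile(reads, tx, anchor_config("five_prime"))
    pk <- call_termination_peaks(prof, tx)
    st <- sites[sites$transcript_id == tx$transcript_id &
                  sites$asite_pos >= 15, ]
    found <- found + sum((st$asite_pos - 15) %in% pk$five_prime_pos)
  }
  eligible <- sum(sites$asite_pos >= 15)
  expect_gte(found / eligible, 0.95)
})

test_that("annotation recovers region, frame, codon, and shifted stops", {
  sim <- generate_transcriptome(simulation_config(
    n_transcripts = 20, erf1_outframe_prob = 1, uorf_prob = 0.5,
    utr5_length = c(80, 140), erf1_background = 0), 61)
  cfg <- simulation_config(erf1_background = 0)
  reads <- simulate_erf1_reads(sim, cfg, 62)
  sites <- sim$truth$erf1_sites
  for (tx in sim$transcripts) {
    prof <- build_profile(reads, tx, anchor_config("five_prime"))
    uorfs <- sim$truth$uorfs[sim$truth$uorfs$transcript_id ==
                               tx$transcript_id, ]
    pk <- annotate_peaks(call_termination_peaks(prof, tx), tx, uorfs)
    st <- sites[sites$transcript_id == tx$transcript_id, ]
    for (i in seq_len(nrow(pk))) {
      j <- match(pk$asite_pos[i], st$asite_pos)
      if (is.na(j)) next
      expect_equal(pk$frame[i], st$frame[j])
      expect_true(pk$asite_codon[i] %in% STOP_CODONS)
      if (st$type[j] == "annotated_stop") {
        expect_true(pk$at_annotated_stop[i])
        expect_true(pk$in_frame[i])
      }
      if (st$type[j] == "uorf_stop") expect_true(pk$at_uorf_stop[i])
      if (st$type[j] == "outframe_stop") expect_false(pk$in_frame[i])
    }
  }
})

test_that("shifted-stop labels follow the +/-1 overlap convention", {
  # A-site codon CTG at p, TGA at p+1 (the -1-frameshifted UGA class)
  u5 <- strrep("C", 20)
  seq <- paste0(u5, "ATG", "GGC", "CTG", "AGC", strrep("GGC", 5), "TAA",
                strrep("T", 12))
  tx <- transcript_model("s", seq, 20, 20 + 30)
  p <- 26  # CTG starts here; sequence[27..29] = CTG, TGA at 27(0-based p+1)
  expect_equal(subseq0(tx, p, p + 3), "CTG")
  expect_equal(subseq0(tx, p + 1, p + 4), "TGA")
  pk <- data.frame(transcript_id = "s", five_prime_pos = p - 15,
                   fold_enrichment = 50)
  ann <- annotate_peaks(pk, tx)
  expect_equal(ann$shifted_stop, "plus1")
  expect_equal(ann$shift_label, "minus1_frameshift")

  # A-site codon GAG at p with TGA one nt 5' (the +1-frameshifted class)
  seq <- paste0(u5, "ATG", "GCT", "GAG", "GCC", strrep("GGC", 5), "TAA",
                strrep("T", 12))
  tx <- transcript_model("s", seq, 20, 50)
  p <- 26  # GAG at 26..29; TGA at 25..28?
  expect_equal(subseq0(tx, 26, 29), "GAG")
  expect_equal(subseq0(tx, 25, 28), "TGA")
  ann <- annotate_peaks(data.frame(transcript_id = "s", five_prime_pos = 11,
                                   fold_enrichment = 50), tx)
  expect_equal(ann$asite_pos, 26)
  expect_equal(ann$shifted_stop, "minus1")
  expect_equal(ann$shift_label, "plus1_frameshift")
})

test_that("drop ratio reflects loss of downstream ribosome density", {
  tx <- make_tx(utr5 = 30, cds = 150, utr3 = 60)
  a <- tx$cds_start + 60
  prof <- coverage_profile("t", rep(2, tx$length))
  expect_equal(termination_drop_ratio(a, prof, tx), 1)
  counts <- rep(2, tx$length)
  counts[(a + 3 + 1):tx$length] <- 0
  expect_equal(termination_drop_ratio(a, coverage_profile("t", counts), tx), 0)
  # upstream empty -> missing
  counts <- rep(0, tx$length); counts[(a + 4):(a + 20)] <- 3
  expect_true(is.na(termination_drop_ratio(a, coverage_profile("t", counts),
                                           tx)))
})

test_that("5'UTR peaks match planted uORF stop fractions", {
  peaks <- data.frame(transcript_id = "t",
                      region = c("utr5", "utr5", "utr5", "cds"),
                      asite_pos = c(10, 20, 33, 80))
  uorfs <- data.frame(stop = c(10, 33, 55))
  m <- match_peaks_to_uorf_stops(peaks, uorfs)
  expect_equal(m$fraction_matched, 2 / 3)
  expect_equal(m$matches, c(TRUE, FALSE, TRUE))
  # disjoint and empty cases
  expect_equal(match_peaks_to_uorf_stops(peaks,
    data.frame(stop = 999))$fraction_matched, 0)
  expect_true(is.na(match_peaks_to_uorf_stops(peaks[4, ],
    uorfs)$fraction_matched))
  # 1-nt slop rescues near misses
  m <- match_peaks_to_uorf_stops(peaks, data.frame(stop = c(11, 21, 32)),
                                 slop_nt = 1)
  expect_equal(m$fraction_matched, 1)
})

test_that("peak position histogram bins distances to the annotated stop", {
  tx <- make_tx(id = "h", utr5 = 20, cds = 120, utr3 = 20)
  txs <- list(h = tx)
  s <- stop_codon_start(tx)
  pk <- data.frame(transcript_id = "h", asite_pos = s - 30)
  h <- peak_position_histogram(pk, txs, bin_nt = 10)
  expect_equal(h$count, 1)
  expect_true(h$bin_start <= -30 && -30 < h$bin_end)
  empty <- peak_position_histogram(pk[0, ], txs)
  expect_equal(nrow(empty), 0)
  pk <- data.frame(transcript_id = rep("h", 4),
                   asite_pos = c(s - 100, s - 98, s - 6, s - 4))
  h <- peak_position_histogram(pk, txs, bin_nt = 10)
  expect_equal(h$count, c(2, 2))
})
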