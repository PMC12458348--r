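test_that("anchor assignment follows the 5'/P-site/A-site offsets", {
  reads <- rbind(read_row("t", 100), read_row("t", 7), read_row("t", 33))
  expect_equal(assign_anchor(reads, anchor_config("five_prime")),
               c(100, 7, 33))
  expect_equal(assign_anchor(reads, anchor_config("psite")), c(112, 19, 45))
  # A-site anchor is always P-site + 3
  expect_equal(assign_anchor(reads, anchor_config("asite")) -
                 assign_anchor(reads, anchor_config("psite")),
               rep(3, 3))
  # read with 5' end 15 nt upstream of the stop has the stop in its A site
  tx <- make_tx(utr5 = 20, cds = 60, utr3 = 20)
  fp <- stop_codon_start(tx) - 15
  a <- assign_anchor(read_row("tx", fp), anchor_config("asite"))
  expect_equal(a, stop_codon_start(tx))
})

test_that("build_profile counts anchors, honours length gates and bounds", {
  tx <- make_tx(utr5 = 10, cds = 30, utr3 = 10)
  empty <- build_profile(read_row("other", 5)[0, ], tx)
  expect_equal(sum(empty$counts), 0)

  reads <- rbind(read_row("tx", 12), read_row("tx", 12), read_row("tx", 12))
  prof <- build_profile(reads, tx, anchor_config("five_prime"))
  expect_equal(prof$counts[13], 3)
  expect_equal(sum(prof$counts), 3)

  set.seed(21)
  reads <- read_row("tx", sample(0:(tx$length - 1), 200, replace = TRUE),
                    len = sample(20:31, 200, replace = TRUE))
  for (mode in c("five_prime", "psite", "asite")) {
    ac <- anchor_config(mode)
    prof <- build_profile(reads, tx, ac)
    pos <- assign_anchor(reads, ac)
    expect_equal(sum(prof$counts), sum(pos >= 0 & pos < tx$length))
    brute <- vapply(0:(tx$length - 1), function(p) sum(pos == p), numeric(1))
    expect_equal(prof$counts, brute)
  }
  # length-stratified profiles sum to the unstratified profile
  p_all <- build_profile(reads, tx)
  p_short <- build_profile(reads, tx, length_range = c(20, 23))
  p_mid <- build_profile(reads, tx, length_range = c(24, 27))
  p_long <- build_profile(reads, tx, length_range = c(28, 31))
  expect_equal(p_short$counts + p_mid$counts + p_long$counts, p_all$counts)
})

test_that("CDS filters are inclusive at 16 reads and 10% coverage", {
  tx150 <- make_tx(utr5 = 10, cds = 150, utr3 = 10)
  # 16 reads on 15 distinct positions: coverage exactly 10%, reads exactly 16
  counts <- numeric(tx150$length)
  counts[tx150$cds_start + 1 + seq(0, 140, by = 10)] <- 1
  counts[tx150$cds_start + 1] <- 2
  expect_equal(sum(counts), 16)
  expect_equal(mean(counts[cds_positions(tx150) + 1] > 0), 0.10)
  expect_true(passes_cds_filters(coverage_profile("t", counts), tx150))

  # 15 CDS reads fail the read threshold even at exactly 10% coverage
  counts[tx150$cds_start + 1] <- 1
  expect_equal(sum(counts), 15)
  expect_false(passes_cds_filters(coverage_profile("t", counts), tx150))

  # 16 reads on 16 of 300 positions: reads pass, coverage < 10% fails
  tx300 <- make_tx(utr5 = 10, cds = 300, utr3 = 10)
  counts <- numeric(tx300$length)
  counts[tx300$cds_start + 1:16] <- 1
  expect_false(passes_cds_filters(coverage_profile("t", counts), tx300))

  # heavy but concentrated coverage fails the 10% site rule
  counts <- numeric(tx300$length)
  counts[tx300$cds_start + 1] <- 100
  expect_false(passes_cds_filters(coverage_profile("t", counts), tx300))
})

test_that("CDS normalization yields unit CDS mean and is idempotent", {
  tx <- make_tx(utr5 = 10, cds = 60, utr3 = 10)
  prof <- coverage_profile("tx", rep(4, tx$length))
  norm <- normalize_by_cds(prof, tx)
  expect_equal(norm$counts, rep(1, tx$length))

  counts <- numeric(tx$length)
  counts[cds_positions(tx) + 1] <- 2
  counts[5] <- 20
  norm <- normalize_by_cds(coverage_profile("tx", counts), tx)
  expect_equal(norm$counts[5], 10)

  set.seed(9)
  for (i in 1:20) {
    counts <- rpois(tx$length, 3) + c(rep(0, 10), rep(1, 60), rep(0, 10))
    norm <- normalize_by_cds(coverage_profile("tx", counts), tx)
    expect_equal(mean(norm$counts[cds_positions(tx) + 1]), 1)
    expect_equal(normalize_by_cds(norm, tx)$counts, norm$counts)
  }
})

test_that("metagene averaging respects per-offset denominators", {
  tx <- make_tx(id = "a", utr5 = 20, cds = 60, utr3 = 30)
  txs <- list(a = tx)
  prof <- normalize_by_cds(coverage_profile("a", rep(2, tx$length)), tx)
  mg <- metagene_aggregate(list(prof), txs, align_to = "stop",
                           offsets = -20:20)
  expect_true(all(mg$mean_density == 1))

  # metagene of N identical transcripts equals the single-transcript curve
  tx2 <- make_tx(id = "b", utr5 = 20, cds = 60, utr3 = 30)
  counts <- rpois(tx$length, 5) + 1
  p1 <- normalize_by_cds(coverage_profile("a", counts), tx)
  p2 <- normalize_by_cds(coverage_profile("b", counts), tx2)
  mg1 <- metagene_aggregate(list(p1), txs, "stop", -10:10)
  mgN <- metagene_aggregate(list(p1, p2, p1), list(a = tx, b = tx2),
                            "stop", -10:10)
  expect_equal(mgN$mean_density, mg1$mean_density)

  # transcript lacking offset +50 drops out of that offset's average
  short <- make_tx(id = "s", utr5 = 20, cds = 60, utr3 = 10)
  long <- make_tx(id = "l", utr5 = 20, cds = 60, utr3 = 80)
  ps <- coverage_profile("s", rep(1, short$length))   # flat density 1
  pl <- coverage_profile("l", rep(3, long$length))    # flat density 3
  mg <- metagene_aggregate(list(ps, pl), list(s = short, l = long),
                           "stop", c(0, 50))
  expect_equal(mg$n, c(2, 1))
  expect_equal(mg$mean_density, c(2, 3))

  expect_error(metagene_aggregate(list(), txs), "no profiles")
})

test_that("frame fractions sum to one and recover planted compositions", {
  tx <- make_tx(utr5 = 9, cds = 30, utr3 = 12)
  counts <- numeric(tx$length)
  counts[tx$cds_start + 1 + c(0, 3, 6)] <- 5         # all frame 0
  ff <- frame_fractions(coverage_profile("tx", counts), tx, "cds")
  expect_equal(unname(ff), c(1, 0, 0))

  counts <- numeric(tx$length)
  counts[tx$cds_start + 1 + 0:3] <- c(2, 1, 1, 0)
  ff <- frame_fractions(coverage_profile("tx", counts), tx, "cds")
  expect_equal(unname(ff), c(0.5, 0.25, 0.25))

  # simulator 3'UTR leak is frame-agnostic: fractions near 1/3 at high depth
  cfg <- simulation_config(n_transcripts = 1, utr3_length = c(300, 300),
                           cds_length = c(150, 150), depth = 2,
                           context_fraction = 0, leak_scale = 60,
                           pausing = list(model = "loguniform", min = 1,
                                          max = 1))
  sim <- generate_transcriptome(cfg, 12)
  tx <- sim$transcripts[[1]]
  reads <- simulate_ribo_reads(sim, cfg, 13)
  prof <- build_profile(reads, tx)
  ff <- frame_fractions(prof, tx, "utr3")
  n <- sum(prof$counts[(tx$cds_end + 1):tx$length])
  se <- sqrt(1 / 3 * 2 / 3 / n)
  expect_true(all(abs(ff - 1 / 3) < 4 * se))
  expect_equal(sum(ff), 1)
})
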