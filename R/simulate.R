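#' Simulation configuration
#'
#' Defines the study conditions the synthetic data emulate: uniform-Poisson
#' elongation coverage over the CDS; a terminating-ribosome population whose
#' 5' ends sit at -15 (stop codon in the A site) and -12 nt (forward-shifted)
#' relative to the stop codon, with a bimodal footprint-length mixture (long
#' 30-31 nt, short 20-23 nt); sequence-dependent pausing strength driven by
#' the G+A fraction of the 9 nt upstream of the stop codon; frame-agnostic
#' 3'UTR leak reads whose intensity decreases with pausing strength;
#' AUG-initiated uORFs with in-frame P-site read enrichment; eRF1-seq reads
#' concentrated at termination sites over a low CDS background; and an MPRA
#' library of 9-nt random inserts partitioned between monosome and polysome
#' by in-frame stop-codon presence.
#'
#' @param n_transcripts Number of transcripts.
#' @param utr5_length,cds_length,utr3_length Sampling ranges `c(min, max)` in
#'   nt; CDS lengths are forced to multiples of 3 (min 18).
#' @param depth Mean elongation footprints per CDS nt.
#' @param pausing Either `list(model = "context", base, slope)` (multiplier =
#'   base + slope x upstream GA fraction) or
#'   `list(model = "loguniform", min, max)` (multiplier drawn log-uniformly).
#' @param leak_scale 3'UTR per-nt leak rate = `depth * leak_scale /
#'   multiplier` (a free parameter: the emulated intensity contrast, not a
#'   measured value).
#' @param stop_window_split Fraction of terminating reads with 5' end at
#'   -15 nt (the rest at -12).
#' @param smear_nt Half-width of optional uniform smearing of terminating
#'   5' ends (default 0: the two observed peaks only).
#' @param term_long_fraction Mixing fraction of long (30-31 nt) terminating
#'   footprints; the rest are short (20-23 nt).
#' @param context_fraction Fraction of transcripts given a designed 9-mer
#'   immediately 5' of the stop codon (alternating GA-rich, drawn from
#'   {G,A}, and C-rich, drawn C-biased from {C,T}) so both context classes
#'   are populated.
#' @param uorf_prob Per-transcript probability of planting one AUG-initiated
#'   uORF with an in-frame stop inside the 5'UTR.
#' @param uorf_codons Range of uORF lengths in codons (stop excluded).
#' @param uorf_enrichment In-frame P-site read enrichment of planted uORFs
#'   over the 5'UTR scanning background.
#' @param utr5_rate Per-nt Poisson rate of frame-uniform 5'UTR P-site reads.
#' @param erf1_site_mean Mean eRF1-seq reads per termination site.
#' @param erf1_background Per-nt Poisson rate of eRF1 CDS background reads.
#' @param erf1_outframe_prob Per-transcript probability of planting one
#'   out-of-frame stop codon inside the CDS (an alternative termination
#'   site).
#' @param mpra List: `n_variants`, `depth_mono`, `depth_poly`, `p_stop`,
#'   `p_base` (monosome partition probability with/without an in-frame stop
#'   at insert offsets 0/3/6), `ga_coef` (additive modulation by insert G+A
#'   fraction, centred at 0.5).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_transcripts = 200L,
                              utr5_length = c(60L, 120L),
                              cds_length = c(150L, 600L),
                              utr3_length = c(60L, 150L),
                              depth = 5,
                              pausing = list(model = "context", base = 1,
                                             slope = 8),
                              leak_scale = 0.1,
                              stop_window_split = 0.7,
                              smear_nt = 0L,
                              term_long_fraction = 0.5,
                              context_fraction = 0.5,
                              uorf_prob = 0,
                              uorf_codons = c(4L, 12L),
                              uorf_enrichment = 4,
                              utr5_rate = 0,
                              erf1_site_mean = 50,
                              erf1_background = 0.2,
                              erf1_outframe_prob = 0,
                              mpra = list(n_variants = 10000L,
                                          depth_mono = 1e6, depth_poly = 1e6,
                                          p_stop = 0.5, p_base = 0.1,
                                          ga_coef = 0)) {
  stopifnot(depth >= 0, leak_scale >= 0,
            stop_window_split >= 0, stop_window_split <= 1,
            term_long_fraction >= 0, term_long_fraction <= 1,
            context_fraction >= 0, context_fraction <= 1,
            uorf_prob >= 0, uorf_prob <= 1,
            erf1_site_mean >= 0, erf1_background >= 0,
            cds_length[1] >= 18L)
  structure(as.list(environment()), class = "simulation_config")
}

rand_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")

#' Generate a synthetic transcriptome with ground truth
#'
#' Random transcripts with an ATG at `cds_start`, a stop codon at
#' `cds_end - 3`, no accidental in-frame stop codons inside the CDS (internal
#' codons are drawn from the 61 sense codons), designed upstream 9-mers on a
#' configurable fraction of transcripts, planted uORFs, and (optionally) one
#' planted out-of-frame stop codon per transcript as an alternative
#' termination site. Fully deterministic under a fixed seed.
#'
#' @param config A [simulation_config()].
#' @param seed Integer RNG seed.
#' @return List with `transcripts` (named list of [transcript_model()]),
#'   and `truth`: `transcripts` (per-transcript multiplier, GA fraction,
#'   context class, leak rate), `uorfs` (planted uORF intervals and
#'   enrichment), `erf1_sites` (every planted termination site with its type
#'   and frame).
#' @export
generate_transcriptome <- function(config, seed) {
  set.seed(seed)
  n <- config$n_transcripts
  transcripts <- list()
  tx_rows <- list(); uorf_rows <- list(); site_rows <- list()
  if (n == 0)
    return(list(transcripts = transcripts,
                truth = list(
                  transcripts = data.frame(transcript_id = character()),
                  uorfs = data.frame(transcript_id = character()),
                  erf1_sites = data.frame(transcript_id = character()))))
  context_cycle <- c("GA_design", "C_design")
  n_design <- 0L
  for (i in seq_len(n)) {
    id <- sprintf("tx%04d", i)
    u5 <- sample(config$utr5_length[1]:config$utr5_length[2], 1L)
    cds <- sample(config$cds_length[1]:config$cds_length[2], 1L)
    cds <- cds - (cds %% 3L)
    u3 <- sample(config$utr3_length[1]:config$utr3_length[2], 1L)
    n_codons <- cds %/% 3L
    codons <- c("ATG",
                sample(SENSE_CODONS, n_codons - 2L, replace = TRUE),
                sample(STOP_CODONS, 1L))
    utr5 <- rand_nt(u5)
    utr3 <- rand_nt(u3)

    # designed upstream context: the 3 codons immediately 5' of the stop
    context <- "random"
    if (stats::runif(1) < config$context_fraction && n_codons >= 5L) {
      n_design <- n_design + 1L
      context <- context_cycle[(n_design - 1L) %% 2L + 1L]
      nine <- if (context == "GA_design") {
        paste(sample(c("G", "A"), 9L, replace = TRUE), collapse = "")
      } else {
        paste(sample(c("C", "T"), 9L, replace = TRUE, prob = c(0.8, 0.2)),
              collapse = "")
      }
      codons[(n_codons - 3L):(n_codons - 1L)] <-
        substring(nine, c(1L, 4L, 7L), c(3L, 6L, 9L))
    }

    # planted out-of-frame stop: sense-codon pair carrying a shifted TAA
    outframe <- NULL
    if (stats::runif(1) < config$erf1_outframe_prob && n_codons >= 12L) {
      c0 <- sample(3:(n_codons - 7L), 1L)           # 1-based codon index
      fr <- sample(1:2, 1L)
      pair <- if (fr == 1L) c("CTA", "ATC") else c("ACT", "AAC")
      codons[c0:(c0 + 1L)] <- pair
      outframe <- list(offset_in_cds = (c0 - 1L) * 3L + fr, frame = fr)
    }

    # planted uORF: ATG + sense codons + stop, contained in the 5'UTR
    uorf <- NULL
    if (stats::runif(1) < config$uorf_prob) {
      k <- sample(config$uorf_codons[1]:config$uorf_codons[2], 1L)
      need <- 3L * (k + 1L)
      if (u5 >= need) {
        s <- sample(0:(u5 - need), 1L)
        body <- c("ATG", sample(SENSE_CODONS, k - 1L, replace = TRUE),
                  sample(STOP_CODONS, 1L))
        substr(utr5, s + 1L, s + need) <- paste(body, collapse = "")
        uorf <- list(start = s, stop = s + 3L * k, n_codons = k)
      }
    }

    sequence <- paste0(utr5, paste(codons, collapse = ""), utr3)
    tx <- transcript_model(id, sequence, u5, u5 + cds)
    transcripts[[id]] <- tx

    ctx <- classify_stop_context(tx)
    mult <- switch(config$pausing$model,
      context = config$pausing$base + config$pausing$slope * ctx$ga_fraction,
      loguniform = exp(stats::runif(1, log(config$pausing$min),
                                    log(config$pausing$max))),
      stop("unknown pausing model"))
    leak_rate <- if (mult > 0) config$depth * config$leak_scale / mult else 0

    tx_rows[[id]] <- data.frame(
      transcript_id = id, multiplier = mult, ga_fraction = ctx$ga_fraction,
      c_fraction = ctx$c_fraction, context_design = context,
      leak_rate = leak_rate, stringsAsFactors = FALSE)
    site_rows[[length(site_rows) + 1L]] <- data.frame(
      transcript_id = id, asite_pos = stop_codon_start(tx),
      type = "annotated_stop", frame = 0L, stringsAsFactors = FALSE)
    if (!is.null(uorf)) {
      uorf_rows[[length(uorf_rows) + 1L]] <- data.frame(
        transcript_id = id, start = uorf$start, stop = uorf$stop,
        n_codons = uorf$n_codons, enrichment = config$uorf_enrichment,
        stringsAsFactors = FALSE)
      site_rows[[length(site_rows) + 1L]] <- data.frame(
        transcript_id = id, asite_pos = uorf$stop, type = "uorf_stop",
        frame = frame_of(tx, uorf$stop), stringsAsFactors = FALSE)
    }
    if (!is.null(outframe)) {
      site_rows[[length(site_rows) + 1L]] <- data.frame(
        transcript_id = id, asite_pos = u5 + outframe$offset_in_cds,
        type = "outframe_stop", frame = outframe$frame,
        stringsAsFactors = FALSE)
    }
  }
  empty_uorf <- data.frame(transcript_id = character(), start = integer(),
                           stop = integer(), n_codons = integer(),
                           enrichment = numeric(), stringsAsFactors = FALSE)
  list(transcripts = transcripts,
       truth = list(
         transcripts = do.call(rbind, c(tx_rows, list(make.row.names = FALSE))),
         uorfs = if (length(uorf_rows)) do.call(rbind, uorf_rows) else empty_uorf,
         erf1_sites = do.call(rbind, site_rows)))
}

# Poisson counts per position -> read rows at given 5' ends
reads_at <- function(id, positions, counts, lengths_fn) {
  tot <- sum(counts)
  if (tot == 0)
    return(data.frame(transcript_id = character(), five_prime = integer(),
                      length = integer(), n_mismatches = integer(),
                      n_hits = integer(), stringsAsFactors = FALSE))
  fp <- rep(positions, counts)
  data.frame(transcript_id = id, five_prime = fp, length = lengths_fn(tot),
             n_mismatches = 0L, n_hits = 1L, stringsAsFactors = FALSE)
}

#' Simulate Ribo-seq footprints
#'
#' Uniform-Poisson elongation coverage over CDS 5'-end positions (lengths
#' 28-31 nt); a terminating component of total mean `depth x multiplier`
#' split between 5'-end offsets -15 and -12 from the stop codon, with the
#' bimodal terminating length mixture; frame-agnostic 3'UTR leak reads at
#' the per-transcript leak rate; frame-uniform 5'UTR scanning reads
#' (placed by P-site) plus in-frame enrichment over planted uORF codons.
#'
#' @param sim Output of [generate_transcriptome()].
#' @param config The same [simulation_config()].
#' @param seed Integer RNG seed.
#' @return Read data.frame as from [load_alignments()].
#' @export
simulate_ribo_reads <- function(sim, config, seed) {
  set.seed(seed)
  psite_off <- 12L
  out <- vector("list", length(sim$transcripts))
  truth <- sim$truth$transcripts
  uorfs <- sim$truth$uorfs
  k <- 0L
  len_elong <- function(m) sample(28:31, m, replace = TRUE)
  len_term <- function(m) {
    long <- stats::runif(m) < config$term_long_fraction
    ifelse(long, sample(30:31, m, replace = TRUE),
           sample(20:23, m, replace = TRUE))
  }
  for (tx in sim$transcripts) {
    id <- tx$transcript_id
    tr <- truth[truth$transcript_id == id, ]
    parts <- list()

    cdsp <- cds_positions(tx)
    parts$elong <- reads_at(id, cdsp, stats::rpois(length(cdsp), config$depth),
                            len_elong)

    n_term <- stats::rpois(1, config$depth * tr$multiplier)
    if (n_term > 0) {
      off <- ifelse(stats::runif(n_term) < config$stop_window_split,
                    -15L, -12L)
      if (config$smear_nt > 0)
        off <- off + sample(-config$smear_nt:config$smear_nt, n_term,
                            replace = TRUE)
      fp <- stop_codon_start(tx) + off
      fp <- fp[fp >= 0L]
      parts$term <- data.frame(transcript_id = id, five_prime = fp,
                               length = len_term(length(fp)),
                               n_mismatches = 0L, n_hits = 1L,
                               stringsAsFactors = FALSE)
    }

    if (tx$cds_end < tx$length && tr$leak_rate > 0) {
      u3 <- seq.int(tx$cds_end, tx$length - 1L)
      parts$leak <- reads_at(id, u3, stats::rpois(length(u3), tr$leak_rate),
                             len_elong)
    }

    if (config$utr5_rate > 0 && tx$cds_start > psite_off) {
      # placed by P-site so frame composition is exactly uniform
      tgt <- seq.int(psite_off, tx$cds_start - 1L)
      cnt <- stats::rpois(length(tgt), config$utr5_rate)
      u <- uorfs[uorfs$transcript_id == id, ]
      if (nrow(u) == 1 && config$uorf_enrichment > 1) {
        inframe <- u$start + 3L * (seq_len(u$n_codons) - 1L)
        sel <- tgt %in% inframe
        cnt[sel] <- cnt[sel] +
          stats::rpois(sum(sel), config$utr5_rate * (config$uorf_enrichment - 1))
      }
      parts$scan <- reads_at(id, tgt - psite_off, cnt, len_elong)
    }

    k <- k + 1L
    out[[k]] <- do.call(rbind, parts)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate eRF1-seq footprints
#'
#' Reads with 5' ends 15 nt upstream of each planted termination site's
#' A-site codon (annotated stops, uORF stops, planted out-of-frame stops),
#' Poisson with mean `erf1_site_mean` per site, over a uniform Poisson CDS
#' background at `erf1_background` reads per nt. Lengths 30-31 nt.
#'
#' @inheritParams simulate_ribo_reads
#' @return Read data.frame.
#' @export
simulate_erf1_reads <- function(sim, config, seed) {
  set.seed(seed)
  out <- vector("list", length(sim$transcripts))
  sites <- sim$truth$erf1_sites
  k <- 0L
  len_term <- function(m) sample(30:31, m, replace = TRUE)
  for (tx in sim$transcripts) {
    id <- tx$transcript_id
    parts <- list()
    st <- sites[sites$transcript_id == id, ]
    if (nrow(st) > 0) {
      fp <- st$asite_pos - 15L
      cnt <- stats::rpois(nrow(st), config$erf1_site_mean)
      keep <- fp >= 0L
      parts$sites <- reads_at(id, fp[keep], cnt[keep], len_term)
    }
    if (config$erf1_background > 0) {
      cdsp <- cds_positions(tx)
      parts$bg <- reads_at(id, cdsp,
                           stats::rpois(length(cdsp), config$erf1_background),
                           len_term)
    }
    k <- k + 1L
    out[[k]] <- do.call(rbind, parts)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(transcript_id = character(), five_prime = integer(),
                      length = integer(), n_mismatches = integer(),
                      n_hits = integer(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Simulate an MPRA insert library
#'
#' Draws `n_variants` distinct random 9-mers; each variant's monosome
#' partition probability is `p_stop` when it carries an in-frame stop codon
#' (offsets 0/3/6) and `p_base` otherwise, optionally shifted by
#' `ga_coef x (GA fraction - 0.5)` and clipped to `[0, 1]`. Reads per
#' fraction are drawn by multinomial sampling over variants at the
#' configured depths (variant abundances equal).
#'
#' @param config A [simulation_config()] (field `mpra`).
#' @param seed Integer RNG seed.
#' @return List with `mono_reads`, `poly_reads` (character vectors of raw
#'   insert reads) and `truth` (insert, `p_mono`, `has_inframe_stop`,
#'   `ga_fraction`).
#' @export
simulate_mpra_library <- function(config, seed) {
  set.seed(seed)
  m <- config$mpra
  if (m$n_variants > 4^9) stop("more variants than distinct 9-mers")
  idx <- sample.int(4^9, m$n_variants) - 1L
  base <- c("A", "C", "G", "T")
  mat <- matrix("", m$n_variants, 9L)
  v <- idx
  for (p in 9:1) { mat[, p] <- base[v %% 4L + 1L]; v <- v %/% 4L }
  inserts <- apply(mat, 1, paste, collapse = "")
  stopflag <- has_inframe_stop(inserts)
  ga <- (nchar(gsub("[^GA]", "", inserts))) / 9
  p_mono <- ifelse(stopflag, m$p_stop, m$p_base) + m$ga_coef * (ga - 0.5)
  p_mono <- pmin(pmax(p_mono, 0), 1)
  cm <- stats::rmultinom(1, m$depth_mono, prob = p_mono)[, 1]
  cp <- stats::rmultinom(1, m$depth_poly, prob = 1 - p_mono)[, 1]
  list(mono_reads = rep(inserts, cm),
       poly_reads = rep(inserts, cp),
       truth = data.frame(insert = inserts, p_mono = p_mono,
                          has_inframe_stop = stopflag, ga_fraction = ga,
                          stringsAsFactors = FALSE))
}

#' Write a transcript set as FASTA + annotation TSV
#'
#' @param transcripts Named list of [transcript_model()]s.
#' @param fasta_path,annotation_path Output paths.
#' @export
write_transcriptome <- function(transcripts, fasta_path, annotation_path) {
  seqs <- Biostrings::DNAStringSet(vapply(transcripts, `[[`, "", "sequence"))
  names(seqs) <- vapply(transcripts, `[[`, "", "transcript_id")
  Biostrings::writeXStringSet(seqs, fasta_path)
  ann <- data.frame(
    transcript_id = names(seqs),
    cds_start = vapply(transcripts, `[[`, 0L, "cds_start"),
    cds_end = vapply(transcripts, `[[`, 0L, "cds_end"))
  write_table(ann, annotation_path)
  invisible(fasta_path)
}

#' Write footprint reads as SAM
#'
#' Minimal single-end forward-strand SAM in transcriptome coordinates with
#' `NM`/`NH` tags, loadable by [load_alignments()].
#'
#' @param reads Read data.frame.
#' @param transcripts Named list of [transcript_model()]s (for `@SQ` lines
#'   and sequences).
#' @param path Output path.
#' @export
write_reads_sam <- function(reads, transcripts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (tx in transcripts)
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", tx$transcript_id, tx$length), con)
  if (nrow(reads) > 0) {
    seqs <- vapply(seq_len(nrow(reads)), function(i) {
      tx <- transcripts[[reads$transcript_id[i]]]
      end <- min(reads$five_prime[i] + reads$length[i], tx$length)
      subseq0(tx, reads$five_prime[i], end)
    }, character(1))
    lines <- sprintf("r%06d\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d\tNH:i:%d",
                     seq_len(nrow(reads)), reads$transcript_id,
                     reads$five_prime + 1L, nchar(seqs), seqs,
                     reads$n_mismatches, reads$n_hits)
    writeLines(lines, con)
  }
  invisible(path)
}
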