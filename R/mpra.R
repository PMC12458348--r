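#' Gate raw MPRA insert reads
#'
#' Keeps only trimmed insert reads exactly 9 nt long over the unambiguous
#' {A,C,G,T} alphabet (`U` mapped to `T`, case-folded); everything else is
#' dropped and counted by rejection reason.
#'
#' @param raw_inserts Character vector of trimmed insert sequences.
#' @param insert_length Required length (default 9).
#' @return Character vector of passing inserts with attribute `"rejected"`,
#'   a named count vector (`wrong_length`, `ambiguous_base`).
#' @export
gate_inserts <- function(raw_inserts, insert_length = 9L) {
  x <- chartr("U", "T", toupper(raw_inserts))
  wrong_len <- nchar(x) != insert_length
  ambiguous <- !wrong_len & grepl("[^ACGT]", x)
  keep <- x[!wrong_len & !ambiguous]
  attr(keep, "rejected") <- c(wrong_length = sum(wrong_len),
                              ambiguous_base = sum(ambiguous))
  keep
}

#' Count gated inserts and compute RPM
#'
#' Reads are counted per distinct insert and normalized to reads per million
#' within the fraction: `rpm = count / total * 1e6`, so RPM sums to 1e6.
#'
#' @param inserts Character vector of gated insert reads for one fraction.
#' @return data.frame with columns `insert`, `count`, `rpm`.
#' @export
count_and_rpm <- function(inserts) {
  if (length(inserts) == 0) stop("no passing reads in fraction")
  tab <- table(inserts)
  data.frame(insert = names(tab), count = as.integer(tab),
             rpm = as.numeric(tab) / sum(tab) * 1e6,
             stringsAsFactors = FALSE)
}

has_inframe_stop <- function(inserts) {
  vapply(inserts, function(s) {
    any(substring(s, c(1L, 4L, 7L), c(3L, 6L, 9L)) %in% STOP_CODONS)
  }, logical(1), USE.NAMES = FALSE)
}

#' Monosome/polysome ratio per MPRA variant
#'
#' Joins the two per-fraction count tables on the union of inserts and
#' computes `mp_ratio = (rpm_mono + pseudocount) / (rpm_poly + pseudocount)`.
#' With `pseudocount = 0`, variants absent from either fraction get an `NA`
#' ratio rather than 0 or infinity.
#'
#' @param table_mono,table_poly Outputs of [count_and_rpm()].
#' @param pseudocount_rpm Pseudocount in RPM units (default 0.5).
#' @return data.frame of `MpraVariant` rows: `insert`, `count_mono`,
#'   `count_poly`, `rpm_mono`, `rpm_poly`, `mp_ratio`, `has_inframe_stop`.
#' @export
mp_ratio <- function(table_mono, table_poly, pseudocount_rpm = 0.5) {
  if (pseudocount_rpm < 0) stop("pseudocount must be >= 0")
  inserts <- sort(union(table_mono$insert, table_poly$insert))
  im <- match(inserts, table_mono$insert)
  ip <- match(inserts, table_poly$insert)
  cm <- ifelse(is.na(im), 0L, table_mono$count[im])
  cp <- ifelse(is.na(ip), 0L, table_poly$count[ip])
  rm_ <- ifelse(is.na(im), 0, table_mono$rpm[im])
  rp <- ifelse(is.na(ip), 0, table_poly$rpm[ip])
  ratio <- (rm_ + pseudocount_rpm) / (rp + pseudocount_rpm)
  if (pseudocount_rpm == 0) ratio[rm_ == 0 | rp == 0] <- NA_real_
  data.frame(insert = inserts, count_mono = cm, count_poly = cp,
             rpm_mono = rm_, rpm_poly = rp, mp_ratio = ratio,
             has_inframe_stop = has_inframe_stop(inserts),
             stringsAsFactors = FALSE)
}

#' Positional codon matrix of mean M/P ratios
#'
#' For every codon c (64) and 3-mer start offset p (0..6 within the 9-nt
#' insert), the mean M/P ratio over variants whose insert carries c at p.
#' Cells with no contributing variant are `NA` (missing, not zero). The
#' per-codon mean averages each codon's defined offset entries, and the
#' stop-codon rows are reported with their rank among the 64 per-codon means.
#'
#' @param variants Output of [mp_ratio()] (rows with `NA` ratio are ignored).
#' @return List with `values` (64 x 7 matrix), `n` (contributing-variant
#'   counts), `codon_mean` (named length-64 vector), and `stop_ranks`
#'   (rank of TAA/TAG/TGA among per-codon means, 1 = highest).
#' @export
positional_codon_matrix <- function(variants) {
  variants <- variants[!is.na(variants$mp_ratio), , drop = FALSE]
  if (nrow(variants) == 0) stop("no variants with defined M/P ratio")
  offsets <- 0:6
  vals <- matrix(NA_real_, 64, 7, dimnames = list(ALL_CODONS, offsets))
  nmat <- matrix(0L, 64, 7, dimnames = list(ALL_CODONS, offsets))
  for (p in offsets) {
    tri <- substr(variants$insert, p + 1L, p + 3L)
    sums <- tapply(variants$mp_ratio, tri, sum)
    cnts <- tapply(variants$mp_ratio, tri, length)
    idx <- match(names(sums), ALL_CODONS)
    vals[idx, p + 1L] <- sums / cnts
    nmat[idx, p + 1L] <- as.integer(cnts)
  }
  codon_mean <- rowMeans(vals, na.rm = TRUE)
  codon_mean[rowSums(nmat) == 0] <- NA_real_
  rk <- rank(-codon_mean, ties.method = "min", na.last = "keep")
  list(values = vals, n = nmat, codon_mean = codon_mean,
       stop_ranks = rk[STOP_CODONS])
}

#' Per-frame codon enrichment of M/P ratios
#'
#' Offsets are grouped by `offset mod 3` (frame 0 is in-frame with the
#' upstream ORF by construct design); for each codon the mean M/P per frame
#' is reported together with `enrichment` = frame-0 mean / mean of frames
#' 1-2. Frame-shifted shadows of stop codons (NTA/NTG patterns in frame 2)
#' inherit elevated means when stops drive monosome retention.
#'
#' @param variants Output of [mp_ratio()].
#' @return data.frame with `codon`, `frame0`, `frame1`, `frame2`,
#'   `enrichment`.
#' @export
frame_enrichment <- function(variants) {
  m <- positional_codon_matrix(variants)
  frame_mean <- function(f) {
    cols <- which((0:6) %% 3 == f)
    v <- m$values[, cols, drop = FALSE]
    n <- m$n[, cols, drop = FALSE]
    out <- rowSums(v * n, na.rm = TRUE) / rowSums(n)
    out[rowSums(n) == 0] <- NA_real_
    out
  }
  f0 <- frame_mean(0); f1 <- frame_mean(1); f2 <- frame_mean(2)
  off <- rowMeans(cbind(f1, f2), na.rm = TRUE)
  data.frame(codon = ALL_CODONS, frame0 = f0, frame1 = f1, frame2 = f2,
             enrichment = f0 / off, stringsAsFactors = FALSE,
             row.names = NULL)
}
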