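#' Stop-codon pausing index of one mRNA
#'
#' Ratio of footprint 5'-end density in a window of offsets around the stop
#' codon to the mean CDS density. The default window `[-15, -12]` (relative
#' to the stop codon's first nt, inclusive) covers both terminating 5'-end
#' peaks: -15 nt (stop codon in the A site) and the forward-shifted -12 nt
#' population. A pure ratio: no pseudocounts, depth-invariant.
#'
#' @param profile A 5'-end anchored [coverage_profile()] (raw counts).
#' @param transcript The matching [transcript_model()].
#' @param stop_window Inclusive offset range `c(lo, hi)` relative to the stop
#'   codon's first nt; default `c(-15, -12)`.
#' @return Non-negative scalar pausing index.
#' @export
stop_pausing_index <- function(profile, transcript, stop_window = c(-15L, -12L)) {
  cds <- profile$counts[cds_positions(transcript) + 1L]
  cds_mean <- sum(cds) / length(cds)
  if (cds_mean == 0) stop("zero CDS counts on ", transcript$transcript_id)
  w <- stop_codon_start(transcript) + seq.int(stop_window[1], stop_window[2])
  w <- w[w >= 0L & w < transcript$length]
  win_mean <- sum(profile$counts[w + 1L]) / length(seq.int(stop_window[1],
                                                           stop_window[2]))
  win_mean / cds_mean
}

#' Relative 3'UTR footprint density of one mRNA
#'
#' (3'UTR counts / 3'UTR length) / (CDS counts / CDS length). Positions
#' falling inside the stop window are excluded from the 3'UTR tally (with the
#' default window they never are: the window lies upstream of the stop).
#' mRNAs that read through or fail to pause show elevated values.
#'
#' @inheritParams stop_pausing_index
#' @return Non-negative scalar, or `NA` when the transcript has no 3'UTR.
#' @export
utr3_relative_density <- function(profile, transcript,
                                  stop_window = c(-15L, -12L)) {
  if (transcript$cds_end >= transcript$length) return(NA_real_)
  utr3 <- seq.int(transcript$cds_end, transcript$length - 1L)
  win <- stop_codon_start(transcript) + seq.int(stop_window[1], stop_window[2])
  utr3 <- setdiff(utr3, win)
  cds <- profile$counts[cds_positions(transcript) + 1L]
  cds_mean <- sum(cds) / length(cds)
  if (cds_mean == 0) stop("zero CDS counts on ", transcript$transcript_id)
  (sum(profile$counts[utr3 + 1L]) / length(utr3)) / cds_mean
}

#' Classify the sequence context upstream of the stop codon
#'
#' Composition of the window immediately 5' of the stop codon (default 9 nt,
#' the size of the reporter-assay inserts). `ga_fraction` is the combined G+A
#' fraction, `c_fraction` the C fraction. The label is `GA_rich` when
#' `ga_fraction >= t_ga`, else `C_rich` when `c_fraction >= t_c`, else
#' `other`; the thresholds are interpretive configuration, not measured
#' constants, and `GA_rich` takes precedence when both fire.
#'
#' @param transcript A [transcript_model()].
#' @param upstream_window_nt Window length in nt (default 9); must fit inside
#'   the CDS upstream of the stop codon.
#' @param t_ga,t_c Label thresholds (defaults 7/9 and 5/9).
#' @return List with `label`, `ga_fraction`, `c_fraction`.
#' @export
classify_stop_context <- function(transcript, upstream_window_nt = 9L,
                                  t_ga = 7 / 9, t_c = 5 / 9) {
  s <- stop_codon_start(transcript)
  if (s - upstream_window_nt < transcript$cds_start)
    stop("context window extends past the start codon on ",
         transcript$transcript_id)
  win <- subseq0(transcript, s - upstream_window_nt, s)
  ltr <- strsplit(win, "")[[1]]
  ga <- mean(ltr %in% c("G", "A"))
  cc <- mean(ltr == "C")
  label <- if (ga >= t_ga) "GA_rich" else if (cc >= t_c) "C_rich" else "other"
  list(label = label, ga_fraction = ga, c_fraction = cc)
}

#' Per-mRNA pausing table
#'
#' One row per filter-passing transcript: pausing index, CDS mean density,
#' relative 3'UTR density, and upstream stop-codon context.
#'
#' @param reads Read data.frame (already quality-filtered or not; rows failing
#'   [read_passes_filters()] are removed here).
#' @param transcripts Named list of [transcript_model()]s.
#' @param stop_window Inclusive 5'-end offset window (default `c(-15, -12)`).
#' @param upstream_window_nt Context window (default 9 nt).
#' @param length_range Optional read-length filter.
#' @param ... Passed to [classify_stop_context()].
#' @return data.frame of `PausingRecord` rows, with the per-transcript raw
#'   5'-end profiles attached as attribute `"profiles"`.
#' @export
pausing_table <- function(reads, transcripts, stop_window = c(-15L, -12L),
                          upstream_window_nt = 9L, length_range = NULL, ...) {
  reads <- reads[read_passes_filters(reads), , drop = FALSE]
  anchor <- anchor_config("five_prime")
  rows <- list()
  profiles <- list()
  for (tx in transcripts) {
    prof <- build_profile(reads, tx, anchor, length_range)
    if (!passes_cds_filters(prof, tx)) next
    ctx <- classify_stop_context(tx, upstream_window_nt, ...)
    cds <- prof$counts[cds_positions(tx) + 1L]
    rows[[tx$transcript_id]] <- data.frame(
      transcript_id = tx$transcript_id,
      pausing_index = stop_pausing_index(prof, tx, stop_window),
      cds_mean_density = sum(cds) / length(cds),
      utr3_relative_density = utr3_relative_density(prof, tx, stop_window),
      context_label = ctx$label,
      ga_fraction = ctx$ga_fraction,
      c_fraction = ctx$c_fraction,
      stringsAsFactors = FALSE
    )
    profiles[[tx$transcript_id]] <- prof
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(transcript_id = character(), pausing_index = numeric(),
                      cds_mean_density = numeric(),
                      utr3_relative_density = numeric(),
                      context_label = character(), ga_fraction = numeric(),
                      c_fraction = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "profiles") <- profiles
  attr(out, "stop_window") <- stop_window
  out
}

#' Pausing summary stratified by stop-codon context
#'
#' Runs the stop-aligned metagene separately for each context label and
#' summarizes the per-label pausing-index distribution (quartiles). High/Low
#' pausing classes are defined as the top and bottom quartile of the index.
#'
#' @param records A [pausing_table()] result (profiles attached).
#' @param transcripts Named list of [transcript_model()]s.
#' @param offsets Metagene offsets (default `-50:20`).
#' @return List with `metagene` (named list of per-label metagene tables),
#'   `summary` (per-label index quartiles and mean), and `classes`
#'   (per-transcript High/Low/Mid pausing class).
#' @export
stratified_pausing_summary <- function(records, transcripts, offsets = -50:20) {
  profiles <- attr(records, "profiles")
  if (nrow(records) == 0) stop("no transcripts in pausing table")
  norm <- lapply(records$transcript_id, function(id)
    normalize_by_cds(profiles[[id]], transcripts[[id]]))
  names(norm) <- records$transcript_id

  metagene <- list()
  for (lab in unique(records$context_label)) {
    ids <- records$transcript_id[records$context_label == lab]
    if (length(ids) == 0) { warning("empty label ", lab); next }
    metagene[[lab]] <- metagene_aggregate(norm[ids], transcripts,
                                          align_to = "stop", offsets = offsets)
  }
  summary <- do.call(rbind, lapply(split(records, records$context_label),
    function(d) data.frame(
      context_label = d$context_label[1], n = nrow(d),
      q25 = stats::quantile(d$pausing_index, 0.25, names = FALSE),
      median = stats::median(d$pausing_index),
      q75 = stats::quantile(d$pausing_index, 0.75, names = FALSE),
      mean = mean(d$pausing_index), stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  qs <- stats::quantile(records$pausing_index, c(0.25, 0.75), names = FALSE)
  classes <- data.frame(
    transcript_id = records$transcript_id,
    pausing_class = ifelse(records$pausing_index >= qs[2], "High",
                           ifelse(records$pausing_index <= qs[1], "Low", "Mid")),
    stringsAsFactors = FALSE)
  list(metagene = metagene, summary = summary, classes = classes)
}
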