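#' Load a transcriptome from FASTA plus CDS annotation
#'
#' Reads transcript sequences and a CDS annotation table and returns one
#' validated [transcript_model()] per annotated transcript. Sequences are
#' upper-cased and `U` mapped to `T` at load time; all downstream codon logic
#' uses the DNA alphabet.
#'
#' The annotation is a TSV with columns `transcript_id`, `cds_start`,
#' `cds_end` (0-based, half-open, stop-codon inclusive). A FASTA record with
#' no annotation row is skipped with a warning; an annotated transcript whose
#' CDS is not a multiple of 3 or lacks a terminal stop codon is a load error,
#' or is skipped (with the reason recorded) when `permissive = TRUE`.
#'
#' @param fasta_path Path to a FASTA file of transcript sequences.
#' @param annotation_path Path to the annotation TSV.
#' @param permissive Skip invalid transcripts instead of erroring.
#' @return Named list of [transcript_model()] objects, with attribute
#'   `"rejected"` (data.frame of transcript_id + reason) listing skipped
#'   records.
#' @export
load_transcriptome <- function(fasta_path, annotation_path, permissive = FALSE) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "cds_start", "cds_end")
  if (!all(need %in% names(ann)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))

  models <- list()
  rejected <- data.frame(transcript_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  for (i in seq_along(seqs)) {
    id <- ids[i]
    j <- match(id, ann$transcript_id)
    if (is.na(j)) {
      warning("no annotation for FASTA record '", id, "'; skipped")
      rejected <- rbind(rejected, data.frame(transcript_id = id,
                                             reason = "no annotation"))
      next
    }
    tm <- tryCatch(
      transcript_model(id, as.character(seqs[[i]]),
                       ann$cds_start[j], ann$cds_end[j]),
      error = function(e) e
    )
    if (inherits(tm, "error")) {
      if (!permissive) stop(conditionMessage(tm))
      rejected <- rbind(rejected, data.frame(transcript_id = id,
                                             reason = conditionMessage(tm)))
      next
    }
    models[[id]] <- tm
  }
  attr(models, "rejected") <- rejected
  models
}

#' Load footprint alignments
#'
#' Parses footprint alignments in transcriptome coordinates into a read table
#' with one row per mapped read. Three formats are supported:
#' a 5-column TSV (`transcript_id`, `five_prime`, `length`, `n_mismatches`,
#' `n_hits`), SAM, or BAM. For SAM/BAM, `five_prime` is the 0-based leftmost
#' aligned base; reads are assumed forward-strand on the transcript and
#' reverse-strand records are dropped and counted; `n_mismatches` comes from
#' the `NM` tag (missing: 0 with a warning) and `n_hits` from `NH`
#' (missing: 1).
#'
#' This function only parses; the alignment-quality filter is
#' [read_passes_filters()].
#'
#' @param path Input file.
#' @param format One of `"tsv"`, `"sam"`, `"bam"`; default guessed from the
#'   file extension.
#' @return data.frame with columns `transcript_id`, `five_prime`, `length`,
#'   `n_mismatches`, `n_hits`, with attribute `"n_dropped_reverse"`.
#' @export
load_alignments <- function(path, format = c("auto", "tsv", "sam", "bam")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sam = "sam", bam = "bam", "tsv")
  }
  if (format == "tsv") {
    reads <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("transcript_id", "five_prime", "length", "n_mismatches", "n_hits")
    if (!all(need %in% names(reads)))
      stop("read TSV must have columns: ", paste(need, collapse = ", "))
    reads <- reads[, need]
    bad <- which(!is.finite(reads$five_prime) | reads$five_prime < 0 |
                   reads$length < 15)
    if (length(bad))
      stop("unparseable/invalid read record at line ", bad[1] + 1L)
    attr(reads, "n_dropped_reverse") <- 0L
    return(reads)
  }

  bam <- path
  if (format == "sam") {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "strand", "qwidth"),
    tag = c("NM", "NH"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  rev <- rec$strand == "-"
  n_rev <- sum(rev, na.rm = TRUE)
  keep <- !rev
  nm <- rec$tag$NM
  nh <- rec$tag$NH
  if (is.null(nm) || all(is.na(nm))) {
    warning("NM tag missing; mismatches treated as 0")
    nm <- rep(0L, length(rec$pos))
  }
  nm[is.na(nm)] <- 0L
  if (is.null(nh)) nh <- rep(1L, length(rec$pos))
  nh[is.na(nh)] <- 1L
  reads <- data.frame(
    transcript_id = as.character(rec$rname)[keep],
    five_prime = rec$pos[keep] - 1L,
    length = rec$qwidth[keep],
    n_mismatches = as.integer(nm)[keep],
    n_hits = as.integer(nh)[keep],
    stringsAsFactors = FALSE
  )
  attr(reads, "n_dropped_reverse") <- as.integer(n_rev)
  reads
}

#' Alignment-quality read filter
#'
#' Keeps uniquely mapped reads with at most 2 mismatches: multimappers
#' (`n_hits > 1`) and reads with more than 2 mismatches are disregarded.
#'
#' @param reads Read data.frame (or single-row list) with `n_hits` and
#'   `n_mismatches`.
#' @param max_mismatches Maximum tolerated mismatches (default 2).
#' @return Logical vector, `TRUE` for reads that pass.
#' @export
read_passes_filters <- function(reads, max_mismatches = 2L) {
  reads$n_hits == 1L & reads$n_mismatches <= max_mismatches
}

#' Write / read a coverage profile as bedGraph
#'
#' Serializes the per-nucleotide counts of a [coverage_profile()] as bedGraph
#' (transcript id as the chrom field; 0-based half-open intervals; runs of
#' equal value merged; zero runs omitted unless `keep_zero = TRUE`).
#'
#' @param profile A [coverage_profile()].
#' @param path Output path.
#' @param keep_zero Also emit zero-valued runs.
#' @export
write_coverage <- function(profile, path, keep_zero = FALSE) {
  counts <- profile$counts
  r <- rle(counts)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- if (keep_zero) rep(TRUE, length(r$values)) else r$values != 0
  df <- data.frame(chrom = profile$transcript_id,
                   start = starts[keep], end = ends[keep],
                   value = r$values[keep])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_coverage
#' @param transcript_length Length of the counts vector to reconstruct.
#' @param anchor Anchor mode recorded on the reconstructed profile.
#' @return `read_coverage`: a [coverage_profile()].
#' @export
read_coverage <- function(path, transcript_length, anchor = "five_prime") {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "value"))
  counts <- numeric(transcript_length)
  for (i in seq_len(nrow(df))) {
    counts[(df$start[i] + 1L):df$end[i]] <- df$value[i]
  }
  coverage_profile(df$chrom[1], counts, anchor)
}

#' Write a result table as TSV
#'
#' TSV with a header line; round-trips through [utils::read.delim()].
#'
#' @param records data.frame.
#' @param path Output path.
#' @export
write_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
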