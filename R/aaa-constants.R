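# Shared sequence constants (file sorts first so later files can use them
# at top level).

#' Stop codons (DNA alphabet)
#' @export
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' All 64 codons in lexicographic order
#' @export
ALL_CODONS <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                c("A", "C", "G", "T"))[, 3:1], 1, paste,
                    collapse = "")

#' The 61 sense codons
#' @export
SENSE_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)
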