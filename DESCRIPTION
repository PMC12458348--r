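Package: riboterm
Title: Analysis of Translation Termination from Ribosome Profiling Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for profiling terminating ribosomes from ribosome
    footprint data in transcriptome coordinates: footprint anchor
    assignment (5' end, P-site, A-site), CDS-normalized metagene
    aggregation, a per-mRNA stop-codon pausing index with upstream
    sequence-context stratification, sliding-window termination peak
    calling for release-factor selective profiling (eRF1-seq) with
    region/frame/A-site codon annotation, detection of translated
    upstream open reading frames by per-frame Wilcoxon tests combined
    with Stouffer's method under FDR control, and monosome/polysome
    partitioning analysis of massively parallel reporter assay (MPRA)
    libraries with 9-nt random inserts. Includes a synthetic-data
    generator that emulates the statistical structure of the sequencing
    inputs with ground-truth tables for every planted signal.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
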