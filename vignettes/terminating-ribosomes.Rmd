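---
title: "Profiling terminating ribosomes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling terminating ribosomes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboterm)
```

This vignette describes the models and procedures implemented in
`riboterm`, the assumptions behind them, the free parameters and their
defaults, and the places where the design was genuinely open and a choice
had to be made.

## Coordinates and anchors

Everything runs in transcript space with 0-based, half-open coordinates.
A transcript model is a sequence plus `cds_start` and `cds_end`, with the
CDS *including* the stop codon, so the stop codon is always
`[cds_end - 3, cds_end)` and the three regions partition every position:
5'UTR `[0, cds_start)`, CDS `[cds_start, cds_end)`, 3'UTR
`[cds_end, length)`. `U` is mapped to `T` at load time; all codon logic
uses the DNA alphabet.

A footprint is reduced to a single anchor coordinate. With the 5' end at
position 0 of the read, the P-site codon occupies read positions 12–14 and
the A-site codon positions 15–17; `anchor_config()` exposes `five_prime`,
`psite` (+12), and `asite` (+15) modes. During termination the stop codon
sits in the A site, so terminating footprints produce a 5'-end peak at
−15 nt relative to the stop codon's first nt; a second, forward-shifted
population appears at −12 nt. Reads are quality-filtered before any
counting: multimappers (`NH > 1`) and reads with more than 2 mismatches
are discarded. Anchors that fall beyond the transcript end are dropped
per-read rather than erroring; a footprint overhanging the 3' end is kept
as long as its anchor is in range (edge handling the upstream literature
leaves unstated; this is our convention).

## Metagene profiles

Per-mRNA coverage is normalized by the mean CDS density, so the CDS
average of every normalized profile is exactly 1 and mRNA abundance and
translation efficiency cancel. mRNAs with fewer than 16 CDS reads or with
under 10% of CDS positions covered are excluded (both thresholds
inclusive). Normalized densities at equal distances from the start or
stop codon are then averaged across mRNAs. Because transcripts have
different UTR lengths, a transcript contributes to offset *d* only when
that offset exists on it; per-offset denominators are reported. Filters
are evaluated on the unstratified profile and then applied uniformly to
all read-length strata of that transcript, so stratified profiles always
sum to the unstratified one.

## Stop-codon pausing index

For each mRNA the pausing index is the mean 5'-end count over the stop
window (default offsets −15 to −12 inclusive, covering both terminating
peaks) divided by the mean CDS density. It is a pure ratio — no
pseudocounts — hence exactly depth-invariant and exactly zero when the
window is empty. Whether the original analyses used one or both stop
peaks is not documented; the default window covers both, and a
single-offset window is available via `stop_window` for sensitivity
analysis. All read lengths contribute by default since terminating
footprints span both the long (30–31 nt) and short (20–23 nt) classes.

The per-mRNA 3'UTR relative density — (3'UTR counts / 3'UTR length) /
(CDS density) — is the quantity behind the observation that mRNAs lacking
termination pausing show elevated 3'UTR occupancy.

**Stop-context stratification.** "GA-rich" and "C-rich" stop contexts are
nowhere defined numerically in the literature this package follows, so
the classification is a declared interpretation: over the 9 nt
immediately 5' of the stop codon (the 9-nt window matches the MPRA insert
length), `ga_fraction = (#G + #A)/9` and `c_fraction = #C/9`, with labels
GA_rich at `ga_fraction >= 7/9` and C_rich at `c_fraction >= 5/9`
(GA_rich wins if both fire). The thresholds are configuration, not
measured constants; they were chosen so that designed all-{G,A} 9-mers
and C-biased 9-mers classify cleanly while typical random contexts fall
into "other". High/Low pausing classes are the top/bottom quartiles of
the index distribution, again because no published cut exists.

## Termination peak calling (eRF1-seq)

The caller implements a deterministic fold rule: a site is a peak when
its count strictly exceeds `fold_threshold` (default 10) times the mean
of a `window_nt` (default 120) window, after excluding mRNAs with fewer
than 10 total reads. Three details are underdetermined by that rule and
fixed here as package conventions:

* the window is *centred* on the candidate site, clipped at transcript
  ends, and its mean is taken over the positions actually in range,
  *including* the candidate — the most conservative reading, and the one
  that keeps the threshold well-defined at transcript edges;
* the inequality is strict, so a site at exactly 10x the window mean is
  not a peak;
* runs of candidate sites within 2 nt collapse to the maximal-count site
  (ties to the 5'-most). The −15/−12 terminating doublet is 3 nt apart
  and deliberately survives collapsing.

Calling is scale-invariant by construction. Annotation adds the A-site
position (+15), its codon, region, frame relative to the annotated start,
and two flags of biological interest: `at_annotated_stop` /
`at_uorf_stop`, and the shifted-stop status. For the latter both a raw
offset label (`minus1`/`plus1`: where the overlapping stop codon starts
relative to the A-site codon) and a `shift_label` naming the ribosomal
frameshift that would read that stop are emitted, because the two sign
conventions are easy to confuse: a CTG whose TGA starts one nt 3' is
the −1-frameshift class, and a GAG whose TGA starts one nt 5' is the
+1-frameshift class. The downstream/upstream Ribo-seq density ratio
(`termination_drop_ratio`, default 60-nt flanks, A-site codon excluded)
separates true termination (ratio well below 1) from eRF1 binding at
stop-like sense codons (no drop).

## Translated-uORF calling

Candidates are all AUGs starting in the 5'UTR, each paired with the first
in-frame stop codon downstream, scanning into the CDS if necessary
(overlapping uORFs); near-cognate starts are excluded. For a candidate of
*n* codons the P-site counts at `start + 3j` (frame 0) are compared to
those at `+1` and `+2` with two paired one-sided Wilcoxon signed-rank
tests. Design choices:

* **paired per-codon** rather than unpaired rank-sum: pairing the three
  frames within each codon position controls position-to-position depth
  variation and is the stricter reading of "Wilcoxon test"; an unpaired
  interpretation would confound frame preference with coverage gradients.
* **exact null distribution** for up to 25 informative differences: zero
  differences are dropped, ties take midranks, and the distribution of
  the positive-rank sum is computed by dynamic programming over the
  generating function of the doubled ranks, which stays exact under
  midranks (the standard `wilcox.test` refuses exact p-values there).
  Above n = 25 a normal approximation with tie-corrected variance and
  0.5 continuity correction takes over. If every difference is zero the
  p-value is 1.
* the two p-values are combined by Stouffer's method with equal weights,
  `p = 1 - Φ((z1 + z2)/√2)`, with p = 1 clipped at 1 − 10⁻¹² to keep the
  normal score finite, and adjusted across all candidates jointly by
  Benjamini–Hochberg; `robust` means q < 0.05.

A candidate is testable with at least 2 codons and at least 8 P-site
counts within its span (a configurable gate replacing the CDS-level
filters, which do not apply to 5'UTR signal).

## MPRA analysis

Insert reads are gated to exactly 9 unambiguous nt, counted per distinct
insert, and normalized to reads per million within each fraction, so RPM
sums to 10⁶ exactly. The monosome/polysome ratio uses a pseudocount of
0.5 RPM in both numerator and denominator — the handling of variants
absent from one fraction is not documented anywhere, and with a
pseudocount of 0 such variants are reported missing rather than 0 or
infinite. The positional matrix averages M/P over variants carrying each
of the 64 codons at each of the 7 3-mer offsets (0–6) of the insert;
using all 7 offsets rather than the 3 codon-aligned slots preserves the
observation that the pausing motif carries no reading-frame information,
and frame-restricted summaries (`frame_enrichment`) derive from the same
matrix. Variants are distinct 9-mers; reads are counted without UMI
collapsing.

## The synthetic-data generator

The generator emulates the statistical structure the analyses assume,
with every planted signal recorded in a ground-truth table:

* random transcripts (defaults: 5'UTRs 60–120 nt, CDSs 150–600 nt, 3'UTRs
  60–150 nt) with ATG/stop at the CDS boundaries and no accidental
  in-frame CDS stops; half the transcripts receive a designed 9-mer
  before the stop ({G,A} or C-biased {C,T}) so both context classes are
  populated;
* elongation coverage is uniform Poisson (default 5 reads/nt) — the
  analyses normalize by the CDS mean, so codon-specific dwell times would
  add realism without changing what is being tested;
* terminating reads with total mean `depth × multiplier` at 5'-end
  offsets −15/−12 (default split 0.7/0.3, no smearing), lengths drawn
  from the bimodal 30–31 / 20–23 nt mixture. The default multiplier model
  is `1 + 8 × GA-fraction` of the upstream 9-mer, giving roughly an
  order-of-magnitude pausing range between C-rich and pure-GA contexts —
  a deliberately strong but desk-scale version of the wide pausing range
  seen in cells; a log-uniform multiplier model is available for
  rank-recovery studies;
* 3'UTR leak reads are frame-uniform (encoding the poor 3-nt periodicity
  of 3'UTR footprints) with per-nt rate `depth × 0.1 / multiplier` — the
  inverse link and scale are free parameters, since no quantitative leak
  model has been published;
* eRF1-seq reads sit at −15 from each planted termination site (annotated
  stops, uORF stops, and optional out-of-frame stop codons embedded in
  sense-codon pairs) over a uniform CDS background;
* the MPRA library draws distinct 9-mers, assigns monosome probability
  `p_stop` (default 0.5) with an in-frame stop and `p_base` (default 0.1)
  without, and emits reads multinomially at the configured depths.

What the generator does **not** emulate: codon-level dwell-time
variation, ribosome collisions and stacking, nuclease-bias length
artefacts, mRNA-abundance dispersion across transcripts, UMI/PCR
duplication structure, or any mechanistic model of ribosome sliding and
reinitiation. Passing tests therefore demonstrate correctness of the
computations and recoverability of planted effects under idealized noise,
not robustness to every artefact of real libraries.

## Numerical choices and degenerate inputs

Exact Wilcoxon enumeration switches to the normal approximation above 25
informative differences; Stouffer clips p = 1 at 1 − 10⁻¹²; BH is the
standard step-up; the pausing index and drop ratio return errors/missing
values (never silent zeros) for empty CDS, empty flanks, or missing
3'UTRs; bedGraph output merges equal-value runs and omits zeros. Peak
calling on an all-zero profile returns an empty set; `n_transcripts = 0`
is a valid simulation.

Test and verification problem sizes were chosen to make the planted
effects statistically decisive at desk scale: 200 transcripts at depth 5
for metagene geometry, 500 for pausing-index recovery (Spearman against
planted multipliers), 100 transcripts for peak specificity/sensitivity,
~600 null candidates and 60 planted uORFs for error control and power,
and 10⁴ MPRA variants at 10⁶ reads per fraction.

## Known limitations

Transcript-space only (no genome coordinates or spliced alignments); no
statistical FDR on termination peaks (the rule is a deterministic
threshold, faithful to its source); context classification is
composition-based, not motif discovery; the MPRA model ignores
variant-specific mRNA stability. These are scope decisions, not oversights.
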