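---
title: "Methods: junction-based exon inclusion analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: junction-based exon inclusion analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exonusage)
```

## The problem

Titin (*TTN*) is an extreme case for splicing analysis: 364 exons (the
first non-coding), a repeated region where nine exon blocks recur three
times, metatranscript-only ("meta-only") exons absent from the canonical
adult skeletal (N2A) and cardiac isoforms, and isoform-specific exons
(45, 46, 48). Short reads cannot phase whole isoforms across such a gene,
but reads that align across an excised intron identify individual splice
junctions unambiguously (outside the repeated region), and junction
counts aggregated over a cohort support a per-exon picture of inclusion
versus exclusion. `exonusage` implements that junction-centric analysis
as a reusable pipeline; everything operates on one gene model at a time.

## Coordinate conventions and strand handling

Internally every interval is 0-based half-open; user-facing reports are
1-based (c.-style CDS positions). A junction is stored as its intron
interval `[intron_start, intron_end)`. The gene model normalises strand
once: exon ordinals run 5'→3' in transcript orientation, and each exon's
donor (3' boundary in transcript direction) and acceptor (5' boundary)
coordinates are derived from the strand at model construction. On the
minus strand — *TTN*'s case — a junction's donor side is therefore its
intron *end*. All downstream classification logic is strand-agnostic;
the test suite exercises both orientations throughout.

## Junction extraction

Each `N` operation in a read's CIGAR yields one candidate junction; the
intron interval follows from walking the reference-consuming operations
(`M`, `D`, `N`, `=`, `X`) from the alignment position. A read supports a
junction only if the aligned (`M`/`=`/`X`) bases immediately flanking the
gap span at least `min_anchor` nucleotides on both sides. The default
`min_anchor = 8` nt matches common junction-caller defaults and
suppresses spurious 1–2 nt overhangs; it is exposed as an argument
because no single value suits all read lengths. No deduplication or
mapping-quality filtering is applied: the downstream statistic uses raw
junction read counts, and the multi-sample QC filter is the intended
noise control. Junction strand is taken from an `XS:A:` tag when present
and otherwise left `*`; classification takes strand from the gene model,
so unstranded junction files work unchanged.

## Event classification

Each junction end is compared with the canonical boundaries of its type
(donor ends against donor boundaries, acceptor ends against acceptor
boundaries), in transcript orientation:

* both ends exact, exons consecutive in the reference isoform →
  canonical;
* both ends exact, non-consecutive → exon skipping; the skipped set is
  every model exon strictly between the two ends, so meta-only exons
  count as skipped;
* an end within `max_offset` of its nearest boundary but not on it →
  alternative donor/acceptor (or both), with signed offsets, positive
  downstream in transcript direction;
* otherwise unassigned (reported, never an error).

`max_offset = 500` nt by default: alternative sites of interest sit in
the flanking exon or near intron, and a larger radius would start
assigning junctions of neighbouring structures to the wrong exon. When a
position is exactly equidistant between two boundaries the upstream
(smaller-ordinal) exon wins — an arbitrary but deterministic and
documented tie-break; with realistic exon/intron sizes and small offsets
ties essentially never occur. Events whose donor or acceptor exon
carries a repeat-block label are only *flagged* (`in_repeated_region`):
multi-mapping in a region of nine blocks repeated three times cannot be
resolved from junction evidence alone, so the package reports the flag
and leaves interpretation to the caller.

An event is `previously_reported` when its exon pair is consecutive in
any isoform definition of the model — e.g. junction 47–50 for the
skeletal N2A isoform — which is how novel junctions are separated from
known isoform structure.

## Reading-frame prediction

The frame consequence of an event is the net change in included coding
sequence,

```
delta = donor_offset − acceptor_offset − Σ coding_length(exons strictly between)
```

in transcript coordinates. For a pure skip this is minus the summed
coding length of the skipped exons; a donor extended into the intron
inserts bases; an acceptor shifted into its exon removes them; an
alternative site in a distant exon accumulates every fully-spanned
exon's coding length. The event preserves frame iff `delta %% 3 == 0`.
Events touching the non-coding first exon return `not_applicable`
rather than a guess, as do unassigned events. The formula assumes each
coding exon contributes its first `coding_length` bases (transcript
orientation) to the CDS; for models whose coding exons are fully coding
— both packaged models — this is exact.

## QC filtering

Discovery thresholds are inclusive: a junction passes with at least
`min_total_reads = 1000` pooled reads *and* detection in at least
`min_samples = 14` samples (defaults sized for a 42-sample cohort).
Cross-cohort validation is strict: at least `validation_min_reads = 11`
pooled reads in the independent cohort, encoding "more than 10".
Unvalidated junctions are preserved and reported separately, never
silently dropped. Validation matching uses coordinates only (not
strand), because discovery junctions extracted from SAM without strand
tags would otherwise never match a stranded validation file. Validation
totals are pooled across the validation cohort's samples.

## The inclusion-rate statistic

For exon *e*, `I` sums the counts of passing junctions whose donor or
acceptor lies at or within *e* (alternative-site junctions landing
inside an exon support its partial inclusion and count toward `I`), and
`E` sums the counts of passing junctions strictly spanning *e*; a
multi-exon skip contributes its full count to the `E` of every exon it
spans. The rate is `(I/2)/((I/2)+E)`. The halving reflects that an
included internal exon generates junction reads on two flanks while
each excluding read is observed once; under proportional sampling
(`I ≈ 2pd`, `E ≈ (1−p)d` at depth `d`) the statistic's expectation is
the true inclusion proportion `p`, with bias of order `p(1−p)/(2d)` from
the ratio — negligible at the depths the filter admits. Terminal exons
have one flank, so they use divisor 1; keeping the divisor at 2 there
would bias their estimate toward exclusion by a factor of up to 2. `E`
is computed per exon, not per block of adjacent exons sharing the same
skip evidence: adjacent exons may additionally be spanned by different
alternative-site events, and per-exon sums keep the statistic local.

Categories are structural, not rate cut-offs: an exon is constitutively
expressed when passing junctions touch it and none span it,
constitutively spliced out when no passing junction touches it (even if
sub-threshold inclusion evidence exists), `variable` when both kinds of
evidence pass, and `no_data` (rate `NA`, never 0 or 1) when neither
does. This reproduces the situation where an exon with a 98–99% rate is
still listed as variable while a neighbour without passing contrary
evidence is labelled constitutive. By default the usage table covers
coding exons outside repeat blocks; `include_repeats = TRUE` opts into
the biased repeated-region values. Percent reporting rounds half away
from zero. By default only QC-passing junctions enter `I` and `E`
(`apply_filter = FALSE` disables this), so the table is a function of
the same evidence set that the event tables report.

## Splice-site consensus scores

Sites are scored with a position-frequency consensus value: the raw
score is the sum (default) or log-product of the per-position
frequencies of the observed nucleotides, min–max-normalised to 0–100
against the worst/best windows attainable under the matrix — so the
per-position argmax sequence scores exactly 100 and the argmin sequence
exactly 0. The packaged donor matrix is the classic 9-mer table (3
exonic + 6 intronic positions) with the invariant GT dinucleotide; the
acceptor matrix is a 15-position consensus-derived table (pyrimidine
tract, invariant AG, first exonic base). Both invariants are asserted on
load. These matrices reproduce the *scheme*, not any specific web
service's proprietary tables, so published per-site score values should
be treated as qualitative anchors; the scorer itself is verified against
a brute-force evaluation of the formula to 1e-9. Windows containing `N`
or gaps return a first-class "unpredicted" result rather than a number.
The product variant floors zero frequencies at a 1e-4 pseudo-count so
the log is defined; the default sum variant needs no floor.

## The synthetic-data generator

The generator defines the conditions the pipeline is validated under:
42 samples, expected depth 1e4 junction-spanning reads per transcript
unit, Poisson counts (negative binomial with dispersion 0.1 available to
stress the estimator), 86 bp single-end reads for SAM emission, and
explicit seeds everywhere — no hidden global randomness. Each isoform
contributes its consecutive-exon junctions with mean `depth ×
proportion`; per-exon truth is the summed proportion of isoforms
containing the exon. Emitted SAM reads encode each junction as
`<a>M<gap>N<b>M` with anchors drawn in `[min_anchor, read_length −
min_anchor]`, so extraction reproduces the count matrix exactly by
construction. What the generator does *not* emulate: sequencing error,
base qualities, coverage non-uniformity along transcripts,
multi-mapping (so repeated-region ambiguity is represented only by the
classification flag), intron retention, and library-size variation
between samples. Passing recovery tests therefore demonstrate
correctness of the estimator and pipeline plumbing under the stated
sampling model, not robustness to alignment artefacts.

The packaged 364-exon *TTN*-like model is synthetic: it reproduces the
published organisation (non-coding exon 1, meta-only exons 148, 150,
159–171, 213–217, repeat-block labels cycled across exons 172–205,
isoform-specific exons 45/46/48, and metatranscript/N2A/Novex-3 isoform
definitions) with deterministic synthetic coordinates, all coding
lengths multiples of 3. It supports structural tests — skip patterns,
meta-only flags, frame calls — not genomic coordinate lookups.

## Problem sizes and numerical choices

The validation suite runs at sizes chosen to give tight Monte-Carlo
error while staying desk-scale: estimator unbiasedness at depths 1e2
and 1e4 with 200 replicates (tolerance 3 standard errors of the mean);
full-pipeline recovery on 42-sample cohorts at depth 1e4, 200 replicates
per inclusion level in the tests and 50 in the acceptance script;
extraction equivalence on 1000 emitted reads; classification
equivalence against exhaustive enumeration on 700–800 junction-end
pairs per strand around a 9–10-exon model. Rates are computed in double
precision (exact for these integer counts); integer percentages round
half away from zero; undefined rates propagate as `NA` throughout.

## Known limitations

* One gene model at a time; no genome-wide mode.
* No isoform-level quantification: junctions are analysed marginally,
  and co-occurrence of events on one molecule is out of reach of short
  reads by design.
* Repeated-region events are flagged, not resolved.
* The frame prediction is sequence-free: it reasons over coding lengths
  and offsets, not over stop codons an insertion might introduce.
* Consensus matrices are scheme-faithful defaults, not a reproduction
  of any specific scoring service.
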