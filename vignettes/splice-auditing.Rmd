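---
title: "Auditing constructs for cryptic splice sites: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing constructs for cryptic splice sites: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Mammalian splice signals are short and degenerate: a 5' (donor) site is
essentially an obligate GT dinucleotide in a weakly constrained 9-base
context, a 3' (acceptor) site an AG preceded by a pyrimidine-rich
tract. Because the information content is low, sequences never meant to
be spliced — restriction sites, epitope-tag encodings, Gly-Ser linkers,
codon-optimized ORFs, bacterial backbone elements — regularly contain
windows that look like authentic splice sites to the spliceosome. When
such a window pairs with a compatible partner site in a transcribed
construct, part of the mRNA is silently excised.

spliceaudit implements the computational side of a defensive workflow:
score windows, audit whole constructs, profile the synonymous codon
space of peptide elements, design encodings without predicted sites,
and quantify actual splicing from RNA-seq alignments against the full
plasmid.

## The scoring model and its assumptions

A window is scored as the log2 odds of observing it under a splice-site
model versus a background model, in bits. The scorer follows the
MaxEntScan decomposition exactly:

* **Donor (9-mer; 3 exonic | GT | 4 intronic).** Score =
  log2(consensus odds of the bases at positions 4-5) +
  log2(model odds of the remaining 7 positions, stored as one 4^7
  table).
* **Acceptor (23-mer; 18 intronic | AG | 3 exonic).** Score =
  log2(consensus odds at positions 19-20) plus the log2 of a
  product/quotient over nine overlapping subsequence tables of the
  remaining 21 positions (segments 1-7, 8-14, 15-21, 5-11, 12-18 in
  the numerator; 5-7, 8-11, 12-14, 15-18 in the denominator — each
  position enters the product net exactly once).

Windows lacking GT/AG at the obligate positions are scoreable (the
consensus-odds term penalizes them by roughly 12 bits), but every
scanner in the package filters to canonical windows by default, because
that is how putative sites are defined operationally.

The conventional decision threshold is `tau = 0` bits — the point where
a window is more likely under the splice-site model than under the
background. All "splicing-prone" definitions in the package default to
this threshold; it is a parameter everywhere it appears.

### The packaged tables are synthetic, and what that means

This package does not ship the published MaxEntScan parameter tables.
Instead `inst/extdata/splice_model_synthetic/` holds per-position base
frequencies of human donor and acceptor sites compiled from widely
reproduced literature consensus matrices, plus a genomic background
(A/T 0.27, C/G 0.23). At load time these become a first-order
maximum-entropy model — the maximum-entropy distribution constrained
only by single-position marginals, i.e. a position weight matrix in
log-odds form — expressed inside the reference scorer's container (the
7-mer donor table and the nine acceptor tables are filled with
independent-position products).

Consequences to keep in mind:

* Scores are on the familiar bit scale, and broad statements transfer:
  consensus-like windows score strongly positive, the vast majority of
  random windows score negative, GT/AG-free sequences cannot host
  sites at all.
* Quantities that depend on *positional correlations* do not transfer.
  The published second-order tables reward motif families such as
  GT(A/G)AG beyond what their single-position frequencies imply;
  analyses that hinge on those correlations (e.g. how often tag codon
  spaces reach the 0-bit threshold) come out systematically lower
  under the first-order model. The acceptance suite keeps the
  published-value comparisons at full strength, so the affected checks
  fail visibly rather than silently.
* `load_splice_model(path)` accepts a directory holding the native
  MaxEntScan `me2x5`/`me2x3acc1..9` files; with those, scoring is
  bit-compatible with the reference scripts and the same comparisons
  pass. The loader validates table sizes and positivity and records an
  md5 checksum over the table files; every report carries that
  checksum, so results are always attributable to a specific model.

## Window geometry and coordinates

All modules share one geometry definition (`splice_geometry()`): donor
9/3/GT, acceptor 23/18/AG/3. Coordinates in every report are 0-based,
half-open, on the forward strand of the stored sequence, matching BED
conventions; minus-strand windows are reported with the forward
interval they occupy plus `strand = "-"`. Each window also carries a
`boundary` — the forward-strand coordinate of the exon|intron (donor)
or intron|exon (acceptor) junction — which is the coordinate to compare
against RNA-seq junction calls.

Circular sequences (plasmids) are scanned by virtual extension: a
sequence of length L is scanned as `s + s[0:W-1]` for window width W,
with start positions reported modulo L. An origin-spanning window thus
has `start < L` but `end = start + W` possibly exceeding L;
`end - start` always equals the window width. IUPAC codes other than N
are rejected at input; windows containing N are skipped and tallied
(`n_skipped`) rather than expanded, keeping scan time linear — explicit
ambiguity questions go through `summarize_ambiguous()`, which expands
exhaustively under a cap (default 65,536 expansions).

Both strands are scanned by default. Whether a given construct's
transcribed strand is the only relevant one depends on context
(antisense transcription from backbone promoters is real), so the
default errs on the side of reporting; the strand set is recorded in
the report metadata.

## Codon-space profiling

A peptide of length L has `prod(degeneracy)` synonymous encodings
(exact in double precision up to 2^53). Spaces up to 10^6 encodings
(configurable cap) can be enumerated exhaustively in lexicographic
codon order; larger spaces are sampled by drawing each residue's codon
independently and **uniformly**. Uniform (rather than codon-usage
weighted) draws answer the design question "what fraction of the
encoding space is risky", not "what would a typical optimizer emit";
usage-weighted sampling can be layered on by passing a custom codon
table. Duplicates are retained so fractions remain unbiased Monte-Carlo
estimates under uniform draws. The ensemble default is n = 10^6 draws,
the conventional size for this analysis; at that size a fraction's
binomial standard error is below 0.05 percentage points.

Per encoding, the profile records the maximum donor and maximum
acceptor score over canonical windows, and calls the encoding prone on
a side when the maximum reaches `tau`. Window placement is governed by
`flank_policy`:

* `internal_only` (default): windows fully inside the encoding. Tags
  are profiled as standalone units — the choice made for the headline
  tag analyses, since tag context varies across constructs.
* `expand_N`: additionally scores windows whose obligate GT/AG lies
  inside the encoding but whose flanks extend into unknown context,
  taking the worst case over that context. Under the first-order model
  the worst case factorizes per position (each N contributes its
  maximum base odds), so this is exact; under loaded second-order
  tables it is not available and the call errors rather than
  approximating. This is the recommended policy for building blocks
  destined for arbitrary contexts.
* `fixed_flanks`: scores the encoding in a user-supplied left/right
  context (the flanks must cover the geometry-required 18/3 intronic
  and 3/4 exonic bases).

Encodings too short to host a window of a kind (e.g. an 18-nt 6xHis
encoding versus the 23-mer acceptor window) get `NA` for that kind and
count as not prone.

`linker_prone_curve()` applies the same machinery to repeated linker
units, reporting the prone-5' fraction per repeat count; each length
uses a sub-seed derived from the user seed, so curves are reproducible
end to end.

## Splice-safe design

`design_safe_encoding()` searches the synonymous space for an encoding
with no canonical window at or above `tau` (plus optional forbidden
motifs and GC bounds). The search is seeded stochastic hill-climbing
with restarts rather than exact dynamic programming: an acceptor
window spans up to 9 codons, so an exact DP would carry a large context
state, while in practice short peptides are easy and the independent
verifier makes soundness independent of the search path. Each move
replaces one codon among the residues overlapped by currently
offending windows, and is accepted if it improves the lexicographic
objective (constraint violations, number of windows at or above `tau`,
maximum window score); ties are broken by first encounter, keeping the
trajectory deterministic for a given seed. When a restart stalls, a
fresh random encoding is drawn (default 50 restarts, 200 moves each).

On success the result is re-verified by an independent route
(`verify_encoding()`, which re-finds windows through the scanner and
re-translates the encoding); on failure the search signals a
`spliceaudit_infeasible` error carrying the best encoding found and its
maximum score — infeasibility is reported, never approximated. For
some peptides a splice-free encoding genuinely need not exist at low
`tau`; the explicit failure mode is the honest answer there.

Hazard motifs (KpnI, NheI, polyadenylation hexamers) are available as
optional forbidden motifs but are off by default: they matter only when
the element will sit in transcribed, clonable context, which is the
caller's call.

## Junction quantification

The module consumes spliced alignments (SAM with headers) produced by
any spliced aligner; alignment itself is out of scope. SAM and CIGAR
handling is delegated to Rsamtools/GenomicAlignments (M/=/X consume
reference and read, D consumes reference within a block, N splits
blocks, I/S consume read only); unmapped, secondary, and supplementary
records are excluded.

A junction is keyed by its exact intron coordinates (tolerance 0; on a
short, unambiguous plasmid reference merging near-duplicates would only
obscure distinct cryptic sites). A read supports a junction when its N
gap matches exactly and both flanking blocks align at least
`min_anchor` bases (default 6 — short enough to keep power at modest
read length, long enough that random 6-mer matches are rare). The
per-junction spliced fraction is

    spliced_fraction = J / (J + I)

with J the junction-supporting reads and I the reads aligning at least
`min_anchor` bases strictly inside the intron without carrying the
junction. "Within the intron" could alternatively be operationalized as
coverage-averaged intron depth; the read-count form was chosen for
symmetry with the junction-anchor rule, and `min_anchor` is surfaced so
the denominator stringency is explicit in every report. A junction with
J = 0 but intronic coverage reports 0; with no informative reads at
all it reports a missing value rather than crashing. Duplicate reads
are not collapsed — the statistic is a raw read proportion.

## The read simulator

`make_reporter()` + `simulate_reads()` emulate the split-reporter
design used to test elements for splicing potential: a reference with
one intron (canonical GT...AG termini, optionally carrying an inserted
test element) spliced out in a known fraction psi of transcripts. Each
read independently derives from the spliced transcript with probability
psi; reads are error-free by default (an optional uniform substitution
rate exists for stress tests), single-end, with exact CIGARs (M-N-M
across the junction) and fixed quality, emitted as FASTQ plus matching
SAM so no external aligner enters the test loop.

With `span_junction = TRUE` the read start is drawn so the donor
boundary falls at a uniform offset inside the read with at least
`min_anchor` bases on both sides. Because the number of eligible start
positions is identical for spliced and unspliced transcripts, every
read is informative and contributes to exactly one of J or I, making
the estimator an unbiased binomial proportion of psi — this is the
configuration used for parameter-recovery checks. With uniform starts
(the default) the J and I windows have different sizes, so the raw
statistic is a biased estimate of psi; that regime emulates whole-
transcript coverage rather than a calibrated estimator.

What the simulator does not emulate: sequencing errors by default,
paired ends and fragment-length distributions, expression mixtures of
multiple isoforms, alignment ambiguity, and library-prep artifacts.
Passing the round-trip tests therefore validates the counting and the
statistic, not robustness to aligner noise.

## Numerical and engineering choices

* All scores are computed and compared in double precision; reports
  conventionally display 2 decimals (the reference scorers print 2),
  but nothing is rounded internally.
* The synthetic tables are validated at load (layout, positivity,
  column sums within 2%); native-format tables are validated by length
  and positivity. Corruption errors name the offending file.
* Exhaustive enumeration caps: 65,536 ambiguity expansions, 10^6
  encodings; both configurable, both chosen so the default paths stay
  interactive.
* Seeds are mandatory for every stochastic operation (sampling, search,
  simulation); there is no hidden entropy, and derived sub-seeds are
  simple offsets of the user seed.
* Test problem sizes: oracle cross-checks use hundreds of random
  windows per kind; codon-space convergence checks use spaces small
  enough to enumerate (48-256 encodings) against samples of a few
  thousand; parameter recovery uses 5,000 reads per psi level. These
  sizes give comfortable statistical margins (3 binomial SEs) while
  keeping the suite fast.

## Known limitations

* The synthetic first-order model understates correlated splice motifs;
  threshold-crossing fractions for GT/AG-rich codon spaces are
  conservative relative to the published second-order tables (the
  acceptance suite quantifies this visibly). Supply genuine tables for
  publication-grade scores.
* No branch-point model and no splicing-efficiency prediction: a score
  is a motif-resemblance measure, not an in vivo usage rate, and a
  high-scoring site can be silent in a given context.
* Promoter and polyadenylation auditing is limited to literal motif
  flagging; no promoter-strength model is included.
* The GenBank reader is deliberately minimal (LOCUS name/topology and
  ORIGIN sequence only); annotation features are ignored.
* Proteome-scale motif scans are out of scope; they require external
  annotation resources.
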