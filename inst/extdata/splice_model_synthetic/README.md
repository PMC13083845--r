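# Synthetic splice model (first-order maximum entropy)

These tables are a **synthetic** splice-site model, not the published
MaxEntScan parameter tables. They give, per window position, the base
frequencies of human 5' (donor) and 3' (acceptor) splice sites compiled
from widely reproduced literature consensus matrices (Shapiro/Senapathy
style position-frequency tabulations of human GT-AG introns), plus a
genomic background composition. At load time `load_splice_model()` turns
them into the maximum-entropy model with first-order marginal
constraints (a position weight matrix in log2-odds form) expressed in
the reference scorer's container: a 7-mer odds table for the donor model
and the nine-subsequence product/quotient tables for the acceptor model.

Scores are therefore on the familiar MaxEnt bit scale (log2 odds of
splice site versus background), and the operational `>= 0` threshold
applies, but individual scores will differ from the published
second-order MaxEntScan tables because positional correlations are not
encoded here.

If you have the genuine MaxEntScan distribution, point
`load_splice_model()` at a directory containing its native `me2x5` and
`me2x3acc1` ... `me2x3acc9` files to score with the published model
bit-exactly.

## Schema

- `background.tsv`: columns `base`, `freq`.
- `donor_frequencies.tsv`: columns `pos` (1-9), `role`
  (exon/consensus/intron), `A`, `C`, `G`, `T`. Positions 4-5 are the
  obligate GT dinucleotide and play the role of the reference scorer's
  consensus-odds term.
- `acceptor_frequencies.tsv`: same columns for positions 1-23;
  positions 19-20 are the obligate AG.
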