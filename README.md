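# spliceaudit

Cryptic splice sites hide in the most routine parts of expression
constructs: multiple cloning sites (the KpnI site GGTACC forms a 5'
splice motif in most contexts), epitope-tag encodings (the common V5
nucleotide sequence opens with a strong GGTAAG donor), Gly-Ser linkers
(GGN/AGT codons are GT-rich), codon-optimized ORFs, and plasmid
backbones. When the host spliceosome recognizes them, the mature mRNA
no longer matches the designed sequence — tags silently drop out,
frames shift, and phenotypes get attributed to the wrong molecule.

spliceaudit is an R toolkit for the defensive workflow around this
problem, aimed at anyone designing or validating mammalian expression
constructs:

1. **Score** candidate 5' (donor) and 3' (acceptor) splice sites with a
   maximum-entropy log-odds model (MaxEnt-style bits; `>= 0` is the
   conventional threshold for a putative site).
2. **Audit** whole plasmids — linear or circular, both strands — for
   high-scoring windows and hazard motifs before synthesis.
3. **Profile** the synonymous codon space of tags and linkers: how many
   of the possible encodings of a peptide are splicing-prone?
4. **Design** splice-safe encodings by silent mutation, with
   independent verification.
5. **Quantify** aberrant splicing from spliced RNA-seq alignments
   mapped to the full plasmid (junction counts and per-junction spliced
   fractions), with a paired read simulator for end-to-end validation.

## The scoring model

A donor window is a 9-mer (3 exonic bases | GT | 4 intronic bases), an
acceptor window a 23-mer (18 intronic bases | AG | 3 exonic bases). A
window's score is the log2 odds of the window under a splice-site model
versus a genomic background:

    score = log2[ P_consensus(obligate dinucleotide) / P_bg
                  x P_model(remaining positions) / P_bg ]

computed with the classic MaxEntScan decomposition (consensus-position
odds times a 7-mer table for donors; the nine-overlapping-subsequence
product/quotient for acceptors).

**Model provenance.** The package ships a clearly labeled *synthetic*
model (`inst/extdata/splice_model_synthetic/`): a first-order
maximum-entropy model built from literature consensus base frequencies
of human splice sites. Scores are on the familiar bit scale and the
`>= 0` convention applies, but individual values differ from the
published second-order MaxEntScan tables, which encode positional
correlations that a first-order model cannot (see the fixture README
and the methods vignette). If you have the genuine MaxEntScan
distribution, point `load_splice_model()` at a directory containing its
native `me2x5` / `me2x3acc1..9` files and scoring is bit-compatible
with the reference `score5`/`score3` scripts.

## Worked example

```r
library(spliceaudit)
m <- load_splice_model()

# 1. audit a toy MCS fragment
audit_sequence(nuc_sequence("mcs", "AAGGTACCTTAATAAACCGCTAGCGG"), m)
#> <audit_report> mcs (topology linear, tau=0)
#>   2 splice window(s) >= tau, 5 motif hit(s), 0 window(s) skipped for N
#>   seq  kind start end strand boundary window_seq   score
#> 1 mcs donor     0   9      +        3  AAGGTACCT 5.41963
#> 2 mcs donor     1  10      -        7  AAGGTACCT 5.41963
```

The KpnI site (GGTACC at 0-based positions 2-8, also reported among the
motif hits together with a polyadenylation hexamer and NheI) hosts a
donor window scoring 5.4 bits on both strands — a putative 5' splice
site sitting inside an ordinary cloning scar.

```r
# 2. how risky is the V5 tag's codon space?
risk_profile(peptide("V5", "GKPIPNPLLGLDST"), m, mode = "sampled",
             n = 1e5, seed = 1)
#> <risk_profile> V5 (GKPIPNPLLGLDST), 100000 encodings (sampled, tau=0, internal_only)
#>   prone 5': 0.2010  prone 3': 0.4806  prone both: 0.0940
```

Under the synthetic model, 20% of uniformly drawn V5 encodings contain
a putative internal donor site, 48% an acceptor site, and 9.4% both.
(With the published second-order tables these fractions are
substantially higher; the first-order model understates correlated
motifs such as GTAAG.)

```r
# 3. design a splice-free V5 encoding and verify it independently
design_safe_encoding(peptide("V5", "GKPIPNPLLGLDST"), m, seed = 3)
#> <safe_encoding> V5 (GKPIPNPLLGLDST)
#>   GGAAAGCCTATTCCTAATCCTCTGCTTGGCCTCGATTCGACT
#>   max donor -Inf, max acceptor -Inf (tau=0, internal_only; 2 iterations, 1 restarts)

# 4. simulate a split reporter spliced in 18% of transcripts and
#    quantify it back from the SAM
rep <- make_reporter(seed = 7)
sim <- simulate_reads(rep$reference, rep$intron, psi = 0.18,
                      n_reads = 5000, read_length = 100, seed = 11,
                      span_junction = TRUE)
quantify_splicing(read_alignments(sim$sam))
#> <splice_quant> 5000 reads, 1 junction(s), min_anchor=6
#>      rname donor_end acceptor_start read_count spliced_fraction
#> 1 reporter       300            450        869           0.1738
```

The junction is recovered at exactly the simulated intron boundaries
and the spliced fraction (0.174) matches the true value 0.18 within
binomial sampling error.

## Command line

A thin wrapper is installed at `inst/cli/spliceaudit`:

```sh
spliceaudit scan --in plasmid.gb --format genbank --circular --tau 0
spliceaudit ambiguous --pattern NNGGTACCN --kind donor --tau 0
spliceaudit tag-risk --preset V5 --n 1000000 --seed 1
spliceaudit optimize --preset V5 --seed 1
spliceaudit simulate --psi 0.2 --seed 4 --span-junction --out-dir sim/
spliceaudit junctions --sam sim/sim.sam
```

All reports are TSV with `#` metadata lines carrying the tool version,
parameters, seed, and model checksum.

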