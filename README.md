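# atropomine

Machine-learning genome mining for atropopeptide biosynthetic gene
clusters (BGCs).

Atropopeptides are ribosomally synthesized and posttranslationally
modified peptides (RiPPs) whose short precursor genes routinely escape
annotation: the mature natural product is a 4–8 residue core peptide
carrying oxidative crosslinks (biaryl, C–N and aryl-ether bridges)
installed by a single family-defining cytochrome P450. `atropomine`
inverts the usual mining logic — instead of looking for the (unfindable)
precursor genes, it recognises the *tailoring enzyme*, then searches the
genomic neighbourhood of each recognised P450 for the precursor, and
finally predicts the high-resolution masses of the modified core
peptides so that candidate BGCs can be linked to metabolites in culture
extracts. It is written for natural-product genome miners working with
bacterial (primarily actinobacterial) genomes.

## Method

**1. P450 classification.** Every candidate P450 is globally aligned
(BLOSUM62, gap open 10, extend 1) to an annotated reference P450 and
fragmented at reference positions 92/192/275/395 into five functional
regions (N-terminus, substrate-binding regions 1 and 2, core region,
C-terminus). Sequences are recoded in a six-group physico-chemical
reduced alphabet, and each region is represented by counts of
overlapping 4-mers; a 4-mer becomes a feature axis if it occurs in at
least half of the positive training sequences in that region. Training
sets are dereplicated by greedy clustering at 95% identity (word size 5
prefilter), classes are balanced by random oversampling, and a random
forest (100 trees, max depth 10 in the first round, 14 after refinement,
min 1 sample per leaf) is trained on a stratified 60:40 split. The score
of a query is the fraction of trees voting positive; a query is called
positive iff score > 0.15 (strict).

**2. Precursor search.** For each positive P450 gene, the ±3 kb
neighbourhood is scanned in all six reading frames for ORFs of 10–40
codons (starts ATG/GTG/TTG, translation table 11). Candidates must
either contain two consecutive aromatic residues (F/W/Y) in the
C-terminal six-residue core (first-round rule) or one of the leader
motifs KSLK/RSLK/ESLK/KSRK/KPLK/PSLK anywhere in the precursor
(second-round rule). ORFs overlapping annotated CDS are discarded unless
the CDS is itself labelled a tryptorubin-family RiPP precursor; nested
ORFs sharing a stop codon collapse to the shortest start (alternatives
recorded). Results are emitted as annotated GenBank regions plus a TSV.

**3. Mass screening.** For a predicted core peptide the package
enumerates N-terminal truncations × crosslink counts; each crosslink
subtracts 2 H from the elemental formula and the protonated monoisotopic
m/z is computed with the electron-mass correction,

&nbsp;&nbsp;&nbsp;&nbsp;m/z [M+H]⁺ = Σᵢ nᵢ·Mᵢ + M(H) + m(p) − m(e),

reported to four decimals, with signed ppm errors against observed
masses: ppm = (obs − calcd)/calcd × 10⁶.

A seeded fixture module generates protein families with planted
segment-localised 4-mer signatures and GenBank neighbourhoods with an
embedded P450, an unannotated truth precursor and rule-violating decoys,
so the whole pipeline is testable with known ground truth.

## Worked example

```r
library(atropomine)

# a synthetic neighbourhood with a planted precursor (truth known)
g  <- generate_neighborhood(neighborhood_spec(seed = 5))
nb <- extract_neighborhood(g$record, g$anchor_protein_id)
find_precursors(nb, rule_mode = "both")
#>   start  end strand               leader   core matched_motif
#> 1  5243 5324      + MRNQGDYFCLPGRTDVRSLK NSWWHY          RSLK
```

The search recovered one precursor ORF at record coordinates
5243–5324 (0-based, stop codon included): a 20-residue leader carrying
the RSLK motif followed by the 6-residue core `NSWWHY`, whose adjacent
W–W pair satisfies the aromatic-core rule. All five planted decoys
(too short, too long, CDS-overlapping, motif-less, non-aromatic core)
were rejected.

```r
series <- candidate_series("SWYQWL", max_crosslinks = 2,
                           allow_n_truncations = 1)
#>   sequence truncation n_crosslinks     formula       mz
#> 1    WYQWL          1            2  C42H46N8O8 791.3511
#> 2    WYQWL          1            1  C42H48N8O8 793.3668
#> 3    WYQWL          1            0  C42H50N8O8 795.3824
#> 4   SWYQWL          0            2 C45H51N9O10 878.3832
#> 5   SWYQWL          0            1 C45H53N9O10 880.3988
#> 6   SWYQWL          0            0 C45H55N9O10 882.4145

round(ppm_error(793.3655, 793.3668), 2)
#> [1] -1.64
```

For the hexapeptide core `SWYQWL`, the pentapeptide variant `WYQWL`
(N-terminal Ser removed by host peptidases) with two crosslinks is
predicted at m/z 791.3511 [M+H]⁺ and with one crosslink at 793.3668;
an ion observed at 793.3655 matches the one-crosslink candidate within
−1.64 ppm.

A thin CLI wraps the same functions
(`system.file("cli/atropomine.R", package = "atropomine")`), with
subcommands `train`, `classify`, `mine`, `corefind`, `masses` and
`simulate`.

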