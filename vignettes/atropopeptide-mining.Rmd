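---
title: "Mining atropopeptide BGCs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining atropopeptide BGCs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`atropomine` implements a two-stage strategy for finding atropopeptide
biosynthetic gene clusters: recognise the family-defining tailoring
cytochrome P450 with a supervised classifier, then search its genomic
neighbourhood for the short, usually unannotated precursor-peptide gene,
and finally predict the masses of modified core peptides for screening
culture extracts. This vignette explains the model and its assumptions,
the parameters that matter, what the synthetic fixtures do and do not
emulate, and the numerical conventions the package commits to.

```{r setup, eval = FALSE}
library(atropomine)
```

## The classification model

### Reference-anchored segmentation

Bacterial P450s share a conserved fold in which substrate specificity is
concentrated in identifiable regions. Rather than learning on whole
sequences, every protein is fragmented into five functional regions —
N-terminus, two substrate-binding regions, the core region and the
C-terminus — by aligning it to one annotated reference P450 and cutting
at reference residues 92, 192, 275 and 395. The reference and its cut
positions are user inputs (`reference_scheme()`); the defaults encode
the standard functional-region annotation for the reference the method
was developed with.

Each query is aligned to the reference *pairwise* (global
Needleman–Wunsch, BLOSUM62, gap open 10, gap extension 1) rather than
through one multiple alignment of the whole input. Pairwise anchoring
gives the same boundary-mapping semantics, is independent of the
composition of the query set, and makes segmentation testable in
isolation. When a reference cut lands inside a query deletion, the
boundary anchors to the nearest aligned query position to the *left*;
this keeps the five segments contiguous, so their concatenation always
reproduces the query exactly (an invariant the test suite enforces).
Left- versus right-anchoring is a genuinely open choice; left-anchoring
was selected and is applied uniformly.

### Reduced alphabet

To limit overfitting to exact residue identity, sequences are recoded
into a six-group physico-chemical alphabet before feature extraction:
aliphatic {A,V,L,I,M}, aromatic {F,W,Y}, positively charged {K,R,H},
negatively charged {D,E}, polar {S,T,N,Q,C}, and conformationally
special {G,P}. The published grouping for this method lives in
supplementary material that is not reproduced here, so the mapping is a
required, overridable argument (`alphabet =`) everywhere it is used: if
the original grouping differs it can be dropped in verbatim without
touching code. The wildcard `X` maps to its own symbol which is excluded
from every feature k-mer, so ambiguous residues can never contribute
counts.

### k-mer features and the half rule

For each of the five regions, every overlapping 4-mer (in the reduced
alphabet) that occurs in at least `ceiling(0.5 * n_positives)` of the
positive training sequences' corresponding segments becomes one feature
axis; a protein is vectorised as the count of each retained 4-mer in
each region. Counting is overlapping-substring counting, verified
against a naive sliding-window oracle. Features are ordered
lexicographically within regions for deterministic serialisation
(`write_feature_space()`).

### Forest, score and threshold

Classes are balanced by random oversampling (minority resampled with
replacement up to the majority count, seeded, bit-for-bit reproducible),
then split 60:40 into training and validation parts. The split is
stratified by class — stratification is not strictly part of the
original protocol but avoids degenerate validation sets at small n. A
random forest is trained with 100 trees (the tree count is not specified
by the protocol; 100 is the conventional library default and gives
1/100 score granularity, ample against a 0.15 threshold), maximum depth
10 (14 in the refinement round) and minimum 1 sample per leaf. The
protocol's leaf parameter is stated as a *maximum* of one sample per
leaf, which would forbid training; it is interpreted as the standard
minimum-samples-per-leaf tunable.

The score of a query is the fraction of trees voting for the positive
class — the only score definition compatible with a fixed 0.15 cut on a
vote-based forest — and a query is positive iff its score is *strictly*
greater than 0.15. Changing the threshold never changes scores, and the
positive set shrinks monotonically as the threshold rises.

Evaluation reports the confusion counts on the held-out 40%, the
positive-class F1, recall, specificity and balanced accuracy
(recall + specificity)/2.

### Refinement round

Mining feeds back: newly discovered positives are merged into the
positive set, dereplicated against it, and the feature space and forest
are rebuilt with depth 14 (`iterate_training()`). With no new sequences
the rebuilt feature space is identical to the first round's, a property
the tests pin down.

### Dereplication

Training sets are reduced with a greedy longest-first incremental
clustering: a sequence joins the first representative it matches at
≥ 95% identity, where identity is alignment matches divided by the
length of the shorter sequence (the convention of the external
clustering tool the protocol used, reimplemented here so the package has
no binary dependencies). The word size of 5 acts purely as a
shared-k-mer prefilter on candidate pairs; membership is always decided
by alignment identity. Classification sets additionally pass a
300–450 aa length filter before clustering. Dereplication is idempotent
and every input stays within the threshold of some representative —
both checked against an all-pairs oracle.

## The precursor search

For each positive P450 gene the neighbourhood spanning 3 kb on each
side of the gene's *boundaries* (not its midpoint; truncated at record
edges) is scanned in all six frames for ORFs of 10–40 codons. Start
codons are ATG/GTG/TTG (the common bacterial set; configurable);
translation uses table 11 with the initiator translated literally
(GTG→V, TTG→L) — the rules below only inspect internal and C-terminal
residues, so forcing Met would change nothing except reported leader
sequences, and a flag exists to force it.

Candidates then pass through, in any order (the filters are pure and
commute):

* **Aromatic-core rule** (first mining round): the C-terminal six
  residues must contain an adjacent pair from {F, W, Y}. Histidine is
  excluded from the aromatic set: characterised family cores anchor on
  W/Y/F, and His-dependent chemistry belongs to a related but distinct
  family. The rule always inspects the last six residues even though
  longer cores exist; the motif rule, which does not use the six-residue
  window, is the instrument that found them.
* **Leader-motif rule** (second round): the precursor must contain one
  of KSLK, RSLK, ESLK, KSRK, KPLK, PSLK; the leftmost occurrence is
  reported. The typical motif position (leader residues 17–20) is
  informational and deliberately not enforced.
* **CDS-overlap filter**: any ORF sharing ≥ 1 nt with an annotated CDS
  on either strand is discarded, unless the CDS label contains
  "tryptorubin family RiPP precursor" (case-insensitive). Strandedness
  of the overlap is not considered — an unstated detail in the protocol;
  any-overlap is the conservative reading.
* **Nested-ORF deduplication**: candidates sharing a strand and stop
  codon encode the same core with alternative starts; the shortest
  rule-passing form is kept and the discarded start coordinates are
  recorded, because the true start cannot be decided from sequence
  alone when several start codons are present.

Coordinates are 0-based half-open internally and 1-based inclusive in
GenBank output; regions are written re-based to the window start with
carried-over annotations and one CDS feature per precursor (translation,
core, motif, rule mode, alternative starts). A minimal GenBank
flat-file reader/writer is part of the package because no installed R
package handles feature-table round-trips; it supports simple and
`complement()` locations, multi-line qualifiers and multi-record files.

`gc_content()` (ambiguity-excluding, strand-invariant) and `gc_delta()`
support comparing a P450 gene's GC content with its genome mean, a
useful secondary signal for horizontally acquired clusters.

## Mass screening

The mature natural product is a crosslinked, often N-terminally trimmed
core peptide. `candidate_series()` enumerates truncations × crosslink
counts; each candidate carries an integer elemental formula (residue
compositions + H₂O) and the protonated monoisotopic m/z. Conventions:

* Each oxidative crosslink subtracts exactly 2 H, regardless of bond
  type (C–C, C–N, C–O): all three chemistries are oxidative couplings
  with the same mass consequence. Per-modification deltas are
  configurable (`delta_h`) for future chemistry.
* The electron-mass correction *is* applied to cations: the [M+H]⁺ mass
  is the neutral monoisotopic mass plus one hydrogen atom minus one
  electron (equivalently, plus one bare proton). Published
  "calcd" values for this family follow the corrected convention in the
  main text (while some physical-data listings use the uncorrected one,
  0.0005 higher); the package follows the corrected convention and
  exposes `electron_correction = FALSE` for comparison.
* Output precision is four decimals, ppm errors are signed
  (obs − calcd)/calcd × 10⁶.

## Synthetic fixtures: what they emulate, and what they do not

The generators exist so that every pipeline stage can be tested against
known truth without large external downloads.

`generate_family()` emulates a target P450 family against a background
family: positives are point-mutated copies of a random 430 aa backbone
(within the 300–450 aa band of bacterial P450s) carrying reduced-alphabet
4-mer signatures planted at fixed positions in chosen functional
regions; negatives are mutated copies of an unrelated backbone of the
same length, scrubbed of the signature k-mers in the corresponding
regions. Two deliberate choices:

* The default mutation rate is 0.05 per site, placing typical pairwise
  identities near 0.90 — *below* the 0.95 dereplication threshold.
  A dereplicated training set by construction contains no pair above
  the threshold, and fixtures that feed the full pipeline must share
  that property or the dereplication stage collapses them.
* Signatures are planted after mutation, so every positive carries every
  signature; presence is re-verified at generation time. Negatives are
  re-scrubbed after mutation for the same reason.

`generate_neighborhood()` emulates a nucleotide record (default 9 kb,
60% GC — actinobacteria-like) embedding an annotated anchor P450 CDS, an
*unannotated* truth precursor (leader with a planted family motif at
residues 17–20, six-residue core with a planted adjacent aromatic pair)
and a decoy panel in which each decoy violates exactly one rule of the
conjunction mode: 9 aa (too short), 41 aa (too long), one overlapping
the anchor CDS, one without any leader motif, one without an aromatic
core pair. Reverse translation uses a fixed codon per residue (first in
lexical order) for byte-determinism; planted ORFs avoid internal Met
because, with those fixed codons, ATG is the only in-frame start codon
a residue can introduce, and an internal start sharing the planted stop
would displace the truth under the shortest-start deduplication rule.
After assembly the generator *sanitises* the random background: any ORF
that would pass both precursor rules but is not the planted truth is
destroyed by point mutations strictly outside every planted element.
This step is what makes "the search recovers exactly the truth"
well-defined on random backgrounds, and it is the neighbourhood
analogue of the family generator's re-check-and-replant step.

What the fixtures do **not** emulate: real P450 phylogeny and
inter-family homology gradients, genuine leader/core sequence biases
beyond the planted motif and aromatic pair, codon usage, overlapping
gene architecture, or annotation noise. Passing the fixture-based tests
therefore demonstrates that the machinery is correct (rules, coordinate
arithmetic, learning of segment-localised signals), not that the shipped
defaults reach any particular accuracy on real genomes; on real data the
classifier's performance is governed by the curated training sets the
user supplies.

## Numerical choices and degenerate inputs

* Alignment tie-breaks follow the deterministic traceback of the
  underlying aligner; identical inputs give identical segmentations.
* Queries shorter than 50 aa are rejected as unalignable; empty
  segments are legal (a query may lack residues in a region) and
  vectorise to zero counts, as do segments shorter than k.
* Sequences are uppercased on ingestion; comparison is
  case-insensitive.
* Windows shorter than 36 nt yield an empty ORF scan (not an error);
  ORF enumeration reports every start codon with its first in-frame
  stop, before deduplication.
* Formula subtraction that would produce a negative atom count is an
  error (crosslink underflow is impossible on real peptides).
* Oversampling, splitting, forest growth and both generators are
  seeded; identical seeds give byte-identical outputs, a property the
  tests assert.

## Problem sizes used by the test suite

The suite exercises the classifier at 40/40 (five seeds) and 10–16
sequences for unit checks, the ORF-scan oracle on 500 random sequences
up to 5 kb, vectorisation on 1000 oracle cases, dereplication oracles at
n = 30, and precursor truth-recovery on 50 random neighbourhood specs.
These sizes were chosen to exercise every code path and invariant at
desk scale; the pipeline itself has no intrinsic size limits beyond
memory.

## Known limitations

* The shipped reduced alphabet is a faithful physico-chemical default,
  not the published supplementary grouping; users reproducing published
  results should supply that grouping via `alphabet =`.
* Model persistence is by re-derivation (feature space + training data +
  seed), not by serialising trees; `write_feature_space()` plus a seeded
  `train_classifier()` call reconstructs the model exactly.
* The GenBank parser covers the subset of the format the pipeline emits
  and consumes (simple/complement locations, qualifiers, multi-record
  files); `join()` locations and rich location operators are out of
  scope.
* No remote record fetching: users supply GenBank files locally.
* Mass screening predicts [M+H]⁺ only — no adducts, isotope patterns or
  MS² fragments.
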