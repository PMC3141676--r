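---
title: "Methods: small RNA tag processing, hairpin miRNA discovery and target rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA tag processing, hairpin miRNA discovery and target rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnapipe)
```

## Scope and model of the data

`srnapipe` implements the computational arm of a small-RNA sequencing
study in the diatom *Phaeodactylum tricornutum*: three libraries of
18-28 nt RNA fragments (normal, nitrogen-limited and silicon-limited
growth), sequenced deeply, cleaned, mapped exactly to the genome, split
into annotation categories by a priority rule, and mined for novel
miRNAs by hairpin-precursor criteria, a dinucleotide-shuffle stability
test and a 5'-end homogeneity decision; accepted miRNAs are then
scanned against transcripts with position-specific duplex rules.

Because the deposited sequencing data are not needed to test any of the
method's logic, the package carries a synthetic-data generator that
plants every feature class the pipeline must recognise into a toy
genome, together with a per-read truth table.  All statistical claims
made by the test suite are claims about this synthetic model, and the
generator's defaults define the study conditions used throughout.

## The synthetic study

`make_genome()` draws background sequence i.i.d. uniform over A/C/G/T
and overwrites it with non-overlapping planted features:

* **Hairpin loci.** An arm of 22-26 nt, a terminal loop of 8-12 nt and
  the arm's reverse complement with one injected symmetric mismatch.
  The mature miRNA (20-24 nt) is the 5' segment of the first arm.
  Construction guarantees the precursor criteria: the arms pair
  `stem - mismatches >= 16` bases and the stacked stem folds far below
  the energy threshold.
* **Noncoding RNA loci** are verbatim copies of the bundled synthetic
  rRNA/tRNA/snRNA/snoRNA reference fragments (`inst/extdata`), so
  degradation fragments both map to the genome and match the
  references.
* **Gene models** are two-exon genes (250 + 120 + 250 nt) on either
  strand, exported as GFF3.
* **siRNA duplex loci** plant a plus-strand tag and a minus-strand tag
  offset so the two are perfectly complementary with 2-nt 3' overhangs.
* **Repeats** are two copies of one 150-nt family (BED).  The
  organellar entry carries an inverted-repeat pair: two intervals whose
  sequences are exact reverse complements.
* A 1.2-kb tail of `chr_1` is reserved as a minus-strand **read
  hotspot**; no sequence feature may overlap it.

`make_libraries()` emits, per library, adapter-flanked reads: mature
reads with negative-binomial counts (mean 25, size 8 — the heavy tail
reproduces libraries in which ~3 of 4 distinct tags are sequenced
once), with 5' ends jittered by one base with probability
`five_prime_jitter`; noncoding and mRNA degradation fragments; siRNA
duplex tags; known-miRNA homolog reads; hotspot reads; genome-derived
background (10% of tags duplicated 2-3 times); non-genomic random
reads; and deliberate artifacts (adapter-free reads, sub-18-nt
inserts) for the cleaning stage.  What the generator does **not**
emulate: sequencing errors, quality-score variation, ligation bias,
expression differences between conditions.  Tests passing on this
model therefore demonstrate the pipeline's logic, not its robustness
to platform noise.

## Read processing

The 3' adapter is located by an exact match of its first 8 nt anywhere
in the read, trimming at the leftmost occurrence.  Reads with no
detectable 3' adapter are dropped as unligated artifacts: an 18-28 nt
insert sequenced at 36 cycles must read through into the adapter, so a
read without one carries no reliable insert boundary.  "Low quality"
means any base below phred 20 or any N — the choice of threshold is a
package default, configurable.  Inserts outside 18-30 nt are dropped
and counted.  Collapsing preserves read counts exactly (a conservation
property the tests assert), and summary percentages follow the report
conventions: whole percents for singleton shares, two decimals
(half-up) for category and overlap tables.

## Exact mapping

Mapping is all-hits, both strands, zero mismatches.  `map_tags()`
hashes every genome substring of each tag length against the tag set;
`map_tag()` wraps Biostrings exact matching for single queries.  Both
are checked in the tests against a naive full-scan oracle built on
base-R string search.  Multi-hit tags contribute their full redundant
count to every hit in Figure-style strand profiles (matching the
all-hits policy); a fractional weighting is available for diagnostics.
Hotspots are maximal runs of 1-kb windows (step 500) holding at least
1% of the library's redundant reads; defaults are configurable and the
tests use planted clusters.

## Annotation priority

Each tag receives exactly one category along
rRNA/tRNA/snRNA/snoRNA (GenBank-labelled references outrank
Rfam-labelled ones) > known miRNA > exon > intron > siRNA >
non-annotated.  Noncoding matching uses a deterministic ungapped
criterion — at least 16 nt at 90% identity, found via a shared-8-mer
diagonal search — instead of a BLAST E-value, which would depend on
database size and tool internals.  Known-miRNA homology is a
full-length gapless comparison sliding over a length difference of at
most 2, accepting at most 2 mismatches or 90% identity.  Gene overlap
requires full containment of a hit in an exon or intron;
boundary-straddling hits contribute nothing.  siRNA duplexes require
equal-length tags, perfect complementarity over all but the 3'-terminal
dinucleotides, and hence 2-nt 3' overhangs on both strands — a blunt
reverse complement does not qualify.  Phasing of siRNA 5' ends is
scored as the largest register fraction modulo 21, with a permutation
p-value; minus-strand ends are shifted +2 before register assignment
(the duplex-overhang correction).

## The folding engine

Discovery depends on a self-contained, deterministic secondary
structure folder (`fold()`): dynamic programming over pseudoknot-free
structures with Watson-Crick and G:U pairs, nearest-neighbour stacking
energies, a minimum hairpin loop of 3 nt, and size-dependent loop
penalties (log-size for hairpin loops, linear for interior/bulge loops
capped at 10 unpaired bases, flat for multiloops).  Loop penalties
matter: with cost-free loops, random windows pair candidate tags
promiscuously and the hairpin filter loses its meaning; with sized
penalties the engine's behaviour on random sequence approaches that of
thermodynamic folders.  The engine is validated against an independent
exhaustive enumeration of all nested structures for sequences up to
14 nt.  Published MFE values computed with external folders are not
expected to reproduce numerically under this model; any backend
honouring the `fold()` contract (structure, partner vector, energy) can
be substituted.

## miRNA discovery

Candidates are tags with more than one read and 1-20 genome hits.  At
each hit a window of 300 nt flank on each side is extracted
(reverse-complemented for minus-strand hits) and folded.  The star arm
is the dominant side pairing the mature; up to 4 stray pairs to the
other side are ignored, more means the mature straddles the terminal
loop.  Walking the mature:star duplex counts symmetric interruptions
(mismatches) and asymmetric ones (bulges); interruptions larger than
3 nt on either side disqualify the duplex, since miRNA:miRNA* bulges
span a few bases at most.  The excised precursor (duplex plus loop plus
20-nt retained flanks — the 300-nt window is only a search space) must
itself fold back into the reported stem-loop and reach -18 kcal/mol;
all reported characteristics come from the precursor's own fold.  If
the full window fails, tighter excisions (±100, ±50) are retried, since
a global fold can bury a genuine stem in flank structure.  Stability is
tested by the dinucleotide-preserving (Altschul-Erickson) shuffle:
`p = (1 + #{shuffled MFE <= observed}) / (N + 1)` with N = 199 by
default (the test suite and the replicated recovery experiment use
N = 99 to keep hundreds of repetitions fast; the decision structure is
unchanged).  5' homogeneity is, per library, the redundant reads
sharing the mature 5' end over all redundant reads on the precursor's
mature strand.  Acceptance requires best-library homogeneity > 0.5 when
p <= 0.05, or >= 0.75 otherwise; the best-library reading is one of two
defensible interpretations (the other being every library with reads)
and is recorded in each report row.  When several hits of a tag yield
accepted hairpins the most stable precursor is reported, and lesser
candidates whose hits fall inside an already-accepted precursor are
treated as reads of that locus, not as independent candidates.
Candidates within 10% of any threshold are flagged `needs_review` —
the mechanical residue of manual rechecking; the judgment itself is out
of scope.

### What recovery tests do and do not show

Over 100 simulated studies (jitter 0.1), planted-miRNA sensitivity is
~98% and a small number of *background* loci are accepted (~0.3 per
study).  These are not bookkeeping errors: they are loci where a
duplicated background tag happens to pair 16+ bases (G:U included)
into a star with small interruptions, the precursor reaches
-18 kcal/mol, and the trivially-high homogeneity of a two-read locus
satisfies the decision rule.  An independent thermodynamic folder
assigns such loci hairpin MFEs below the threshold as well.  In other
words, the published criteria themselves admit occasional
random-sequence loci once a multi-read tag lands on one; on real data
such loci are indistinguishable from genuine lineage-specific miRNAs
without orthogonal evidence (expression blots, star reads,
conservation).  The package reports them honestly rather than
tightening thresholds beyond what the method states.

## Target rules

Duplex alignment consumes the whole miRNA against an antiparallel
target window (window length = miRNA length + 3, step 1), scoring
Watson-Crick +5, G:U +1, mismatch -3, gap -9, with match/mismatch
contributions doubled at seed positions 2-8.  Sites must score >= 90
with duplex energy <= -20 kcal/mol; duplex energy uses the same
stacking table as the folding engine restricted to intermolecular
stacks, which makes the energy ratio against the miRNA's perfect
complement exactly 1 for a perfect site.  The strict filter applies,
counting from the miRNA 5' end and weighting G:U as 0.5 everywhere:
<= 4 weighted mismatches at positions 2-21; no run of three mismatches
anywhere; no adjacent mismatches in 2-12 (a G:U between two mismatches
leaves them non-adjacent); strict Watson-Crick at 10-11; <= 2.5
weighted mismatches at 1-12; and energy ratio > 0.74.  The relaxed
variant enforces only the positions-2-21 rule, ignoring position 1 and
positions beyond 21.  Strict passes are a subset of relaxed passes by
construction, and a 10,000-duplex test asserts it.

## Numerical conventions and degenerate inputs

Coordinates are 1-based inclusive everywhere (the native convention of
the interval containers used), rendered `chrom:start:end:strand` in
reports.  Percentages round half away from zero.  Summary mean
precursor length is floored; mean MFE rounds to two decimals.
`randfold_p()` with N = 0 returns p = 1 with a warning; a homogeneity
denominator of zero renders as `0/0` and counts as fraction 0.  Tags
containing N are rejected by the mapper rather than silently skipped.
The dinucleotide shuffle returns constrained sequences (homopolymers,
strictly alternating sequences) unchanged, as the Eulerian-path null
requires.

## Problem sizes

The bundled analyses and tests run at deliberately small scale: 2
chromosomes of 8 kb, 3 hairpin loci, libraries of a few hundred reads,
100 replicate studies for the recovery experiment, 500 draws for the
shuffle-null uniformity check (N = 99), 1,000 queries for the mapper
oracle, 10,000 duplexes for the rule-containment property.  These sizes
were chosen as the smallest at which each claim is statistically
meaningful.

## Known limitations

* The folding model is intentionally compact (no dangles, no
  coaxial stacking, flat multiloop cost, interior loops capped at
  10 nt); it ranks hairpins sensibly but its absolute energies are not
  comparable to published Mfold/RNAfold values.
* The E-value-free noncoding matching criterion is deterministic but
  stricter than BLAST for short, gapped similarities.
* The 5'-homogeneity decision uses the best library; studies wanting a
  consensus-across-libraries reading should post-filter the report.
* Expression differences between the three conditions are not
  simulated, so condition-specific expression patterns are outside what
  the synthetic tests can validate.
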