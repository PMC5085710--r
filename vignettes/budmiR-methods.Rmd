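---
title: "Methods: small RNA-seq miRNA discovery, differential expression and degradome-supported target calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA-seq miRNA discovery, differential expression and degradome-supported target calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(budmiR)
```

## Scope and model of the data

budmiR implements the computational core of a classic two-library plant
small RNA-seq study: a male-sterile (MS) and a male-fertile (MF) library of
18-30 nt reads sequenced from pooled tissue, with no biological replicates.
The pipeline (i) cleans and collapses reads into unique tags, (ii)
partitions tags into annotation categories against user-supplied reference
sets, (iii) identifies conserved miRNAs by exact match to a mature
reference, (iv) predicts novel miRNAs from genome-mapped tags with a
five-criterion hairpin test, (v) calls differential expression with the
Audic-Claverie exact test on normalized counts, (vi) predicts miRNA targets
with a rule-based complementarity scan, and (vii) validates cleavage sites
from degradome (PARE) 5'-end profiles with a permutation test.

Because the libraries are unreplicated pools, no dispersion is estimated
anywhere: the differential-expression model is the exact conditional test
for two Poisson-sampled counts at different sequencing depths, and all
downstream calls treat the two libraries as fixed observations.

## Preprocessing

Reads are cleaned in a fixed order: mean-Phred quality filter, 5' adapter
strip (when the read starts with the adapter at one mismatch or fewer), 3'
adapter location, 5'-adapter contamination check on the insert, N filter,
polyA filter, and the 18-30 nt length window. The 3' adapter is located at
the leftmost position whose read suffix matches an adapter prefix of at
least 5 nt with at most one mismatch; reads without a locatable adapter are
discarded as contaminants rather than kept untrimmed, because an untrimmed
read of unknown insert boundary cannot be collapsed into exact tags.

Three thresholds here are conventions, not published values, and are
exposed as configuration: the polyA rule is operationalized as "at least
80% adenine"; the quality cut-off defaults to mean Phred 20; the minimum
adapter overlap is 5 nt.

Classification against rRNA/tRNA/snRNA/snoRNA/repeat sets uses exact
substring matching on either strand of the reference sequences. This
replaces similarity search against external databases: it removes the
external-database dependence, keeps the decision auditable, and matches the
perfect-match spirit of the rest of the pipeline, at the cost of missing
inexact fragments (a known limitation). Ties across categories are resolved
by a fixed precedence that mirrors sequential filtering:
`miRNA > rRNA > tRNA > snRNA > snoRNA > repeat > exon_sense >
exon_antisense > intron_sense > intron_antisense > unannotated`.

## The folding engine

Novel-miRNA prediction needs a secondary-structure folder. The engine is a
pluggable contract consuming a sequence and returning a dot-bracket
structure and an energy; two engines ship:

* `"nussinov"` (default): a compiled base-pair-maximization dynamic program
  over Watson-Crick and G:U pairs with a minimum hairpin loop of 3 nt, and
  a fixed per-pair pseudo-energy of -2 kcal/mol. The primary objective is
  the pair count (the test suite proves the count equals an exhaustive
  independent DP on sequences up to 70 nt); ties between count-equal
  structures are broken by a strict secondary objective of base-specific
  pair weights plus a helix-stacking bonus, bounded so it can never trade
  away a pair. The tie-break matters: pure count maximization is highly
  degenerate, and without it count-equal but fragmented structures are
  returned for perfectly complementary stems.
* `"vienna"`: the ViennaRNA `RNAfold` thermodynamic folder, used through
  its command-line binary when installed.

The deterministic engine is the default because every planted-truth
guarantee of the synthetic-data module is verified under it at generation
time, making the whole test pyramid (generator, criteria, end-to-end
recovery) internally coherent and reproducible with no external binary.
All downstream logic consumes only the dot-bracket string and the energy,
so swapping engines does not change any other code path.

From the fold, three hairpin statistics are computed: MFE (kcal/mol),
AMFE = |MFE| / length x 100, and MFEI = AMFE / GC%. A GC-free precursor
gets MFEI = 0 (and thus fails the MFEI filter) instead of a division by
zero.

## The five novel-miRNA criteria

A candidate locus is an exact genomic match of a residual (unannotated)
tag; tags with more than 20 loci are dropped as repeats. Around each locus
three windows are excised (tag plus 250 nt upstream, downstream, and
centered) and folded; the accepted window with the best MFE represents the
locus. The criteria on a folded window:

1. **miRNA\* detected** -- some sequenced tag maps onto the star region
   predicted from the structure. The star is derived as the positions
   paired to the mature span shifted by the 2-nt 3' Dicer offset; the
   matching tag may wobble by up to 2 nt at each end (the tolerance is a
   design choice; no published value exists).
2. **duplex mismatches < 3** -- an unpaired mature base whose partner
   region is also unpaired counts one mismatch (internal loops count once
   per mature base).
3. **2-nt 3' overhangs on both strands** -- measured on the observed
   miRNA\* when one is sequenced; when no star tag exists the
   structure-predicted star (which carries the offset by construction) is
   used, so a missing star fails criterion 1 and only criterion 1.
4. **bulges** -- at most one asymmetric bulge and fewer than two bulged
   bases in the duplex.
5. **MFEI > 0.8**, and **mature read count >= 5**.

A mature span overlapping a terminal loop rejects the candidate outright
(`loop_overlap`). When both arms of one precursor pass everything (a
well-sequenced star), the more-abundant arm is reported as the guide and
the other is marked `star_arm_of_guide` -- the field's convention for
reporting one miRNA per duplex.

## Differential expression

Counts are normalized to reads per million; a zero count is replaced by
0.001 so that library-specific miRNAs keep finite fold changes and log2
ratios. The p-value conditions on the count in one library: given `x` at
depth `N1`, the count `y` at depth `N2` follows
`p(y|x) = (N2/N1)^y (x+y)! / (x! y! (1+N2/N1)^(x+y+1))`. The two-sided
p-value doubles the smaller tail (capped at 1). Because the raw conditional
test is not exactly symmetric in its two arguments, the reported value is
the minimum of the two conditioning directions, which makes
`p(x, y, N1, N2) = p(y, x, N2, N1)` hold exactly -- the package treats the
two libraries symmetrically by construction. Tails are accumulated from
log-space terms (no factorials are formed) and the upper tail is summed
directly with an explicit truncation horizon rather than as one minus a
cumulative, avoiding cancellation; the test suite pins the result to a
brute-force series oracle at 1e-10 over a 101 x 101 x 3 grid, and to the
closed form `C(x+y, y) / 2^(x+y+1)` at equal depths.

Fold change is reported as `max(nx, ny) / min(nx, ny)`, so the three bands
-- above 2, 1.2 to 2, below 1.2 -- partition all miRNAs, with direction
carried by the sign of `log2(nx/ny)`. The convention of calling a
*sub-1.2* fold change with p < 0.05 differentially expressed appears in
some study designs; read literally it contradicts the band coloring of the
usual scatter layout, so the default flags DE = significant AND high band,
and `literal_low_band = TRUE` adds the literal reading. Band edges and
alpha are configuration (defaults 2, 1.2, 0.05).

A `2^-ddCt` helper for qPCR relative expression is included for
completeness of the expression-analysis surface.

## Target prediction

Each miRNA is slid along each transcript with a banded complementarity
alignment allowing at most one 1-nt bulge on either strand. Scoring weights
are mismatch/bulge 1 and G:U 0.5 (applied globally, the convention of the
rule set's source method; restricting the half-penalty to the 5' region
would only relax the global limit). The six rules: total weighted
mismatches <= 4; no more than two adjacent mismatches; no adjacent
mismatches within miRNA positions 2-12; positions 10-11 both paired;
weighted mismatches within positions 1-12 <= 2.5; duplex energy at least
75% of the energy of the miRNA bound to its perfect complement. Duplex
energies use per-pair pseudo-energies (G:C -3, A:U -2, G:U -1 kcal/mol) for
both the duplex and the perfect complement, making the ratio
engine-consistent by construction. Bulges are counted as one mismatch each
and are forbidden opposite positions 10-11; position indexing is 1-based
from the miRNA 5' end. Overlapping candidate alignments at one locus
collapse to the best-scoring duplex. The scanner is compiled and uses a
seed prefilter on miRNA positions 1-13, which keeps the degradome
permutation test (thousands of whole-transcriptome rescans) fast.

## Degradome analysis

Degradome tags (5'-end signatures, sense strand, exact match) build a
per-position depth profile for each transcript. The predicted cleavage
position of a target site is the transcript base paired to miRNA position
10 (canonical slicing between 10 and 11). Peak categories follow the
CleaveLand convention: 0 = unique maximum above the median of nonzero
depths; 1 = shared maximum; 2 = above the median; 3 = at or below it;
4 = depth exactly 1.

The p-value is a permutation test rather than an analytic null: the miRNA
is shuffled preserving dinucleotide composition (Altschul-Erickson
Eulerian-path shuffle), each shuffle is scanned against the whole
transcriptome, and a shuffle succeeds if it has any rule-passing duplex
whose cleavage position reaches a category at least as good as the
observed one. With the add-one correction,
`p = (1 + successes) / (1 + n_perm)`. This scheme is self-contained,
seedable and testable; it is declared as a substitute for the original
tool's null model, not a reconstruction of it. Defaults: 1000
permutations, mandatory seed; calls with p < 0.05 are reported.

## The synthetic-data generator

The generator defines the study conditions the tests run under: two
libraries of 50,000 reads with insert-length mode in 21-24 nt (24 most
frequent), a planted set of 8 known and 10 novel miRNAs, log-normal base
abundances (meanlog log 60, sdlog 0.5) shared across libraries and
multiplied by per-miRNA fold factors `{1, 1, 4, 4, 0.25, 8, 0, Inf}`
(0/Inf plant library-specific miRNAs), Poisson count sampling, miRNA\*
reads at a few copies, an rRNA/tRNA/snRNA/snoRNA/repeat/mRNA-fragment
background plus ~60% random unannotated tags (echoing the dominance of
unannotated tags in real bud libraries), and a sprinkling of contaminants
exercising every discard reason. Degradome data plant one cleavage peak
per transcript at ten times the background depth (Poisson 20 vs count 2).
Where the emulated study stated a value (length window, depth scale,
modal lengths, fold-change bands, peak dominance) the defaults follow it;
the remaining levels are fixed once at values a sequencing practitioner
would call unremarkable, and are not tuned.

Planted hairpins are perfect inverted repeats (15 nt stem extension +
mature) around a non-pairing {A,C} loop, verified at generation time by
folding and re-running the criteria; construction retries with fresh
sequences until the realized criteria equal the intended pattern, so the
truth table is correct by verification, not by hope. Single-criterion
violators are engineered structurally (three 1x1 non-pairable internal
loops; a blunt star; a 2-nt star-side bulge; unpaired C flanks that raise
GC% without adding pairs; a read count of 4; a withheld star).

Two deliberate idealizations keep the planted truth provable: genomic
spacers between hairpins use a poly-A alphabet that cannot pair with
anything in the hairpins under the default engine, so excised windows fold
to exactly the designed structures; and background ncRNA references are
random sequences labelled per category, so classification precedence is
testable without external databases. Consequently the simulator does not
emulate sequencing error, isomiR end-variation, genome repeat structure or
realistic nucleotide composition -- passing tests demonstrate the
*machinery* is correct under the stated statistical structure, not that
real cotton data would yield any particular biological result.

## Numerical and degenerate-input choices

* Tail summation for the exact test truncates when the horizon passes the
  conditional mean by 20 standard deviations and terms fall below 1e-18.
* MFEI of a GC-free window is 0, failing the filter, never NaN.
* An empty read stream warns and yields empty output; a malformed FASTQ
  record errors with its record index; an unknown reference category, a
  chromosome missing from the genome FASTA, and a non-positive library
  size all error immediately.
* Fold-change band edges are half-open with 2.0 in the middle band;
  equality at 1.2 is middle band, matching the ">2" and "1.2 <= fc < 2"
  statements.
* All randomness flows from explicit seeds; the pipeline rerun at the same
  configuration is byte-identical (asserted in the tests).

## Problem sizes in the shipped tests

The unit suite runs on toy inputs (tens of tags, transcripts under 600
nt). The end-to-end checks simulate 50,000 reads per library with 10
planted novel hairpins, scan ~20 miRNAs against 8 transcripts, and use
1000 (recovery) / 300 (null) permutations over 200 null trials. These
sizes were chosen as the smallest at which the recovery and error-rate
properties are statistically meaningful.

## Known limitations

* Exact matching everywhere (classification, genome mapping, degradome
  alignment): no mismatch tolerance, no isomiR handling.
* Known-miRNA identification does not assign precursors or infer arms
  structurally; arm labels come from reference ID suffixes only.
* The degradome null is a permutation scheme, not the original analytic
  null; p-values from the two are not numerically comparable.
* The default folder is a pair-count model with pseudo-energies; absolute
  MFE values are not thermodynamic (use the ViennaRNA engine for those),
  though MFEI-based filtering is calibrated to the same 0.8 threshold.
* No multiple-testing correction is applied anywhere, matching the
  emulated design (unreplicated pools, per-miRNA exact tests).
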