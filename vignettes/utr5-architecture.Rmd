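---
title: "Methods: characterising 5'UTR regulatory architecture with utrscape"
author: "utrscape authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterising 5'UTR regulatory architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific problem

The 5' untranslated region (5'UTR) of an mRNA carries much of its
translational regulation. Upstream AUG codons (uAUGs) can capture the
scanning 43S pre-initiation complex and form upstream open reading frames
(uORFs), overlapping ORFs (oORFs), N-terminal extensions (NTEs) or
start-stop elements, all of which modulate how much protein the main coding
sequence produces. Genes that are sensitive to changes in dosage -- those
intolerant of loss-of-function (LoF) variation, and many disease genes --
are expected to rely on this layer of regulation more heavily than tolerant
genes. `utrscape` implements a reusable pipeline for testing exactly that:
it annotates the uAUG landscape of one representative transcript per gene,
derives a per-gene feature vector, and compares those features across
cohorts stratified by LoF constraint (LOEUF deciles), disease gene sets,
transcription-start-site diversity and expression, under explicit
Bonferroni control. A synthetic-cohort generator makes every stage testable
without any external downloads.

## Element classification

Every occurrence of `ATG` in the spliced 5'UTR is one upstream element, and
the four classes partition them:

* **start-stop** -- the AUG is immediately followed by `TAA`/`TAG`/`TGA`
  (a 6-nt element; the ribosome pauses without producing a peptide);
* **uORF** -- the first in-frame stop codon lies wholly inside the 5'UTR;
  the element runs from the AUG through that stop codon. When several
  uAUGs share one stop, each is a separate element (so a uORF and a
  start-stop can share a stop codon);
* **NTE** -- no in-frame stop inside the 5'UTR and the uAUG is in frame
  with the CDS (`(utr_length - offset) %% 3 == 0`): translation elongates
  the annotated protein;
* **out-of-frame oORF** -- no in-frame stop and out of frame with the CDS.

Element length includes both the start and the stop codon, so a start-stop
has length 6 and the shortest true uORF has length 9. The re-initiation
distance is measured from one base past the stop codon to the CDS start
(0 = abutting). Codons containing `N` are unclassifiable and never act as
stops, a deliberately conservative treatment of ambiguity. These
conventions are enforced by an exhaustive test against a brute-force
per-frame translation oracle over every possible 8-mer 5'UTR.

Kozak context uses the classical -3/+4 rule: *strong* requires `A`/`G` at
-3 **and** `G` at +4; *moderate* exactly one of the two; *weak* neither. A
uAUG closer than three bases to the cap has no -3 base, which counts as
non-matching. The +4 base may come from the CDS when the element abuts the
junction. Because the literature uses several variants of this rule, it is
isolated in one function (`kozakStrength`) rather than baked into the
scanner. Translational-efficiency lookup assembles a fixed context window
(default 6 bases upstream through 2 bases downstream of the AUG, matching
the span of published FACS-seq efficiency tables; the window is
configurable because table dialects differ) and distinguishes two exclusion
reasons: *too close* to the cap to complete the window, versus *context not
in the table*. Codon optimality is the fraction of optimal codons in an
element, excluding the trailing stop codon and a leading `ATG` start codon
from the denominator -- a start-stop therefore has no defined score
(missing, never 0).

## Transcript models and coordinates

One representative transcript per gene is loaded from GTF + FASTA
(`loadTranscripts`). Explicit `five_prime_utr` features are honoured when
present; otherwise the 5'UTR is inferred as the exonic sequence 5' of the
first CDS base. Minus-strand sequences are reverse-complemented; exon
blocks are stored in transcript order. The 5'UTR intron count is the
number of junctions strictly internal to the 5'UTR: a junction shared
between the last UTR base and the first CDS base of one exon does not
count. Transcripts without an annotated 5'UTR are excluded and counted
(`retained + excluded + skipped == seen` is asserted in tests). Duplicate
transcripts for one gene keep the first and warn, mirroring a
single-representative-transcript design.

Internally the package follows the Bioconductor convention (1-based,
inclusive `IRanges`) for stored exon structures, while the public mapping
functions `genomicToTranscript`/`transcriptToGenomic` speak 0-based
BED-style offsets, which is also the dialect of the score tracks and of
the element table. VCF positions are 1-based on input, as usual. The
round-trip identity of the two mappers over every UTR base is
property-tested on randomised exon structures.

## Conservation and structure

Per-base score tracks (PhyloP-style conservation, CADD-style
deleteriousness) are aggregated as unweighted means over covered bases;
uncovered bases leave both numerator and denominator (zero covered bases
gives a missing value, never 0). Three aggregates per gene feed the
cohort contrasts: all 5'UTR bases; all uORF start and stop codon bases pooled
across uORFs (pooled, not per-uORF-then-averaged -- the two differ when
coverage is uneven, and pooling is the contract); all bases of
start-stops. Multi-valued bases (one CADD score per alternative allele)
are summarised per base first, by mean (default) or max (configurable).

Minimum free energy is never computed in-process: the spliced full-length
5'UTR is handed to an external executable speaking the RNAfold dialect
(`RNAfold` is used when on the `PATH`; any program printing a parenthesised
energy works, and a function backend supports testing). A missing backend
yields a missing MFE and the pipeline continues. Length-window analyses
(e.g. restricting to 100-300 nt 5'UTRs to decouple structure from length)
use inclusive bounds on both ends.

## The dinucleotide-preserving shuffle null

AUG depletion is measured against sequences with identical dinucleotide
composition. The shuffle views the sequence as an Eulerian trail on the
4-vertex dinucleotide multigraph and samples uniformly over all trails:
a random in-tree towards the final nucleotide is drawn with probability
proportional to edge multiplicities (exact enumeration over the at most
4^3 candidate last-edge functions, feasible because the graph has at most
four vertices), the reserved tree edge is placed last in each vertex's
otherwise uniformly permuted out-edge list, and the trail is walked from
the first nucleotide. This preserves the dinucleotide multiset, the length
and both endpoints exactly; swap-based approximate shuffles are not used.
Uniformity over the exhaustively enumerated trail set is verified by
chi-square on tens of thousands of draws. Note that short or repetitive
sequences can have a *singleton* trail set (e.g. `ACACGT` admits no other
arrangement), which is correct behaviour, not a failure to randomise.

Codon counting is overlapping (all `L - 2` windows), not frame-restricted,
because the depletion statistic targets AUG occurrence at any offset; a
frame-restricted mode is exposed as an option. Per gene, the expected
count of a codon is its mean count over `n` shuffles (the full-scale
analysis uses 1000; the test suite uses 200, which already gives
standard errors far below the tolerances tested); `o/e` is
observed/expected where the expectation is positive and missing where it
is zero -- no pseudocount is invented, and missing ratios simply drop out
of the cohort mean. Sequences containing `N` are excluded with a recorded
reason. On null cohorts (i.i.d. sequences) the cohort o/e of every codon
is centred on 1, which the acceptance suite checks to within four standard
errors.

## Variant effects on the uAUG landscape

A 5'UTR variant (SNV or indel up to 3 bp, on the spliced transcript;
intronic 5'UTR variants are out of scope) is applied in transcript space
and the altered 5'UTR rescanned. Element identity is tracked through a
coordinate map -- in-place substitutions keep all coordinates, indels
shift downstream offsets, deleted bases map to nothing -- so an indel that
merely shifts a uAUG is *not* reported as lost-plus-gained. The effect
labels are: `uAUG_gained`, `uAUG_lost`, `uSTOP_lost` (a uORF/start-stop
keeps its start but loses its in-UTR stop, becoming an oORF/NTE),
`uSTOP_gained` (the reverse transition), `kozak_changed`, and `none`
(never co-occurring with another label). Multiple labels are allowed.
Saturation enumeration emits every SNV, every deletion of length 1-3 and
every insertion of all `4^k` sequences (`k <= 3`) at every UTR position in
deterministic order. Classification is validated against a naive
rescan-and-diff oracle on a thousand random (sequence, variant) pairs per
run, and every variant is checked to be exactly reversible. Minus-strand
transcripts are supported for SNVs (alleles are reverse-complemented on
mapping); minus-strand *indels* are rejected explicitly -- a known
limitation, acceptable because saturation and the synthetic cohorts work
in transcript space.

## Cohort statistics and the test ledger

Genes are stratified by LOEUF rank into deciles with populations differing
by at most one (ties broken by gene id for determinism; decile 1 = most
intolerant). Headline contrasts compare the extreme quintiles (deciles 1-2
versus 9-10). Disease gene sets are compared against the full cohort with
that set removed; the recessive developmental-disorder control compares
against the middle two deciles (with any recessive genes removed from the
background so groups stay disjoint). Expression quartiles are rank
quartiles of mean TPM over genes with a defined value.

Continuous features use the two-sided Wilcoxon rank-sum test: an exact
permutation p-value (`min(1, 2*min(P(W<=w), P(W>=w)))`, correct under
ties) whenever the full set of group assignments is enumerable within a
budget of 2x10^5 combinations, otherwise the normal approximation with tie
correction. The exact path is verified against an exhaustive permutation
oracle for all group sizes up to 6, and against the classical exact
rank-sum distribution in the tie-free case. (Enumerating all assignments
for two groups of 20 -- over 10^11 -- is not feasible; the combination
budget is the practical reading of "exact for small groups".)
Conservation means use Welch's unequal-variance t-test, whose type-I
error under an unequal-variance null is checked by simulation.
Proportions use the 2x2 chi-square without continuity correction (Yates
exposed as an option; an expected cell below 1 attaches a warning flag).
The uAUGs-per-bp rate is compared as one pooled 2x2 table (uAUG starts
versus all UTR positions per group), matching the use of a chi-square
statistic for a rate; a per-gene rank-sum on densities is available as an
ordinary continuous design.

Multiple testing is controlled by a single study-wide Bonferroni
threshold, `alpha / N` where `N` is the number of *planned* tests -- the
ledger -- not the number that happened to run. The package ships a
default 77-test plan (`ledgerDesigns()`): 24
extreme-quintile contrasts (length, length after removing the bottom 10%
of CDS length, 5'UTR share of the mRNA, MFE and GC overall and within the
100-300 nt window, mean uORF length, re-initiation distance, uAUG count,
four conservation aggregates, six prevalence contrasts, the pooled
uAUG-per-bp rate, canonical Ribo-seq start usage and two CAGE thresholds);
12 expression-stratified contrasts (both CAGE thresholds and Ribo-seq
uORF prevalence within each TPM quartile); 36 disease-set contrasts (six
sets x length, GC, conservation, uORF, start-stop and intron prevalence);
and 5 recessive-versus-middle-deciles controls. Fixing the plan fixes the
threshold, `0.05 / 77 = 6.5e-4` (2 s.f.); any user-supplied designs table
changes it accordingly. p-values
below 1e-15 are rendered `"<1e-15"` in the text column with the numeric
value retained. Filters (CDS-length exclusion, length windows, quartile
restriction) are row predicates anchored to the full cohort, so they
compose in any order.

## The synthetic cohort generator

`simulateCohort()` generates the study conditions at desk scale so that
recovery, calibration and closure are all testable offline. Design
choices, in the order they matter:

* **Backgrounds** are first-order Markov sequences with a configurable
  dinucleotide bias (default: CpG depleted to 0.35 of its compositional
  expectation, fixed-point-calibrated so the *stationary* composition
  still hits the target GC); an i.i.d. preset is the null for shuffle
  calibration. Per-decile GC targets interpolate linearly so the extreme
  quintiles average 0.673 and 0.599.
* **Lengths** are log-normal (sdlog 0.6, clamped to 25-2500 nt) with
  per-decile means interpolating linearly so the extreme quintiles average
  269 and 162 nt.
* **Every incidental ATG is then scrubbed** (middle base rewritten to `C`,
  which can never participate in an ATG, so one pass is terminal). Random
  sequence at realistic lengths would otherwise put a uAUG in nearly every
  gene, whereas real 5'UTRs are strongly AUG-depleted; scrubbing makes the
  element landscape exactly the planted one, which is what recovery
  testing needs. The cost is that *element counts* per gene are planted
  rates rather than emergent, which the tests account for.
* **Elements are planted** by explicit construction (`plantUORF`): uORF
  presence probability interpolates 0.462 to 0.278 across quintiles,
  start-stops 0.068 to 0.045, oORFs flat at 0.15 (a deliberate null
  feature, as are 5'UTR introns at 0.25 and expression); planted uORF
  lengths are `3*(3 + Poisson(12))` bp. Planting verifies its own result
  by rescanning and refuses unachievable requests (an NTE at an
  out-of-frame offset, a strong Kozak on a start-stop -- impossible since
  +4 is the stop's `T`).
* **Conservation** is Gaussian per base (decile-trending baseline) with an
  additive Gaussian uplift (+2.5, sd 0.5) at planted element start/stop
  codons, so the aggregation contract has a closed-form expectation. CADD
  emulation emits three scores per base (one per alternative allele).
* **Planted variants hold by construction, not by circular verification**:
  a uAUG-gained SNV completes an ATG at a site where neither the reference
  nor the altered base participates in any stop codon and a margin keeps
  planted elements' Kozak contexts untouched, so no other element can
  change class; a uSTOP-lost SNV rewrites the first base of a *sole-stop*
  uORF's stop codon to `C` (the uORF is planted in the final third with
  all downstream same-frame stops defused, and `C` can create neither an
  ATG nor a stop). The closure test then re-derives the labels with the
  annotator and requires 100% agreement.
* **Layout**: each gene gets its own contig (N-flanked, optional single
  40-nt 5'UTR intron, 30% of genes on the minus strand), emitted as
  GTF + FASTA + TSV/bedGraph-style tracks + VCF + truth tables -- the
  exact dialects the loaders consume, so the end-to-end test runs purely
  through files.

What the generator does **not** emulate: real human sequence content
beyond composition and element placement; transcript isoform diversity
(CAGE counts are drawn from a negative binomial, not from simulated TSSs);
correlated structure between features (e.g. the MFE-length coupling);
Ribo-seq detection biases. Passing the recovery tests therefore shows the
pipeline is algorithmically correct and calibrated on data with the
planted statistical structure -- it does not certify conclusions about
real genomes, where the published resources (MANE, gnomAD, FANTOM5, GTEx)
are required.

## Problem sizes and numerical choices

The test and acceptance runs use: all 65,536 8-mer UTRs (exhaustive
scanner oracle) plus 10,000 random 300-mers (partition property); all
sequences up to length 8 for shuffle invariants, with explicit
Eulerian-trail enumeration up to length 6 and a 50,000-draw chi-square
uniformity check; 200 random 300-mers x 200 shuffles for the o/e null;
1,000 random (sequence, variant) pairs for the variant oracle; and a
2,500-gene cohort (500 genes per extreme quintile group) for planted
effect recovery at the full 77-test Bonferroni threshold. These sizes
give each check comfortable statistical resolution while keeping a full
run in the minutes range on one core. Degenerate inputs follow explicit
contracts: empty UTRs scan to an empty table, empty groups yield a flagged
result rather than a crash, an empty designs table is an error, and
missing always stays distinct from zero (scores, CAGE counts, o/e ratios,
optimality of start-stops).

## Known limitations

Single representative transcript per gene; no liftover between genome
builds; no near-cognate (non-AUG) start prediction (non-canonical uORFs
enter only via the evidence set, matched by strict coordinate equality by
default with a start-only option); minus-strand indel application is
unsupported; no FDR alternatives to Bonferroni (by design, matching the
analysis the package implements); MFE depends on an external folding
executable and is missing without one.
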