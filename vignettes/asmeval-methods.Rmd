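---
title: "Methods: assembly evaluation, marker mining and expression analysis in asmeval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assembly evaluation, marker mining and expression analysis in asmeval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmeval)
```

asmeval evaluates de novo transcriptome assemblies of non-model organisms,
merges multi-k assemblies, mines microsatellite markers and quantifies
qRT-PCR expression.  This vignette explains the models and procedures, the
parameters that matter, the design choices made where conventions diverge,
and what the synthetic-data generator does and does not emulate.

## Length statistics

`length_report()` reports contig count, mean/min/max length, the
percentage of contigs of at least 1 kb, and N50/N90: sort contigs by
length descending, accumulate, and take the length of the contig at which
the cumulative sum first reaches 50% (90%) of the total.  The boundary is
inclusive ("first reaches at least half"), the conventional reading; N50
is only a contiguity measure and says nothing about accuracy, which is why
the annotation-based metrics below exist.

## Read mapping-back metrics

A placement is accepted when it covers at least a fraction 0.75 of the
read and has identity of at least 0.90 over the aligned columns; both
comparisons are inclusive, since the thresholds are quoted as set points
rather than strict bounds.  Identity is taken from the SAM `NM` tag as
`1 − NM/aligned_len` with `aligned_len` the summed M/=/X operations — NM
counts mismatches plus indel bases, so this is a slightly conservative
proxy for an aligner-internal similarity whose exact definition aligners
do not publish.  Records without an NM tag have unknown identity and are
rejected and counted separately rather than guessed.

`mapping_report()` uses **total reads** (mapped or not) as the denominator
for all three percentages: mapped back (at least one accepted placement),
in pairs (both mates accepted on one contig), and broken pairs (mates
accepted on two different contigs — a fragmentation signal).  Published
evaluation grids are consistent with this denominator but never state it,
so it is fixed here explicitly.  A mate with several placements counts
once through its best accepted one (highest identity, then longest
alignment).  Orientation and insert size are *not* checked for "in
pairs" — co-placement on one contig is the criterion; the stricter
aligner-internal definition is unknowable from outside.

## Ortholog-based metrics

Candidate assemblies are compared against a related species' proteome in
both directions (contig→protein and protein→contig hit tables in the
12-column tabular format).  `best_hits()` filters at an e-value cutoff of
1e-5 (both directions use the same cutoff) and keeps, per query, the hit
with maximal bit score; ties break by minimal e-value, then longest
subject span, then lexicographically smallest subject id.  The chain is a
total order, so results are independent of input row order — important for
reproducibility because real hit tables arrive in arbitrary order.

A reciprocal best hit (RBH) is a contig–protein pair where each is the
other's best hit; RBH is a matching (each side appears at most once) and
is the operational ortholog call.  The ortholog hit ratio of an RBH contig
is

```
OHR = (send − sstart + 1) / protein_length
```

the fraction of the ortholog covered by the best hit, in amino acids.
Two readings of OHR exist in the literature: hit span over ortholog
length, or raw contig length over ortholog length.  asmeval uses the hit
span: contigs carry UTRs, so the raw-length reading systematically exceeds
1 for complete transcripts, contradicting the convention that OHR = 1
marks a full-length reconstruction.  This is the package's headline
interpretation decision.  Multiple HSPs per contig–protein pair are not
merged; the single best HSP is used (conservative and deterministic, since
no published merging rule exists).  Only RBH contigs enter the OHR
distribution; partial orthologs represented by non-RBH contigs are
deliberately excluded, making the metric conservative.

Core-gene completeness follows the classic core-set convention: a core
protein is *complete* when a single hit covers at least 70% of its length
(inclusive), *partial* with any accepted hit, so partial counts include
complete ones and the partial percentage is always at least the complete
percentage.  Percentages are over the full core set.

## The merge pipeline

Multi-k assemblies are pooled (ids prefixed by source label), reduced with
greedy longest-first clustering, meta-assembled, and finally filtered at
300 bp — short de Bruijn contigs below that length carry little signal.

Clustering sorts sequences by length descending and assigns each to the
first existing cluster whose representative matches it at or above the
identity threshold (default 0.99), else it founds a new cluster, so
representatives are always the longest member.  Identity is the maximal
number of matching columns over all gap-free placements of the shorter
sequence inside the longer one, divided by the **shorter** length, with
the reverse complement also considered — the conventions the standard
greedy clustering tool's flags imply (`-c 0.99 -r 1`).  The short-word
count filter of that tool is a speed heuristic and is *not* reproduced;
instead an exact pigeonhole filter is used (an alignment with at most k
mismatches must contain one of k+1 equal blocks verbatim, so candidate
offsets come from exact block matches), which accelerates without
approximating.

Meta-assembly greedily merges the pair with the longest suffix–prefix
overlap of at least `min_overlap = 40` bases at identity at least
`min_overlap_identity = 0.90` (both strands), replacing the pair with a
consensus; disagreements inside the overlap take the base from the longer
parent, continuing the "longest is representative" logic of the
clustering stage.  The defaults are the documented defaults of the
classic overlap assembler this stage emulates; greedy longest-overlap
selection is a simplification of that assembler's scoring and is not
claimed equivalent in general.  On termination no qualifying overlap
remains between any two outputs — re-checked exhaustively in the tests.

## SSR mining, primers and in-silico PCR

`find_ssrs()` detects perfect (uninterrupted) tandem repeats of primitive
motifs of 2–6 bases, with minimum repeat counts 6 for dinucleotides and 5
for tri- to hexanucleotides.  Mononucleotide runs are excluded.  Each
repeated region is reported once: at the smallest primitive unit (an
(AT)~8~ run is a dinucleotide SSR, never an ATAT tetranucleotide) and at
the leftmost phase of the underlying period-u run, so (AG)~7~ never
additionally reports the embedded (GA)~6~.  Detection is run-based
(vectorised comparison of the sequence against itself shifted by u); the
test oracle enumerates repeats with regex lookahead at every position — an
independent route to the same definition.  Compound and imperfect SSRs
are out of scope.  Coordinates are 0-based half-open internally.

A motif and its reverse complement form one *canonical class*, written
with the lexicographically smaller member first (GA/TC); rotations are
**not** merged — GA/TC and AG/CT are counted separately, matching how
published motif tables list them.

Primer design is a deliberately simple rule system, not a thermodynamic
model: primer length 18–24, GC 40–60%, Tm 50–65 °C by the GC-count
formula `Tm = 64.9 + 41·(GC − 16.4)/len`, product 100–300 bp, Tm
difference at most 5 °C.  Candidate windows are scanned outward from the
locus and the first feasible pair wins; loci without sufficient flanking
sequence get no pair, which is the biologically meaningful gate.  The
acceptance surface is self-consistency (returned primers satisfy every
constraint they were designed under), not primer-by-primer agreement with
any specific external tool.

`virtual_pcr()` searches both strands of every contig for sites where the
left primer and the reverse complement of the right primer match within
`max_product` (default 3000) bases.  The defaults are the strictest
interpretation — no mismatches, exact 3'-terminal base — so the
single-amplicon classification (the putative single-locus marker call) is
conservative; both are exposed as arguments.

## Relative expression

The efficiency-corrected ratio is
`E_gene^ΔCt_gene / E_ref^ΔCt_ref` with `ΔCt = mean Ct(control) − mean
Ct(treated)`, so ratio > 1 means up-regulation under treatment.  Ct values
are averaged per condition before the formula (the common usage;
per-replicate ratio averaging would make the stated contract
nondeterministic in replicate pairing).  Amplification efficiencies
default to 2.0 (perfect doubling) per gene when not measured and are
configurable.  `signed_fold()` maps the ratio to the bar-plot convention:
the ratio itself when at least 1, otherwise −1/ratio, a bijection between
(0, ∞) and (−∞, −1] ∪ [1, ∞).  Fold-change values with magnitude below 1
sometimes seen in published figures cannot be expressed in this
convention and are treated as reporting artifacts, not reproduced.

Significance uses a randomization test: condition labels are permuted
jointly for target and reference (paired by replicate), and the permuted
`|log ratio|` is compared with the observed one.  When
`choose(n, n_control)` does not exceed the permutation budget all
assignments are enumerated and the p-value is exact; otherwise random
shuffles are drawn with the `+1/(n+1)` correction.  With 3+3 replicates
there are only 20 assignments, each tied with its mirror image, so the
smallest attainable p-value is 2/20 = 0.1 — worth knowing before planning
a three-replicate experiment.  The commercial tool this replaces uses a
proprietary "pairwise fixed reallocation" scheme whose internals are not
published; the permutation test here is a documented, conservative
stand-in (type-I error at or below nominal, verified by simulation).
Multiple-testing correction across genes is intentionally not applied;
p-values are reported raw.

## The synthetic-data generator

All generators are seed-deterministic (identical arguments give identical
bytes) and exist so that every pipeline stage can be tested against known
truth:

* `generate_reference()` — genes as `utr5 + cds + utr3` with an
  ATG-initiated, single-stop CDS sampled from sense codons (standard
  genetic code) and UTRs of uniform random DNA.  This is the simplest
  model satisfying every invariant the metrics rely on; it makes no claim
  of realistic codon usage or composition.
* `corrupt_assembly()` — one contig per gene retaining a fraction of the
  transcript (drawn uniformly in `(0.8 f, min(1, 1.2 f))`, exactly 1 when
  `f = 1`, so the mean tracks `f`), plus controlled reverse-complemented,
  chimeric and duplicated contigs, with all provenance in a truth table.
  Fractions of contigs convert to whole counts by rounding half away from
  zero so test contracts can be stated in exact counts.
* `simulate_alignments()` — exact whole-pair counts of unmapped and broken
  pairs; mapped records align full-length at identity 1, so acceptance
  thresholds act only where a test constructs violations explicitly.
* `hits_from_truth()` — hit tables computed arithmetically from
  provenance (which part of the CDS a contig covers), with e-values
  monotone in covered length.  No alignment is run, which makes
  ortholog-metric tests exact rather than aligner-dependent.
* `plant_ssrs()` / `simulate_ct_table()` — planted loci with
  non-extending flanks (guaranteeing maximality), and Ct values
  `base − log_E(expression) + N(0, sd)` so the noise-free limit recovers
  ratios to machine precision.

What the generator does **not** emulate: read error models, coverage and
expression-level variation, SNP/indel divergence between contigs and
orthologs, and real codon usage.  Passing tests therefore demonstrate
correctness of the *metrics and procedures* on data whose truth is known —
not robustness to every artifact of real sequencing data.

## Numerical and scale choices

Quality trimming uses the modified-Mott rule: with per-base error
`p = 10^(−q/10)` and limit `L = 10^(−cutoff/10)` (cutoff 20 by default),
the retained segment maximises `Σ(L − p)`; ties prefer the longer, then
leftmost segment, and the result may be empty.  The optimum is found in
one pass over prefix sums and verified against exhaustive O(n²) search in
the tests.  Adapter trimming is out of scope (no adapter list is part of
the problem statement).

Parsing is fail-loud throughout: hit tables must have exactly 12 columns
(extra columns are rejected, not ignored), numeric fields must parse, SAM
CIGARs must be well-formed, FASTA ids must be unique — each error carries
the offending id, position or line number.  Minus-strand rows
(`qstart > qend`) are normalised by swapping with the orientation kept in
a `qstrand` column, since downstream span arithmetic assumes
`qstart ≤ qend`.

Test and acceptance problem sizes (hundreds of genes, a thousand read
pairs or 2-kb sequences, tens of merge inputs) were chosen so the whole
suite verifies every stage on a desktop in about two minutes; every
statistical bound asserted (OHR tracking ±0.05, median log2 error < 0.5
at Ct noise 0.2, type-I error at nominal plus Monte-Carlo slack) was fixed
from the study design before being measured, and the seeds are arbitrary
constants.
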