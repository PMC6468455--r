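---
title: "Small RNA locus discovery: models, criteria and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small RNA locus discovery: models, criteria and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnaloci)
```

# The problem

Small-RNA sequencing libraries from animals mix several read populations:
mature microRNAs (miRNAs) and their passenger ("star") strands, PIWI-
interacting RNAs (piRNAs) produced from genomic piRNA clusters, and
fragments of abundant structural RNAs (tRNA, rRNA) that masquerade as
small RNAs. `srnaloci` implements the desk-scale core of a discovery
pipeline for such libraries: collapse and clean the reads, map them to a
genome, annotate miRNA loci under structural and expression criteria,
detect piRNA clusters under explicit acceptance thresholds, and quantify
the biogenesis signatures that distinguish genuine piRNA production —
5' uridine (1U; "1T" in genome space) bias, position-10 adenine (10A)
bias, the 10-nt 5'-5' ping-pong overlap, and next-uridine phasing.

Because real genomes and libraries are large and partly unpublished, the
package ships a first-class synthetic-data generator that plants loci with
known coordinates and generative parameters into toy genomes and emits a
machine-readable truth set. All acceptance-style checks in the test suite
run against this planted truth.

# The synthetic-data generator

`simulation_config()` + `simulate_genome()` + `simulate_reads()` produce a
single-contig genome (i.i.d. bases at a configurable GC content, default
0.5 — the simplest null under which the 25% baseline for the 1T fraction
is exact in expectation) with planted features laid out non-overlapping,
at least 700 nt apart so that downstream single-linkage cluster merging
(gap 500) can never fuse two features.

The default feature set mirrors the locus architecture the analysis is
designed to recover: three unistrand piRNA clusters (800–1600 nt, 30–60
distinct 30–32-nt reads with a 0.95 probability of a forced 5' U), one
dual-strand cluster (2200 nt), three canonical miRNA loci, one long-
precursor miRNA locus (386 nt), two tRNA and one rRNA contaminant locus,
and one TE copy used only for overlap annotation. Copy counts are
1 + Poisson(3); reads are emitted redundantly (pre-collapsing) so the
collapsing stage is genuinely exercised; FASTQ qualities are constant —
quality trimming is not the scientific content here. Read noise is a
uniform per-base substitution probability, default 0: the package's
recovery guarantees are stated for noise-free reads, and noisy reads
simply fail to map at mismatch allowance 0.

## Ping-pong and phasing geometry

The dual-strand cluster transcribes its precursor from the minus strand.
Minus-strand reads form a single phased chain: each trailing read begins
at the first uridine past the previous read's 3' end, with 0–4 engineered
non-uridine gap bases in between. Responder piRNAs are planted antisense:
a responder's plus-strand 5' end sits 9 nt upstream of its initiator's 5'
end, so the 5'-5' overlap is exactly 10. A consequence of this geometry is
that the responder's position-10 base is the complement of the initiator's
5' base *at the same genomic position*: the 1U bias of initiators and the
10A bias of responders are one shared base and cannot be varied
independently for paired reads. The generator therefore exposes
`prob_5prime_U` for all main-strand reads and lets `prob_10A = NULL`
inherit it at responder-anchored sites; setting `prob_10A` explicitly
overrides the shared base there. Responder lengths mix two modes (24–26
and 30–32 nt, 50/50 by default), emulating production by two PIWI proteins
with different footprints.

## Hairpin construction

A planted miRNA locus is `mature(22) + loop(8) + star(22)`, where the
first 20 star bases are the reverse complement of the first 20 mature
bases. In the duplex this pairs mature position *j* with star position
21−*j*, leaving 2-nt 3' overhangs at both ends — the Dicer geometry the
annotation criteria test for. The long-precursor variant wraps this core
in a perfectly complementary lower stem (`E ... revcomp(E)`) sized to hit
the requested precursor length (386 by default). Two generator
simplifications keep the planted structural extent exact: three
non-pairable "insulator" bases flank each precursor, and the two star
overhang bases are chosen non-pairable with their structural neighbours.
Real precursors end where pairing ends; the insulators just make that
boundary crisp in random surroundings.

The mature sequence carries the seed (positions 2–8) of a configured
family from the packaged seed table, so family assignment can be verified
end-to-end. Mature 5' homogeneity defaults to 1.0 (reads from a bona fide
locus after QC); lowering it plants a fraction of 1-nt-shifted mature
reads.

## What the generator does not emulate

No adapter contamination, no quality-score structure, no indels, no
transposon-derived degradate background, no multi-contig assemblies by
default, and contaminant loci are random sequence rather than real
tRNA/rRNA folds. Passing tests therefore demonstrate correctness of the
analysis logic under the stated generative model, not performance on real
libraries with their heavier-tailed abundance distributions and
imperfectly known contaminant space.

# Read operations

`collapse_reads()` normalises U to T, drops reads containing characters
outside A/C/G/T (bias statistics and ungapped mapping assume a 4-letter
alphabet) and tallies distinct sequences. `filter_annotated()` removes a
read iff it matches a reference substring end-to-end, ungapped, either
strand, within 3 substitutions by default — contaminant subtraction
prioritises specificity, and 3 mismatches is the printed allowance for
this step. `map_reads()` reports *all* ungapped placements on both strands
(default allowance 0 for locus work); multi-mappers are never assigned to
a random single placement, and downstream statistics weight each placement
as `count / n_loci`.

`assemble_crystal_contigs()` builds candidate small-RNA loci from genomic
reads that contain a perfect (either-strand) match to some small read.
Merging is greedy by longest exact suffix-prefix overlap with
lexicographic tie-breaking — a deterministic stand-in for a published
pipeline whose internals are not specified. Contained reads are absorbed
first; near-identical contig deduplication is by substring containment.

# miRNA annotation

`evaluate_locus()` applies the acceptance criteria in a fixed order and
reports the first violated one: (i) two read-supported same-strand arms
forming a duplex within one hairpin, with at least 8 unpaired bases
between them; (ii) weighted mature 5' homogeneity ≥ 0.9; (iii) 2-nt 3'
overhangs at both duplex ends (strict by default, tolerance configurable);
(iv) ≥ 16 paired positions in the duplex; (v) precursor length ≤ 400 nt —
a cap chosen to admit the long flatworm-like precursors up to 386 nt. The
published numeric criteria behind these conventions are not printed
anywhere verbatim, so the defaults are explicit, configurable stand-ins
for standard MirGeneDB-style values; the mature expression floor
(weighted count ≥ 10) acts as a candidacy precondition.

Two design choices deserve explanation:

* **Folding is base-pair maximization, not thermodynamics.** The Nussinov-
  style dynamic program (Watson-Crick + G:U, minimum loop 3, deterministic
  tie-breaking that pairs the leftmost position with its smallest
  admissible partner) is exact, fast in compiled code, and verifiable
  against an exhaustive recursion — which the test suite does on every
  fixture up to 80 nt. Duplex *verification* needs a reproducible pairing,
  not a free-energy estimate; a thermodynamic folder can be substituted
  upstream if desired.
* **Duplex geometry is measured on a register, not on the global fold.**
  Maximum-pairing structures are frequently degenerate near the loop, and
  any tie-breaking rule picks one arbitrary optimum; reading 3' overhangs
  off that structure would make acceptance depend on ties. The overhangs
  and paired-position count are therefore computed from the best
  antiparallel alignment register between the two modal arm reads (ties
  prefer the expected 2-nt register), while the fold is still required to
  show an inter-arm duplex and a valid loop. The precursor extent is then
  found by walking the stem outwards from the outermost duplex pair,
  skipping bulges up to 2 nt.

Candidate windows are formed from pairs of same-strand merged read arms
lying within one precursor length of each other, where at least one arm
passes the expression floor. Dense piRNA-cluster read carpets merge into
single long arms and are therefore never evaluated as miRNA candidates —
a useful structural property, not a special case.

`assign_family()` is a pure function of mature positions 2–8 against the
packaged seed table; a seed absent from the table is "novel", a seed
present under several families sets the ambiguity flag. The packaged
table (`seed_families_synthetic.tsv`) carries the conventional node
structure — 1 Eumetazoa family (MIR-10), 31 Bilateria, 11 Protostomia,
2 Spiralia (MIR-1989, MIR-1992), 1 Ecdysozoa (MIR-305), 3 Nematoda
(MIR-54, MIR-86, MIR-791) — with standard family names but synthetic
placeholder seeds (a handful of famous seeds are real); census and
set-difference arithmetic depend only on names and nodes.
`complement_census()` and `family_set_difference()` implement the
presence/absence bookkeeping; with the packaged node lists the flatworm-
and nematode-lineage complements differ by exactly six families.

# piRNA cluster detection

Candidates are maximal runs of mappings with inter-mapping gaps ≤ 500 nt
(single linkage; the windowing of the reference tool is not published, so
the merge distance is an exposed parameter). Acceptance requires all of:

* span ≥ 500 bp;
* weighted hits ≥ 20 (with `count / n_loci` weighting; an unweighted
  variant is a flag, since "hits" is ambiguous between mappings and
  distinct sequences);
* **> 75%** of sequences (weighted) within 24–32 nt;
* **> 75%** of sequences carrying 1T *and/or* 10A — a per-sequence OR,
  as in the reference detector: a dual-strand ping-pong cluster has
  1T-biased initiators and 10A-biased responders, and neither global
  fraction alone need clear 75% even when every single read carries one
  of the two marks (both global fractions are reported per cluster);
* evenness: the top 10% of distinct sequences (by weighted count) carry
  **< 75%** of the cluster's weight.

Strict inequalities are honoured exactly as printed at the boundaries,
and every rejected candidate's report names all violated criteria. A
cluster is called dual-strand when the minority strand holds more than
10% of the weight — an invented, configurable threshold; the underlying
observation is only qualitative ("minus > plus").

The analytics are deliberately elementary and fully specified:
`base_bias()` (weighted positional base fraction, with reads shorter than
the position excluded from the denominator and an NA flag when nothing
contributes), `entropy_logo()` (information = 2 − Shannon entropy in
bits, letter heights = frequency × information), `ping_pong_profile()`
(all opposite-strand pairs; overlap = minus 5' − plus 5' + 1; pair weight
= product of the two mapping weights; modal ties break to the smallest
overlap), `phasing_profile()` (transcription-ordered consecutive gaps,
downstream-5'-uridine and next-uridine-rule fractions; overlapping pairs
are recorded but kept out of the gap histogram), and
`strand_length_stats()` (per-strand weighted length histograms; a strand
is flagged bimodal when two local modes ≥ 3 nt apart each hold, with
their ±1-nt neighbourhood, > 20% of the strand's weight — the
neighbourhood makes the flag a property of the length *modes*, not of how
weight splits among adjacent bins). Length histograms are normalised
per cluster, not globally; the alternative normalisation is a one-line
change and the choice is flagged here deliberately.

# Orchestration and recovery scoring

`run_pipeline()` executes simulate → collapse → filter (tRNA/rRNA) → map
→ miRNA discovery → miRNA-precursor subtraction → piRNA detection →
recovery scoring, writing standard formats (FASTA/FASTQ, GFF3, BED6 +
sidecar TSV, JSON) into one run directory. The summary JSON contains only
reproducible tallies — timings go to the log file — so identical config
and seed give a byte-identical summary. `score_recovery()` matches calls
to planted features of the same class one-to-one, greedily by decreasing
interval Jaccard with a 0.5 threshold; precision is reported as NA when
there are no calls rather than silently as 0. The shell entry point
(`exec/srnaloci` with `simulate`, `run`, `score` subcommands) is a thin
wrapper over these functions; the per-module operations are exposed as
plain R functions rather than separate subcommands.

# Numerical and scale choices

Problem sizes are chosen so the whole suite runs comfortably on one CPU:
a 30-kb default genome, ~2,000 reads, clusters of 30–120 distinct
sequences, and a 100,000-read null set for the 25% 1T baseline (binomial
standard error ≈ 0.14 percentage points, comfortably inside the ±0.5
check). All randomness flows from a single integer seed: the genome uses
it directly, the read simulator a derived sub-seed, and every seeded
function restores the caller's RNG state. Determinism extends to
byte-identical FASTA/FASTQ output and to folding tie-breaks.

# Known limitations

* Mapping is exhaustive scan-based (via Biostrings pattern matching), fine
  at desk scale but not a short-read aligner; no indels anywhere.
* Base-pair maximization over-pairs relative to thermodynamic folding;
  criteria depending on subtle secondary-structure energetics are out of
  reach by design.
* The evenness and bias filters inherit the weighting choice; with
  heavily multi-mapping libraries the weighted and unweighted variants
  can disagree, and both are available.
* The packaged seed table's seeds are placeholders: real-data family
  assignment requires substituting a curated seed catalogue via
  `read_seed_families(path)`.
* Planted-truth recovery (precision = recall = 1) is demonstrated under
  the default noise-free conditions; it is a correctness statement about
  the implementation, not a sensitivity claim about noisy libraries.
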