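---
title: "Detecting CRISPR/Cas9 editing sites genome-wide: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting CRISPR/Cas9 editing sites genome-wide: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editscan)
library(dplyr)
```

## The problem

CRISPR/Cas9 editing of plants produces small indels at the designed
(on-target) locus through error-prone NHEJ repair, and occasionally at
unintended (off-target) loci that partially match the guide RNA.  Most
screening work checks only a short list of predicted off-target sites.
The approach implemented here inverts that logic: call variants
genome-wide in edited plants, strip everything attributable to the
genetic background, and then ask, for every surviving variant, whether
the surrounding sequence looks like a guide target.  The package
implements each stage of that pipeline together with an in vitro
cleavage-site caller and an amplicon deep-sequencing quantifier, plus a
synthetic-data generator so the whole pipeline is testable without any
external sequencing data.

## Guide matching

A target site is a protospacer match (17--23 nt, 19 nt for the
constructs this pipeline was designed around) followed immediately by a
PAM matching an IUPAC 3-mer pattern (`NGG` for SpCas9; alternatives such
as `NAG` can be declared).  `scan_sequence()` reports every site on both
strands with

* up to `max_mismatches` protospacer mismatches (default 6, the largest
  mismatch count at which SpCas9 cleavage has been observed), or
* exactly one one-nucleotide bulge -- an extra genomic base (DNA bulge)
  or an omitted genomic base (RNA bulge) -- carrying at most
  `bulge_mismatch_cap` mismatches (default 0).

Design choices that the matching contract leaves open were fixed as
follows:

* **PAM handling.**  The PAM must match its pattern; PAM mismatches are
  never added to the mismatch count (the convention used when comparing
  predicted off-target lists).  A `pam_mismatch_counted` switch exists
  for sensitivity analyses but defaults off.
* **Bulge geometry.**  A bulge may sit anywhere strictly inside the
  protospacer.  At either terminus a bulged alignment is
  indistinguishable from a shifted bulge-free alignment, so terminal
  gaps are not enumerated.
* **One site, one record.**  Overlapping alignments are reduced in two
  steps: a bulge alignment is suppressed when an overlapping bulge-free
  alignment on the same strand explains the locus with no more
  mismatches, and alignments sharing a blunt-cut position are reduced to
  the best one (fewest mismatches, bulge-free preferred, leftmost, then
  the `+` strand).  This keeps one deterministic record per physical
  site.
* **Ambiguity codes.**  `N` (or any IUPAC ambiguity code) in the genome
  counts as a protospacer mismatch -- conservative in masked regions.
* **Coordinates.**  0-based half-open internally and in BED output;
  1-based in VCF-facing I/O.  The blunt cut lies between `cut_position`
  and `cut_position + 1`, 3 nt 5' of the PAM.

The scanner computes Hamming mismatch counts for all offsets with a set
of cumulative mismatch matrices (one per alignment shift), which keeps
the whole computation vectorised; no index structure is used, since a
linear scan handles the hundred-kilobase fixtures and megabase-scale
genomes this package targets in seconds.  The test suite checks the
scanner against an independent enumeration oracle built on
`Biostrings::neditStartingAt()` across the full parameter grid.

## Variant consensus and control subtraction

Per-caller VCFs (three SNV callers, three indel callers, two SV callers
in the workflow this reproduces) are normalized -- multi-allelic records
split, shared prefix/suffix bases trimmed, indels left-aligned with one
anchor base -- so the same physical event compares equal across caller
dialects.  The consensus then keeps:

* SNVs reported by at least `snv_min_callers` (default 2 of 3).  The
  source workflow's wording ("repeatedly in the results from three
  programs") is ambiguous between 2-of-3 and 3-of-3; it is read as
  "more than once" and the threshold is exposed in
  `consensus_params()`.
* indels reported by at least 2 of 3 callers;
* SVs reported by both SV callers with matching type and breakpoints
  within ±10 bp (SV callers rarely agree to the base), no longer than
  10 kb;
* only variants with supporting-read depth ≥ 2 in at least one caller.
  A 2x *total*-depth filter would be vacuous at 100x sequencing, so the
  threshold is applied to the variant-supporting depth.

Genotype fields are ignored for identity: callers disagree on genotype
encoding far more often than on the allele itself.  Control subtraction
removes any variant whose normalized key appears in a wild-type
consensus or in the consensus of a mutant edited at different targets,
exactly reproducing the two-stage background filtering of the WGS
workflow.

## Editing-site detection

Each surviving variant contributes a candidate window: its reference
footprint (substituted bases; deleted bases; the anchor base of an
insertion) plus 50 nt on each side, clipped at contig edges.  The 50 nt
flank follows the meta-analysis of published editing outcomes in
plants, in which deletions start up to 40 nt upstream and end up to
30 nt downstream of the cleavage site; it is configurable.  Windows are
scanned for every guide; the best hit per (variant, guide) pair is kept
(fewest mismatches, then bulge-free, then cut position nearest the
variant, then leftmost), labelled `on_target` when it overlaps the
guide's designed locus and `off_target` otherwise; variants with no
qualifying hit are `background`.  Both breakpoints of an SV record are
windowed, since nothing in the record says which end would carry the
editing signature.  A `repeat_flag` marks windows whose sequence occurs
more than once in the reference (exact match, either strand): a
mismatch-heavy hit inside repetitive sequence is likely not a bona fide
off-target site.  The flag is informational, never a filter.

## Digenome-style cleavage calling

In vitro digestion of naked genomic DNA by the Cas9 RNP leaves blunt
ends, which sequencing converts into reads whose 5' ends align
vertically on both strands at the cut.  The published workflow delegates
cleavage-site identification to earlier work without restating it, so
this package defines an explicit, fully parameterised test.  A cut
between positions *p* and *p+1* is called when

* at least `min_reads` (default 5) forward-read starts cluster at
  *p+1*, and at least `min_reads` reverse-read ends cluster at *p*,
  each summed over a ±`window` (default 1) stagger slack; and
* the clustered starts make up at least `min_start_fraction` (default
  0.2) of the local depth, defined as the reads overlapping the
  two-base window `[p, p+2)` -- a definition under which the fraction
  cannot exceed 1.

Runs of nearby candidates are reduced to the local maximum, ranked
first by the un-slacked two-strand signal so that background reads
cannot displace the call from the true cut.  Called sites are then
filtered against the guides with the same matcher used genome-wide (≤6
mismatches or one clean bulge), and a per-guide mismatch histogram is
reported.  Secondary, supplementary, duplicate and unmapped alignments
are excluded; soft-clipped bases never count toward a read start.  A
plain TSV alignment table (`contig`, `strand`, `start`, `end`) is
accepted alongside SAM/BAM so the stage can be exercised without binary
alignment files.

## Amplicon quantification

Reads are aligned to the amplicon reference with a banded global
aligner with affine gap penalties (match +2, mismatch −4, gap open −10,
gap extend −1, band = length difference + 30) written for this package
in C++; equal-length reads within a small Hamming distance of the
reference are classified substitution-only without the DP, which under
this scoring cannot be beaten by a gapped alignment.  A read is mutant
when an indel in its alignment overlaps the counting window
`cut ± count_flank` (default 10 nt -- wide enough for the indel hotspot
around the cut, narrow enough to exclude amplicon-end artifacts).
Following the deep-sequencing workflow this reproduces:

* editing efficiency = mutant reads / total reads, where the total
  counts only reads spanning the counting window (edits on non-spanning
  reads are unobservable and must not deflate the ratio);
* a distinct indel signature supported by fewer than 2 reads is not
  counted (the "at least 2x depth" rule, applied per distinct allele;
  per-site application is available by lowering the threshold);
* signatures below 1 per mille of total reads stay in the mutant count
  but are dropped from the reported spectrum, mirroring the bona fide
  mutation threshold used to separate real low-frequency edits from
  sequencing error;
* substitution-only reads are never mutant by default (the source
  workflow counts reads containing indels); `include_substitutions`
  exists as an opt-in.

Mutation records are reported in PAM-relative coordinates: −1 is the
base immediately 5' of the PAM, there is no 0, and the blunt cut falls
between −4 and −3, where an insertion is anchored at −3.
`summarize_mutation_profile()` bins records into the four standard
histograms (indel size as `1D`, `2D`, ..., `1I`, ...; insertion
positions; deletion starts; deletion ends).

## Synthetic data

The generators in this package define the conditions under which every
stage is tested:

* `make_reference()` draws i.i.d. bases with a GC dial (default 0.36,
  approximating *Arabidopsis thaliana*); it has no repeat structure, so
  repeat-flag behaviour is exercised with explicitly duplicated
  sequence.
* `implant_guide_sites()` writes sites of exact requested geometry
  (mismatch count, bulge type, strand) into the reference, then
  re-scans the whole genome and re-randomizes any accidental extra site
  within the requested mismatch radius, so the truth table is provably
  complete.  Bulges are implanted mid-protospacer, where their geometry
  is unambiguous.
* `simulate_caller_vcfs()` emits truth variants per caller at a given
  sensitivity with Poisson depth (mean 100x, matching the mutant
  sequencing depth of the reproduced study) and binomial allele
  sampling, adds caller-private background calls, and randomly
  right-shifts indel representations to exercise normalization.
* `simulate_amplicon_reads()` draws mutant reads Bernoulli(efficiency),
  assigns signatures multinomially, and applies per-base substitution
  noise at 0.001 -- a typical Illumina error floor.  The default
  signature mix (50% 1-nt deletion at the cut, 30% 1-nt insertion, 20%
  3-nt deletion) reflects the observed dominance of single-nucleotide
  indels at plant editing sites.
* `simulate_digenome_readstarts()` overlays exact blunt-cut read stacks
  (defaults f = r = 10 over 20x background, read length 150) on uniform
  background alignments.

All generators are seeded and byte-reproducible, and leave the caller's
RNG state untouched.  What they do **not** emulate: sequencing-quality
error profiles, repeat and transposon structure, somaclonal variation
from tissue culture, T-DNA integration, or alignment artifacts.
Passing tests therefore demonstrate the correctness of the algorithms
under their stated models, not performance on real libraries -- on real
data, caller sensitivity below 1 and alignment noise will dominate.

## Problem sizes and numerical choices

The test suite and the acceptance script run at deliberately desk-scale
sizes chosen to exercise every code path with comfortable margins: a
3 × 100 kb fixture genome with four implanted sites for the end-to-end
pipeline, 200 random sequences (0.3--5 kb) for oracle equivalence over
the full parameter grid, 10,000-read amplicon libraries across
efficiencies 0.05--0.95, and 20 + 20 digenome replicates at 20x
background.  At n = 10,000 the binomial standard error of an efficiency
estimate is at most 0.005, so the ±0.02 recovery tolerance sits at
about 4 standard errors.  Ties in the aligner's traceback prefer gap
extension and deterministic state order, so signature strings are
stable; indels in homopolymers are reported at their leftmost
placement, consistent with VCF left-alignment.

## Limitations

* The cleavage-site score is a two-strand threshold test, not a
  likelihood model; it reproduces the qualitative Digenome-seq
  signature but not any particular published scoring formula.
* The matcher enumerates at most one bulge and does not compute
  biophysical off-target scores (CFD/MIT).
* Amplicon alignment assumes reads covering the full counting window
  (merged or single-end reads); there is no UMI or chimera handling.
* The consensus treats caller identity as given and does not model
  genotype likelihoods.
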