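---
title: "Detecting polyadenylated HS2/HS3 satellite transcripts in unstranded RNA-seq"
author: "satseeker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting polyadenylated HS2/HS3 satellite transcripts in unstranded RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Human satellites 2 and 3 (HS2/HS3) are pericentromeric tandem repeats built
on the ATTCC pentamer: HS3 keeps a strict 5-bp periodicity with a
characteristic CAACCCGAGT decanucleotide (and, in the 1qh subfamily, the
GATGAT hexamer); HS2 is built from related 23- and 26-bp units. Their
transcripts appear in maturing oocytes, but the pericentromeric regions are
unassembled in the reference genome, so reference-based quantification does
not apply. The practical route is reference-free: assemble contigs de novo,
select candidates by homology with a satellite oligonucleotide probe
(DYZ1, a 48-mer of ATTCC repeats), confirm the candidates are genuine RNAs
(polyadenylated) rather than genomic DNA contamination, collapse redundant
candidates into cluster consensuses, and quantify those against each
sample's reads.

`satseeker` implements every step downstream of assembly, plus a synthetic
data generator with known ground truth so that each stage's operating
characteristics can be measured. Two properties of the data shape most of
the design:

* **Libraries are unstranded.** A read may represent the molecule or its
  reverse complement, so HS2/HS3 sequence appears interchangeably with an
  ATTCC or a GGAAT pattern. Every matching step in the package is therefore
  strand symmetric: half-probe words carry their reverse complements, reads
  anchor on both strands, the k-mer index is canonical, clustering admits
  members in reverse orientation, and per-sequence strand calls
  (`strand_call()`) are reported rather than assumed.
* **Targets are periodic.** Tandem repeats break the implicit uniqueness
  assumptions of standard mappers and pseudoaligners; the deviations that
  this forces are detailed below.

## Pipeline stages and their parameters

| Stage | Function | Key parameters (default, units) |
|---|---|---|
| Tail trimming | `trim_polya()` | `min_tail` (10 bp), `max_mismatch_frac` (0.1), drop floor (20 bp) |
| Candidate screen | `screen_probe()` | probe (DYZ1), `frac` (0.5 of probe length) |
| PolyA verification | `verify_polya()` | `min_reads` (2), `min_tail` (10 bp), `tail_purity` (0.9), seed `k` (15) |
| Clustering | `greedy_cluster()` | identity threshold `T` (0.90), first-hit assignment |
| Consensus | `build_consensus()` | center-star, majority columns |
| Quantification | `quantify_sample()` | `k` (21), EM `tol` (1e-8), `max_iter` (1000) |
| Annotation | `annotate_repeats()` | window (50 bp), density floor (0.5), `min_block` (100 bp) |
| qPCR arithmetic | `delta_delta_ct()` | significance threshold p < 0.01; stability delta (3 cycles) |

The half-probe rule — a transcript passes if it contains an exact match to
any contiguous probe substring of length `ceiling(frac * probe_length)`
(24 bp for DYZ1), on either strand — replaces a BLAST E-value screen with a
deterministic criterion. Whether the original short-sequence BLAST screen
tolerated mismatches inside the half-probe span is not documented; the
exact-match reading is used here, and it is the stricter one. One
consequence worth knowing: of the four published oocyte satellite cDNAs
bundled as `published_transcripts()`, the three from the GV/MII donor panel
pass, while the highly diverged GATGAT-carrying transcript does not — its
longest exact run shared with DYZ1 is 9 bp. A mismatch-tolerant screen is
what originally admitted it.

### Alignment identity

`global_identity()` is matches over alignment columns of a global
Needleman–Wunsch alignment scored match +1, mismatch −1, gap −1. Published
">75% homology" statements about these transcripts name no scoring scheme,
so this scheme is a package convention. Ties are resolved by maximizing, in order,
score, then matches, then fewest columns — implemented as a lexicographic
dynamic program, which makes the identity value well defined rather than an
accident of traceback order.

### Tail detection semantics

A tail is the longest terminal run (3' of A, or 5' of T — unstranded cDNA
presents both) that begins with the tail base, ends at the sequence end,
and contains at most `max_mismatch_frac` non-tail bases. Requiring the run
to open on the tail base stops a tolerated mismatch from annexing adjacent
non-tail sequence. A single removal can expose a shorter terminal run, so
`trim_polya()` iterates until no run remains; that is what makes trimming
idempotent. Exact-run behaviour (`max_mismatch_frac = 0`) reproduces
run-length counts on printed sequences, e.g. the 15-bp polyT leader of the
published SRR5295893 cDNA.

### PolyA verification on periodic targets

Assembly and trimming both strip tails, so polyadenylation is verified by
re-anchoring the *untrimmed* reads: a read supports a tail when its
anchoring overhangs a transcript end with a ≥ 10 bp, ≥ 90%-A run (T for
the 5' end). Anchoring is ungapped seed-and-extend over exact shared
15-mers, and the candidate placements are scored match +1 / mismatch −1
over the overlap with overhangs free — soft-clip semantics. A plain
matching-base count fails here: on a 5-bp-periodic target, the spurious
placement one repeat period upstream buries the tail inside the body and
collects chance A-matches, while the true placement's overhang earns
nothing, so tailed reads systematically mis-anchor. Penalizing overlap
mismatches restores the intended behaviour. Ties go to the leftmost
placement, then the plus strand, keeping results deterministic on
repetitive targets. `min_reads = 2` means one chimeric read can never
confer polyA status.

The expected number of supporting reads is roughly
`coverage / read_length * (tail_length - min_tail + 1)`; at the hardest
corner (20 bp tail, 20x coverage, 100 bp reads) that is only ~2.2 reads,
so sensitivity there is intrinsically limited. Over tails of 20–60 bp and
coverages of 20–60x the measured sensitivity is ≥ 97% with specificity at
100% (fixed seeds; `tests/testthat/test-acceptance.R`).

### Clustering and consensus

`greedy_cluster()` reproduces the greedy centroid semantics of the
classical UCLUST algorithm: sequences sorted by length descending (ties by
id), each joining the first centroid reached at identity ≥ T, else founding
a new cluster; a `best_hit` flag switches to best-scoring assignment. The
identity threshold is not documented in the source analysis; 0.90 is the
package default and a required, logged parameter. Because sorting is
internal, input order cannot change the result. Each sequence is also
tried as its reverse complement and joins in whichever orientation clears
the threshold, so mixed-orientation assemblies cluster correctly.

`build_consensus()` merges the centroid-vs-member pairwise alignments
("once a gap, always a gap") into a center-star alignment and takes
per-column majorities: a strict gap majority drops the column, base ties
break A < C < G < T. On eight members at 3% divergence from a master, the
consensus recovers the master at ≥ 99% identity.

### Quantification

Quantification re-implements equivalence-class EM abundance estimation.
The index maps each canonical 21-mer (minimum of the word and its reverse
complement — unstranded data again) to the set of targets containing it. A
read's compatible target set is the intersection of its present k-mers'
target sets, absent k-mers skipped; reads with identical sets pool into
equivalence classes, and the EM iterates

    alpha_i <- sum_e c_e * (alpha_i / l_i) / sum_{j in e} (alpha_j / l_j)

with effective length `l_i = max(1, length_i - k + 1)`, uniform
initialization, and counts conserved at every iteration.
`tpm_i = 1e6 (c_i/l_i) / sum_j (c_j/l_j)`.

One satellite-specific failure mode required a documented refinement. In
pentamer-periodic sequence the space of single-substitution 21-mer
variants is tiny (5 phases x 21 positions x 3 bases), and every target's
diverged sites populate it; a sequencing error therefore routinely creates
a k-mer that is *present* in the index but absent from the source target,
emptying the strict intersection and discarding the read. Because this
loss hits satellite targets and spares unique-sequence targets, it
distorts TPM substantially at a 1% error rate. The package therefore
rescues a read whose strict intersection is empty by assigning it to the
targets within one error footprint (k k-mers) of the maximal per-target
support. When the strict intersection is non-empty the rule is provably
identical to it (a support count equal to the number of present k-mers is
membership in every set), so clean reads behave exactly as the textbook
algorithm prescribes.

The simulator draws per-target read counts from a multinomial proportional
to true TPM times the same effective length the EM uses, making recovery a
well-posed inversion; read starts are uniform. On a panel of 5 satellite
transcripts and 3 decoys with 50,000 reads at 1% error, every target's
estimated TPM lands within 5% of truth (measured ~2%).

Donor comparisons (`compare_donors()`) are within-donor only: summed
satellite TPM in MII is expressed as a percentage of the GV value
(GV = 100%), donors from different publications are never pooled, the
ACTB-like positive control's coefficient of variation is reported, and a
negative control (a gene not expressed in oocytes) is flagged if its TPM
rises above a floor.

## The synthetic generator: what it emulates, and what it does not

`sim_config()` / `simulate_transcriptome()` / `make_donor_panel()` emulate:
HS3-like arrays (strict pentamer periodicity, decanucleotide every 20
pentamers by default), a GATGAT-bearing HS3 variant, HS2-like 23/26-bp
unit structure, polyadenylated transcripts of 300–640 bp with 20–60 bp
tails, unstranded single-end reads (uniform starts, 1% substitution
errors, 50% strand flips), background mRNA decoys, a deterministic
ACTB-like stable control, and paired GV/MII donor read sets whose
satellite abundance ratio is known per donor (the default design: seven
donors up, three down).

The per-base repeat-unit divergence default (0.18) is calibrated against
the four published transcript cDNAs: their global identity to a pure
(ATTCC)n backbone is 0.71–0.85 and distinct transcripts share essentially
no exact 21-mers, a structure the generator reproduces at 0.18 but not at,
say, 0.03 (which yields arrays sharing more than half their 21-mers —
far more repetitive than anything in the published table). The divergence
of real genomic arrays is not documented; treat the default as a modelling
choice, not biology.

Not emulated: indel sequencing errors, quality-score error models, GC bias
(satellite GC content is known to complicate sequencing, but no usable
model is published), paired-end structure, and de novo assembly itself —
the pipeline consumes contigs (in test mode, the generator's ground-truth
arrays). Passing tests therefore demonstrate correctness of the stages
*given* an assembly, under substitution-only noise; they cannot speak to
assembler behaviour on real satellite reads, which is known to drop
repetitive fragments.

## Numerical and degenerate-input conventions

All coordinates are 0-based half-open. Lowercase input is uppercased and U
maps to T on read; duplicate FASTA ids are kept with a warning. Empty
sequences are rejected at construction. `tpm()` of an all-zero count
vector is all zeros, not an error. EM non-convergence at `max_iter` warns
and returns the last iterate. Effective lengths are floored at 1 so short
references never divide by zero. Overlapping motif occurrences are
counted; a palindromic motif is not double-counted on the two strands.
Block segmentation merges qualifying windows before applying the minimum
block length, so block boundaries are resolved to within one window.
Every stochastic routine takes its seed from configuration; re-running a
pipeline configuration is bit-identical in all tabular outputs.

## Problem sizes in the test suite

The suite simulates its data at desk scale: 50,000 reads for the EM
recovery panel, a 10-donor panel at 4,000 reads per sample, 200 positive /
100 negative transcripts for the verification grid, and 1,000 random
transcripts for the screen-vs-oracle comparison. These sizes keep the full
suite under a few minutes while leaving the measured quantities' sampling
error well inside the asserted tolerances.

## Known limitations

* The exact-match half-probe screen is stricter than a mismatch-tolerant
  BLAST screen and can reject strongly diverged satellite transcripts (see
  above); `frac` can be lowered, but a scored screen is out of scope.
* Family annotation stops at "HS2/HS3-like": finer subfamily calls require
  a curated repeat library that cannot be redistributed.
* Absolute TPM of satellite targets remains approximate when targets share
  long verbatim regions (the equivalence-class EM shares such reads by
  abundance over effective length only); within-donor *ratios*, the
  quantity the donor comparison reports, are robust to this.
* qPCR fold changes assume perfect amplification efficiency; no standard
  curves or melting analysis are modelled.
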