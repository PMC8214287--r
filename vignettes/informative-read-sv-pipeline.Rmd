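---
title: "Informative-read selection and call-set merging for long-read SV detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Informative-read selection and call-set merging for long-read SV detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrsv)
library(dplyr)
```

## The problem and the design

Structural variants (SVs) — deletions, insertions, inversions, duplications,
and translocations of at least 50 bp — leave characteristic footprints in
long-read alignments, most importantly *split reads*: reads whose alignment
is divided across a primary and one or more supplementary records, typically
spanning an SV breakpoint. Aligners differ sharply here. A fast
minimizer-chaining aligner maps whole genomes quickly but splits reads less
readily (and sometimes wrongly, especially across translocations); a slower
SV-aware aligner splits the breakpoint-spanning reads that SV callers need.
Only a tiny fraction of reads — well under 1% — is split by the accurate
aligner at all, so almost all of its running time is spent on reads that
contribute nothing to SV detection.

The pipeline this package implements exploits that asymmetry in six stages:

1. align **all** reads with the fast aligner;
2. extract per-read features from those alignments and classify each read as
   *informative* (would be split by the accurate aligner) or not;
3. re-align only the selected subset — classifier positives plus the reads
   the fast aligner itself split — with the accurate aligner;
4. harmonize the two aligners' SAM tag dialects and merge the streams into
   one BAM;
5. call SVs with two complementary callers on the merged alignments;
6. remove the redundancy the earlier unions created: count *unique*
   supporting reads per call, drop calls below a minimum support, and unify
   same-type calls the two callers reported at nearly the same breakpoints.

Stages 1, 3 (the alignment itself), and 5 are external tools reached through
thin adapters; stages 2, 4, 6 and the selection step of 3 are the bespoke
stages this package implements and tests. The pipeline runner degrades to a
*bespoke-only* mode that consumes pre-computed SAM and VCF inputs, so the
implemented stages run end-to-end with no external binaries.

## The per-read feature vector

Each read is summarized by a fixed, ordered 21-slot vector (schema
`"lrsv-1"`), computed from its **primary** alignment record only —
supplementary and secondary records determine splitness, not features, so the
classifier always sees one fixed-width vector per read:

* five aligner tag scores: `s1` (chaining score), `s2` (best secondary chain
  score), `cm` (minimizers on the chain), `NM` (mismatches plus gaps), `AS`
  (alignment score). Tags the aligner did not emit default to 0 — the network
  needs dense input — and `NM` falls back to `ins + del + mismatch`;
* total inserted, deleted, and mismatched bases. Insertions and deletions
  come from the CIGAR; mismatch *positions* come from `=`/`X` CIGAR ops when
  present, else from walking the MD tag. When neither is available, the
  mismatch total is recovered as `max(0, NM − ins − del)` and positional
  mismatch features degrade to 0;
* the longest run of each edit kind, in bases, both strict and with runs
  joined across exactly one matched base (the bridging match contributes 0).
  Runs are measured in bases rather than operation counts because base counts
  scale with the footprint of the variant that caused them;
* soft-clip lengths at the two read ends (hard clips are ignored);
* the four largest per-bin edit totals after cutting the read into 100-bp
  bins over **read** coordinates. Binning is over read coordinates because a
  deletion consumes no read bases; its full length is charged to the bin of
  the read offset where it occurs. Insertions, deletions, and mismatches are
  pooled into one total per bin; a per-kind variant (12 values) was
  considered and rejected to keep the schema small, since the run features
  already separate the kinds;
* the read length.

Every feature is location-independent: permuting unrelated tags or changing
the mapping position or reference name never changes the vector, so a model
trained on variants injected at particular loci cannot overfit to those loci.
The test suite enforces this, and checks all positional features against an
independent per-base brute-force walk of each alignment.

## The classifier

The network architecture is fixed: five fully-connected tanh hidden layers of
18, 30, 18, 11, and 5 units and one sigmoid output. Training labels come
from paired aligner outputs: a read not split by the fast aligner but split
by the accurate one is labelled 1, a read split by neither 0, and reads split
by the fast aligner are excluded — they are forwarded to the accurate aligner
unconditionally, so the classifier never has to decide them.

The fitting procedure is the package's own choice (the architecture is given,
the optimization is not):

* **loss**: binary cross-entropy with inverse-frequency class weights,
  because positives are on the order of 1% of reads and unweighted training
  collapses to the majority class;
* **standardization**: features are z-scored with means and SDs stored in the
  model (constant features get SD 1). Raw base counts reach the thousands and
  saturate tanh units immediately without scaling;
* **optimizer**: full-batch Adam (step size 0.01), up to 400 epochs, early
  stopping on a stratified 15% validation split with patience 30, restoring
  the best weights;
* **initialization**: seeded symmetric uniform scaled by fan-in
  (`±1/sqrt(n_in)`), so training is bit-reproducible given the seed;
* **decision threshold**: 0.5 by default, configurable; a probability exactly
  at the threshold classifies as informative. The asymmetry is deliberate: a
  missed informative read costs SV sensitivity, a false positive only costs
  accurate-aligner time.

Models serialize to versioned JSON (layer dimensions, row-major weight
arrays, normalization vectors, threshold) at 17 significant digits, so a
reloaded model reproduces forward outputs bit-for-bit; a version or feature
schema mismatch is refused, not guessed around.

## Alignment unification

The two aligners emit different optional tags, and mixing their records in
one SAM breaks SAM-to-BAM conversion. The paper-level requirement is only
that the vocabularies agree before merging; which tags to keep is this
package's choice: an allow-list of `NM`, `AS`, `SA`, `MD` — standard tags both
SV callers can use — with every source-specific tag dropped and an `sr:Z:`
provenance tag added. Merging requires identical `@SQ` (name, length) pairs,
concatenates `@PG` chains, and never drops or deduplicates records: a read
aligned by both aligners is intentionally present twice, because the
downstream unique-support count — not the merge — is where that redundancy is
resolved.

## Call-set post-processing

* **Unique support.** After the alignment merge, one physical read can
  support an SV once per aligner, and a caller counting alignments would
  count it twice. The filterable quantity is therefore the number of
  *distinct* supporting read names; calls carrying only a count (no names)
  fall back to the count.
* **Minimum support.** The default threshold is half the sequencing
  coverage — 5 reads at 10× — on the reasoning that a real variant should be
  supported by about half the average depth. Odd coverages round **up**
  (`ceiling(coverage/2)`), the conservative direction against false
  positives.
* **Cross-caller merging.** Two calls of the same type on the same
  chromosome(s) whose breakpoints differ by strictly less than 50 bp are the
  same event; the member with more unique supporting reads is kept. Both
  coordinates (`pos` and `end`; both breakpoints for translocations) must sit
  inside the window — comparing only the start position would merge nested or
  overlapping distinct events. Matching is greedy by descending support with
  deterministic tie-breaks (named support before count-only, then caller id,
  then position), and each call participates in at most one unification.
  Greedy matching mirrors common SV-merging practice; an optimal bipartite
  matching could differ on adversarial inputs but not on the well-separated
  events the generator (or a genome) produces.
* **Scoring.** A call is correct when an unmatched truth record of the same
  type lies strictly within 10 bp of its breakpoint(s). Recall is TP/|truth|;
  FDR is FP/|calls|, defined as 0 when there are no calls at all (an empty
  call set makes no false discoveries).

Strict inequalities at both windows (50 bp, 10 bp) follow the stated rules
("less than"); the boundary tests pin them. One consequence: a breakpoint
jittered by exactly the tolerance does not match, so the synthetic caller
pairs used in the noiseless-recovery tests draw jitter up to 9 bp, keeping
every intended match strictly inside the 10 bp tolerance.

## What the synthetic data emulates — and what it does not

The generator exists so every bespoke stage has inputs with known answers:

* **References** are i.i.d. sequences with a target GC fraction, 100 kb by
  default (two 50 kb contigs when translocations are requested, which
  require two contigs; a single-contig request with translocations is
  rejected). Desk scale — 100 kb, SV lengths 60–2000 bp, coverage around
  10× — preserves the statistical structure of the full-genome experiments
  (tens of megabases, SVs to 50 kb, up to 50×) while running in seconds.
* **SV injection** places non-overlapping events with a minimum gap
  (default 500 bp) and records exact 1-based breakpoints on the original
  coordinates, including the inserted sequence for insertions, so the altered
  reference is reconstructible from original + truth; the tests rebuild it
  byte-exactly by independent substring surgery.
* **Reads** get uniform starts, truncated-normal lengths (mean 8 kb, SD
  1.5 kb), and independent per-base substitution/insertion/deletion errors at
  5% each — a CLR-like ~15% total error. Reads are emitted until total bases
  reach coverage × genome length. Read names encode the true origin interval.
* **Alignment records** are generated directly — CIGAR, MD, NM, and read
  length mutually consistent by construction — under a *stated* generative
  rule: informative reads carry a soft-clip total above 200 bases or a
  deletion run above 40 bases (the alignment footprints of a missed
  breakpoint), drawn with a margin (clips 260–800 vs. a background of at most
  ~120; deletion runs 60–300 vs. background ops of at most 8 separated by at
  least 3 matches). Background reads carry only small scattered edits. The
  default informative fraction is 1%, echoing the rarity of accurate-aligner
  splits in real data.
* **Caller VCF pairs** are the truth set with per-caller breakpoint jitter,
  dropout, and Poisson support; the expected merged set is computed
  analytically from the construction.

What this does *not* model: real error profiles (homopolymer bias,
quality-score structure), chimeric reads, mapping ambiguity in repeats, or
the way a real aligner's soft-clips correlate with SV type. Passing tests
therefore demonstrate that the implemented stages are *correct against their
contracts* — not that the classifier's accuracy transfers to any particular
instrument or genome. On real data the separation between informative and
background reads is softer, and a model trained on simulation is known to
over-select reads (costing time, not sensitivity); retraining on labels
derived from a paired aligner run of the target data is the intended remedy,
and `label_reads()` exists for exactly that.

## Numerical and degenerate-input conventions

* All generators are pure functions of their seeds (`withr::with_seed`);
  pipeline reruns on fixed inputs produce byte-identical final VCFs.
* An unmapped record yields an all-zero feature block with a warning rather
  than an error; an MD tag inconsistent with its CIGAR is a hard format
  error.
* Constant features standardize with SD 1; model serialization uses 17
  significant digits (exact double round-trip).
* `merge_calls` and `match_to_truth` are deterministic under the documented
  tie-breaks; `filter_min_support` is idempotent and monotone.
* Problem sizes used by the test suite: 1000 records for the
  feature-extraction oracle check; 5000 training and 5000 held-out reads at
  1% prevalence for classifier recovery (recall ≥ 0.95, precision ≥ 0.90);
  100–200 kb references with 8–17 injected SVs for the merge and round-trip
  checks; 300-read fixtures for the end-to-end dry run.

## Known limitations

* Breakend (BND) handling pairs reciprocal mates into one translocation call
  and passes unpaired breakends through as single-ended calls; complex
  breakend graphs are out of scope.
* The external-tool adapters pin reasonable argument templates (SAM + MD tags
  from the fast aligner, read-name reporting from the callers) but caller
  INFO dialects vary by version; the supporting-read INFO key is configurable
  in `parse_sv_vcf()`.
* No genotyping or re-genotyping of merged calls; quality fields pass
  through opaquely.
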