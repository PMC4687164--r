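---
title: "Auditing a finished bacterial genome with short-read resequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing a finished bacterial genome with short-read resequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Finished ("closed") bacterial genomes assembled from single-molecule
long reads are occasionally wrong in a very specific way: long homopolymer
runs are under-called, so the deposited sequence is missing single bases
relative to the organism's true chromosome. Each missing base inside a gene
shifts the reading frame, and an automated annotation pipeline then reports
the locus as a pseudogene, a protein "containing multiple stop codons", or a
pair of adjacent CDS fragments where one gene belongs. Deep short-read
resequencing of the same strain exposes these sites: at an assembly error,
essentially every spanning read carries one extra base relative to the
reference, which is unlike a polymorphism and unlike sequencing noise.

`genaudit` implements this audit as a reusable pipeline: map reads (or
import SAM), build a pileup, call consensus discrepancies with indel
left-normalization, characterise their homopolymer context, apply the
corrections with annotation liftover, classify each correction's coding
consequence, cross-validate corrected alleles against a related genome, and
report per-CDS coverage breadth. A synthetic-data module generates a genome,
a corrupted assembly, reads and a truth table, so every stage is exercised
with no external data.

## Consensus discrepancy model

The audit targets assembly errors in a clonal isolate, not population
variants, so calling is consensus-level and deliberately simple:

* a site is called when one alternative allele is carried by at least
  `min_alt_fraction` (default 0.8) of the reads spanning it, at spanning
  depth at least `min_depth` (default 10);
* at most one call is made per site (highest fraction, ties to the
  lexicographically smallest allele);
* fractions at or below 0.5 are rejected outright — consensus semantics
  require a majority, and the defaults sit far above it because a clonal
  resequencing experiment at high depth leaves true assembly errors near
  fixation.

Insertions are counted against junction-spanning depth (the smaller of the
depths at the two columns flanking the insertion point). Every raw insertion
observation is left-normalized before aggregation, because reads entering a
homopolymer run at different offsets can report the same extra base at
different anchors.

### Left-normalization

An indel inside a repeat has many equivalent placements. We shift each indel
to its leftmost equivalent anchor: while the reference base at the anchor
equals the last base of the allele, the anchor moves left and the allele
rotates. The operation is idempotent and preserves the corrected sequence
exactly; the test suite checks both properties against an exhaustive
string-insertion oracle over a thousand random indels. Insertion positions
use the convention "0-based index of the column the insertion follows"
in memory and 1-based positions in every on-disk report.

## Mapper

The built-in mapper is a seed-and-extend aligner adequate for synthetic data
and small real datasets; external aligners can be substituted entirely via
SAM import, which feeds the identical pileup machinery (a property test
asserts the equivalence). Non-overlapping k-mers (k = 15) vote for candidate
loci; the read is then aligned end-to-end against a window padded by
`band` (16 bp) under unit edit costs in compiled code. Ties break to the
leftmost reference position, then the forward strand. Reads above the edit
cap (10% of read length) are unmapped; reads with equally good alignments at
distinct loci are discarded rather than arbitrarily placed, so repeats do
not inject false alleles. When clip rescue is enabled (used by the
large-INDEL screen), a read failing the cap keeps its best prefix or suffix
under a local-alignment-style score (aligned length minus four times the
edit cost), which anchors soft clips at structural-variant junctions instead
of letting alignments fray into foreign sequence.

## Homopolymer context and summaries

Run length is measured on the **uncorrected reference** (the sequence being
audited), since that is the object whose errors are being described: for an
insertion, the maximal run of the inserted base immediately following the
left-normalized anchor; for other types, the run containing the site. If
the inserted base matches neither neighbour the length is 1 by convention.
Summaries report both "runs longer than 4" (length at least 5) and "runs
longer than 5" (length at least 6) so either threshold reading of the
headline fractions can be checked; the two counters are deliberately
redundant. An alternative convention measures the run on the corrected
sequence, which differs by one for run-extending insertions; the choice here
is declared rather than inferable, and the reported histogram makes
translation between the two trivial.

## Corrections, liftover and coding impact

Corrections are spliced in one pass; the exact identity
`new length = old length + sum(len(alt) - len(ref))` is asserted on every
run. The coordinate map records (old position, offset) breakpoints, is
strictly monotonic outside deleted segments, and is invertible; features are
lifted through it so that an insertion strictly inside a feature grows it
while boundary-junction insertions leave it unchanged. Features with an
endpoint inside a deleted segment are lifted to the junction and flagged,
never dropped.

For each coding correction the corrected locus is re-scanned for open
reading frames (bacterial translation table 11; ATG/GTG/TTG starts) on the
annotated strand, and the chosen ORF is trimmed to the annotated start when
that start is in frame — the repaired gene keeps its annotated start; the
naive re-scan is not a gene finder. Classification precedence is:

1. `gene_merge` — the repaired ORF contains two or more old same-strand CDS
   intervals (at least 90% of each); the canonical case is a 1-bp insertion
   rejoining a frameshift-split gene, e.g. fragments of 280 and 433 amino
   acids merging into a single 722-aa product;
2. `stop_removed` — the old annotated frame carried an internal stop that
   the corrected frame lacks;
3. `frameshift_repair` — a single-CDS locus restored to one ORF, within 5%
   of the expected ortholog length when one is supplied (related-genome
   orthologs legitimately differ by a few residues, e.g. 717 vs 722 aa);
4. substitutions classify as `synonymous`/`missense`; everything outside
   CDS is `intergenic`.

Annotation transfer uses the combined identity score: identity fraction
(matches over aligned reference length) times coverage fraction (aligned
reference length over full reference length), accepted at 0.25 — i.e. 50%
identity over 50% of the gene. Alignment significance is proxied by a raw
score threshold (match +2, mismatch −1, gap open 5, gap extend 2, minimum
15); full extreme-value e-value calibration is out of scope and the proxy is
declared openly.

## Cross-validation

For every discrepancy, windows of ±250 bp (the framing a confirmatory
amplicon would use) are extracted under the reference and corrected alleles
and aligned locally (both strands) against the homologous region of a
related genome located by k-mer seeding. The region is `not_found` below
70% identity or 50% window coverage; otherwise the verdict goes to the
strictly higher-scoring window, with equal scores yielding `neither` —
determinism over optimism. At protein level, the corrected product is
globally aligned to the related product and reported as `m/n`: `m`
identically aligned residues over `n` columns, where `n` spans the full
corrected product (a truncated related protein lowers `m`, not `n`; only
overhangs of the related protein are excluded). These conventions make the
strand-symmetry and partition invariants exact: verdict counts always sum to
the number of discrepancies.

## The synthetic-data generator

The generator emulates the statistical structure the audit assumes, with
defaults fixed as the package's study conditions:

* **Genome**: 200 kb (scalable 0.1–5 Mb), GC 0.31, sampled from a
  stationary Markov chain with stay probability `homopolymer_bias = 0.15`.
  The bias leaves base composition (hence GC) unchanged but lengthens the
  run-length spectrum the way AT-rich genomes do; without it, runs of 9+
  bases would be too rare at desk scale to plant errors in. Realized GC
  stays within ±2 points of target (binomial concentration; tested).
* **CDSs**: 60 planted non-overlapping ORFs of 100–400 aa, start codon plus
  stop-free sense codons weighted by the GC target so coding regions do not
  distort composition. This gives a modest coding density (~20%); real
  bacterial chromosomes are denser (~85%), so the generator's coding
  fraction of discrepancies is intentionally not calibrated to any
  real-data figure — passing tests demonstrate mechanism, not ecology.
* **Corruption**: `run_length_weights` is keyed by the run length
  *observed at the discrepancy site on the corrupted assembly* — the
  quantity the audit reports — with default mass 4–8 concentrated at 6–8.
  Planting a class-w error deletes one base from a true run of length w+1.
  Selection is without replacement within class; exhaustion raises a config
  error listing availability. On linear simulations, runs within
  `end_margin` (default `mean_insert`) of the termini are ineligible,
  because linear read sampling ramps coverage down there — a property of
  the simulated library, not of the caller.
* **Reads**: 2 × 250 bp, FR orientation, insert 600 ± 60 bp, 200× expected
  coverage, substitution-only errors at 0.002 with quality strings encoding
  that rate. Read indel errors are excluded by default to keep the
  consensus caller's null clean; they can be enabled for robustness
  experiments by raising `per_base_error` and extending the error model.
  Fragments wrap on circular genomes.
* **Seeding**: one integer seed; stages draw from derived streams
  (genome seed+1, corruption seed+2, reads seed+3) so running stages
  independently or in sequence reproduces identical data.
* **Annotation of the corrupted assembly**: features containing a planted
  deletion are re-fragmented into the two pieces an ORF-based annotator
  would emit (the 5' piece up to the premature stop in the annotated frame,
  and a 3'-anchored piece opening at a start codon in the true frame). This
  is what makes split-gene merging observable end to end.

What the generator does **not** emulate: sequence-context-dependent error
rates, quality-score decay along reads, chimeric fragments, coverage bias
with GC, real codon usage, and operon structure. Conclusions from passing
tests are therefore about the algorithmic pipeline, not about any
instrument's error profile.

## Problem sizes and numerical choices

The test suite runs the full pipeline at 200 kb / 100 planted errors /
100× / per-base error 0.002 (about 80,000 reads), where recovery precision
and recall are both exactly 1.0, and at several smaller scales; the
acceptance script runs the same audit at the default 200×. The chi-square
goodness-of-fit of planted run-length counts uses n = 500 errors on a
1.5 Mb genome so every weight class has ample run availability. The
chromosome-scale length-conservation case uses a synthetic 4,352,205 bp
sequence receiving 242 single-base insertions, one single-base deletion and
one 181 bp insertion (net +422 → 4,352,627 bp). Degenerate inputs are
defined, not special-cased: empty discrepancy sets produce identity
corrections and all-zero summaries; empty read sets produce valid empty
FASTQ; zero-length windows cannot arise because flanks truncate at sequence
ends (or wrap on circular genomes).

## Known limitations

* The mapper is not performance-tuned for full-size bacterial datasets
  (megabase genome at 200×); SAM import from a production aligner is the
  recommended path for real data, and the two entry points are tested to
  give identical pileups.
* Insertion support uses flanking depth as the spanning denominator, a
  slight overestimate when many reads terminate exactly at the junction.
* The large-INDEL screen is a flagging heuristic (low-depth stretches and
  soft-clip clusters pooled over adjacent columns); it locates junctions to
  within a few bases but does not assemble the inserted sequence.
* Equal-score cross-validation verdicts are reported as `neither`; a
  likelihood-based arbiter could do better on diverged relatives.
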