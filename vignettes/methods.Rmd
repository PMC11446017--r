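---
title: "Joint benchmarking of phased variant calls: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint benchmarking of phased variant calls: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcfjoint)
```

## The evaluation model

`vcfjoint` treats variant benchmarking as a sequence problem, not a
record-matching problem. Given a reference contig R, a phased truth VCF
and a phased single-sample query VCF, the object being compared is the
*haplotype sequence*: the reference with one haplotype's variants
applied. Two sets of records are equivalent exactly when they produce
the same haplotype strings, regardless of how the edits are factored
into VCF records. Everything in the package follows from making that
definition computable at scale:

1. **Normalization** (`load_variants()`): multiallelic records are
   split per ALT (genotypes remapped per haplotype); symbolic alleles,
   breakends, spanning-deletion `*` alleles and missing genotypes are
   skipped and counted; alleles are trimmed to minimal form internally
   (trailing then leading shared bases) while original fields are kept
   for output. Half calls use the called haplotype, the other treated
   as reference, with a warning — the record still carries evaluable
   signal. Same-haplotype overlaps keep the earlier record; exact
   duplicates keep the first. The FILTER column is ignored by default
   (assembly-derived VCFs rarely use it meaningfully); `pass_only`
   restricts to PASS. Evaluation assumes a *phased* query: genotype
   separators are not distinguished, and `/` is treated as written.
2. **Clustering** (`reach_cluster()`): variants that could participate
   in one equivalence must be evaluated together. Each cluster carries
   an affine-gap alignment cost of its own representation, and a *reach*
   in each direction: the furthest reference position at which an
   alignment through the cluster can still place a scored difference
   without exceeding that cost. Clusters whose reaches overlap merge;
   merged costs are recalculated (they can only drop — two one-base
   deletions in one repeat run become a single two-base gap) and only
   merged clusters have reaches recomputed. Merging is greedy over runs
   of mutually overlapping reaches and iterates to a fixed point.
3. **Superclusters** (`build_superclusters()`): connected components of
   truth and query clusters under reach overlap, each evaluated
   independently over a window padded by `flank` bases.
4. **Joint evaluation** (`run_benchmark()`): per supercluster, the four
   haplotype strings are built and compared by unit-cost edit distance;
   the orientation (which query haplotype corresponds to which truth
   haplotype) minimizing the total distance is chosen, ties to the
   as-given pairing. Each haplotype pair is decomposed at sync points
   into groups; per group the credit is the fractional reduction in
   edit distance, and the TP/FP/FN decision is all-or-nothing at the
   credit threshold. A true-positive group spanning size categories
   contributes a TP to each member's own category — this is the
   mechanism by which joint evaluation outperforms per-size-class
   evaluation.
5. **Phasing** (`assign_phase_blocks()`, `phase_state()`,
   `count_switch_flip()`, `ngc50()`): described below.

Credit is deliberately defined through *unit-cost edit distance*, while
clustering uses affine-gap costs: credit asks "how much of the truth
signal did the query recover", for which every base counts equally;
reaches ask "where could this representation legally wander", for which
gap structure matters.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `credit_threshold` | 0.7 | fraction | minimum credit for TP; inclusive, so a 7-base call for a 10-base truth deletion (credit exactly 0.7) passes |
| `phasing_threshold` | 0.6 | fraction | minimum relative edit-distance reduction for a supercluster to count as phased; inclusive |
| `sv_threshold` | 50 | bases | INDEL/SV boundary; a 50-base deletion is an SV |
| `largest` | 5000 | bases | records with longer REF or ALT are dropped before evaluation |
| `max_eval_size` | off | bases | additional ceiling on variant length |
| `penalties` | 3/2/1 | cost units | mismatch / gap-open / gap-extend for cluster costs and reaches; results depend on this design-space point, so it is pinned in the config rather than hard-coded |
| `flank` | 8 | bases | supercluster window padding; unconstrained by the model, pinned for reproducibility |
| `cluster`, `gap_n` | biwfa / 10 | — / bases | reach-based clustering is the default; gap clustering is the cheap opt-in alternative |
| `max_cluster_span` | 10000 | bases | clusters growing beyond this are frozen with a warning; beyond ~10 kb the evaluation windows stop being meaningful local problems |
| `size_bins` | 1, 50, 500, 5000 | bases | stratified reporting edges, mirroring the SNP/INDEL/SV headline split |

## Numerical and tie-breaking choices

These choices close gaps the model itself leaves open; each is pinned by
a test.

* **Alignment tie order.** Backtracking prefers match/mismatch over a
  gap in the target over a gap in the query, and prefers extending a
  gap over opening one; backtracking from the end, this places gaps
  leftmost in repeats. Any fixed order would be defensible; having one
  makes FP/FN adjudication and sync boundaries deterministic.
* **Reach boundary condition.** "Aligning through a cluster to position
  r" is defined as: some end-to-end affine alignment of the cluster
  haplotype extended with reference bases up to r, against the extended
  reference window, whose *final operation is a scored difference*,
  costs no more than the cluster's representation cost. The
  difference-at-the-boundary condition is what makes a zero budget pin
  the reach to the span edge and keeps a lone SNP from reaching through
  unrelated matching sequence, while letting a deletion sweep a whole
  homopolymer. Candidate windows start at 8 bases and double until the
  feasible extension leaves the window edge. The implementation is a
  banded-free DP kernel; tests compare it against an independent
  per-extension brute force.
* **Sync points.** A reference position p splits a supercluster only if
  (a) p lies strictly inside no variant footprint of either source and
  (b) the vertex (t(p), q(p)) — where t, q are the *record-based*
  coordinate maps of the truth and query haplotypes — lies on the
  chosen optimal truth-vs-query alignment path. Condition (b) is what
  keeps a left-aligned truth indel and its right-aligned query
  counterpart in one group (their coordinate maps disagree between the
  two placements, so no sync point separates them), while still
  allowing a split after a *partial* match whose net length difference
  has been absorbed by the alignment. Group `ed_ref`/`ed_call` values
  are then recomputed per segment, so credit never depends on which
  optimal path was chosen.
* **Degenerate groups.** A group with query calls but no truth signal
  (`ed_ref = 0`) gets credit 0 (spurious calls); a query that makes the
  haplotype *worse* (`ed_call > ed_ref`) is clamped to credit 0; a
  group where truth variants cancel to the reference is credited 1
  exactly when the query also matches.
* **Genotype asymmetry.** No special rule: evaluating haplotypes
  separately yields the expected behaviour (truth het vs query hom:
  TP + TP + FP; truth hom vs query het: TP + FN + TP). Records whose
  per-haplotype decisions disagree are additionally counted as genotype
  mismatches.
* **Switch/flip decomposition.** Within a phase block, the orientation
  string of phased superclusters is decomposed by a DP minimizing
  (switches + flips) with ties toward fewer switches — so a lone
  terminal orientation change counts as a flip, not a switch. No error
  is charged for the initial orientation. Superclusters straddling a
  phase-block boundary have no well-defined orientation and are treated
  as unphased (and flagged). Verified against exhaustive enumeration
  over all strand assignments.
* **NGC50 breakpoints.** Switch errors break segments midway between
  the two adjacent phased superclusters; flip errors (for switchflip
  NGC50) at the flipped supercluster's midpoint. Positions within the
  block are not prescribed by the metric definition; midpoints are
  pinned. Because switchflip breakpoints are a superset of switch
  breakpoints, switchflip NGC50 ≤ switch NGC50 ≤ phase-block NG50 holds
  structurally.
* **Interval conventions.** All internal coordinates are 0-based
  half-open (VCF positions converted on read/write; BED used as-is). A
  record overlaps the BED mask if its reference footprint
  `[pos, pos + len(REF))` intersects any interval; a pure insertion uses
  its one-base anchor footprint. Touching reaches merge (clusters and
  superclusters use the same inclusive rule).

## What the simulator emulates — and what it does not

`make_diploid_genome()` builds references with embedded homopolymers
(10–16 bases) and short tandem repeats (unit 2–3, 4–7 copies), then
places SNPs (2/kb), INDELs (1.2/kb) and SV deletions/insertions
(0.4/kb, 60–160 bases) without same-haplotype overlap, ~30% homozygous,
with PS phase sets on heterozygous records. Indels falling in repeat
tracts are written right-aligned — legal, but not the canonical form an
aligner would emit. One large deletion per contig is laid out so that it
can be rewritten exactly as a 47 + 1 + 97-base decomposition plus one
SNP; the two reference-base equalities this requires are enforced when
the reference itself is built.

The three query modes produce *provably haplotype-identical* companions:
`identical` copies records; `decomposed` applies the 47/1/97 rewrite,
left-shifts repeat indels and merges close SNP pairs into complex
records; `realigned` re-emits every truth cluster from a fresh alignment
under an alternative penalty set. The generators verify string equality
of all haplotypes and fail loudly otherwise, so the evaluation-layer
invariants (zero FNR/FDR, zero switch/flip on these pairs) rest on an
asserted precondition, not on hope. `make_flip_trap()` constructs the
repeat case where a two-base deletion appears at the same POS/REF/ALT on
*opposite* haplotypes of truth and query with compensating neighbours:
exact-match phasing comparison reports a flip, alignment-aware
evaluation reports none.

The realigned mode's alternative penalties default to mismatch 2, gap
open 3, gap extend 2. A mismatch-dominant alternative set would rewrite
nearby SNP pairs as a deletion plus an insertion separated by matches —
an equivalence that is only visible *non-locally* and that no
reach-bounded clustering can bridge; representation divergence in this
simulator is therefore confined to the locally-bridgeable kinds (gap
placement in repeats, record merging), which is also the regime in which
the evaluation model's guarantees hold.

What the simulator does not model: sequencing errors and genuine caller
mistakes (tests that need errors construct them explicitly), population
samples, very long (>10 kb) SVs, nested/overlapping repeat structure of
real centromeres, and unphased or partially phased queries. Passing
tests on these fixtures therefore demonstrate correctness of the
*evaluation machinery* under controlled representation divergence — not
calibration of error rates on real data.

## Problem sizes

The shipped tests and the acceptance script run entirely on simulated
data at desk scale: 3 kb contigs with ~25 variants per truth/query pair,
100 fixture pairs for the representation-invariance property, 500
random sequence pairs (length ≤ 64/48) per alignment oracle, 200 reach
windows, and 1000 random orientation strings (length ≤ 12) against a
2^n exhaustive oracle. These sizes were chosen so each suite completes
in about a minute while still exercising every code path, including
repeat-mediated cluster merging and cross-size equivalences.

## Known limitations

* Multi-sample and unphased VCFs are out of scope; exactly one sample
  is evaluated and its phasing is taken as given.
* Symbolic SV alleles (`<DEL>`, `<INS>`, breakends) are skipped, not
  resolved; sequence-resolved calls are required.
* The credit model evaluates groups all-or-nothing; it reports no
  GA4GH-style genotype-error subcategories beyond the genotype-mismatch
  counter, and no QUAL-threshold ROC sweeps.
* Execution is sequential. The `threads` argument is accepted for
  interface compatibility and validated; results are identical for any
  value, which is the only contract the evaluation model needs.
* Representation equivalences that are not locally alignable within a
  cost-bounded reach (e.g. a SNP pair rewritten as distant
  deletion/insertion pairs) are not discovered; they appear as
  FP/FN pairs, which is the honest reading of calls whose equivalence
  cannot be established from the local sequence.
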