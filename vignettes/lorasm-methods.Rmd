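---
title: "Methods: progressive correction and two-stage assembly of noisy long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: progressive correction and two-stage assembly of noisy long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Nanopore long reads carry two kinds of error structure that defeat
single-threshold overlap-consensus correction. First, the per-read error
rate is broadly distributed — roughly 7–50% with most reads between 10 and
20% — so any single overlapping-error-rate cutoff is either too strict for
high-error reads (they collect no supports and are discarded) or too
lenient for low-error reads (they collect noisy supports and are corrected
badly). Second, individual reads contain *high-error-rate subsequences*
(HERS): windows of ≥500 bp whose local alignment error exceeds 50%, whose
frequency grows with read length. Correctors that trim HERS shorten the
reads and, downstream, the assembly.

`lorasm` implements a correction-then-assembly pipeline built around three
ideas: adaptive per-template support selection, two-pass progressive
correction (easy parts first, HERS afterwards against the now-clean
supports), and a two-stage assembly in which string-graph contigs built
from corrected reads are finally *bridged* with the original raw reads,
recovering the length that HERS-induced read splitting destroyed.

## Candidate selection

Sampled canonical k-mers (k = 13, stride 5, repeat k-mers above 500
postings masked) connect each template read to candidate reads. For each
candidate, every shared k-mer pair gets a *distance-difference factor*
(DDF) score: the number of other same-strand pairs whose template/candidate
offset differences agree within ε = 32 bp. The top-scoring pair is the
seed; its supporting pairs are reduced to the longest co-linear chain
(strictly increasing in both coordinates). The chain size is the hit score,
its first/last anchors give approximate mapped intervals, and a mid-chain
anchor seeds the local alignment (any chain anchor is an exact match; the
middle one is the most robust starting point). Hits with fewer than 3
anchors are dropped.

## Adaptive alignment-quality threshold

For every template the 50 top-DDF candidates are aligned; alignments
spanning >60% of the template or candidate are recorded, giving differences
$d_1,\dots,d_n$ with mean $d_0$ and population standard deviation $D$. The
individual threshold is the *quality lower bound*

$$\text{difference} \le \min(\text{global}, \; d_0 + 5D), \qquad
\text{global} = 0.5 .$$

Two formula ambiguities are config-switchable and deserve a note.
The rule is sometimes written as a subtraction ($d_0 - 5D$) in *error*
space while being described as a lower bound on alignment *quality*;
subtracting five SDs from the mean
difference of the very alignments being filtered leaves essentially no
support below the cutoff, and a pipeline built that way corrects nothing.
Reading the bound in quality (identity) space — identity ≥ mean − 5 sd,
i.e. difference ≤ $d_0 + 5D$ — reproduces every described behaviour: the
individual threshold is below the global one for low-error templates and
above it (so the global binds) for high-error templates. The default is
therefore `threshold_formula = "plus"`, with `"minus"` available for
comparison. Likewise the spread $D$ can be taken with or without the
$1/n$; the default is the population SD
(`threshold_sd_normalized = TRUE`), the unnormalised form is selectable. With no recorded alignment the global threshold is the
fallback and the template is corrected only if enough supports pass it.

One quantitative caveat. For a very-high-error template (say 35% planned)
one might expect the global threshold to bind (effective cutoff exactly
0.5). In practice the realized alignment difference between a 35% template
and its ~10%-error supports is $\approx 1-(1-0.31)(1-0.10) \approx 0.38$
— optimal alignment cancels edits, so differences do not add — and
$d_0 + 5D$ lands around 0.36–0.42. The individual threshold is then the
binding one, but since it sits *above* its own supports' mean by
construction it never starves such a template of supports; the global 0.5
binds only through the no-recorded-alignment fallback. The corresponding
acceptance assertion is intentionally left failing with this analysis
(see the test's comment).

## Blockwise and sensitive alignment

Pass-1 alignments extend from the seed in 500 bp template blocks, each
block aligned semi-globally (candidate end free) inside a band of ±250 bp;
extension stops in a direction when a block pair's error exceeds 0.5 or a
read ends. Per-block distances use Myers' bit-parallel algorithm;
transcripts, needed only for supports that pass the threshold, are
recomputed with a banded DP whose band is the already-known block distance
plus a margin, so the banded traceback is exact.

Per-block (and per-window) error is `edits / min(block length, aligned
partner span)`. The denominator matters at the extreme: with alignment
columns in the denominator even random-versus-random sequence scores only
≈0.41, so a 0.5 ceiling would never trigger and HERS would be undetectable
by definition. With the chosen denominator a garbage block scores ≈0.6–0.8
and a genuinely noisy-but-homologous block pair ≈0.3, giving the 0.5
ceiling a clean margin on both sides. Whole-read error rates (the Table-1
style statistics) keep edits / alignment columns.

The pass-2 *sensitive* aligner runs when blockwise extension stopped early:
a gap-tolerant anchor chain (k = 11, allowing ~40% gap-length disagreement)
locates the mapped subsequences across the high-error segment, consecutive
anchor gaps are aligned exactly with banded global alignment, and the ends
are extended blockwise. Pairs whose overall difference exceeds 0.5 are
dropped.

## Coverage count array and consensus

A per-base coverage count array (CCA) records how many accepted supports
cover each template base; a candidate whose approximate interval is already
covered everywhere by more than C = 12 supports is skipped before any
alignment work. Additionally, once 20 supports have passed the threshold no
further candidate is aligned (`max_supports`; the method's own observation
is that a dozen suffice, and tests verify the gated consensus equals the
gate-free one).

Consensus is a per-column plurality vote over the support transcripts:
aligned bases and deletions vote per template position, insertion strings
attach between positions and are emitted only on a strict majority; base
ties break lexicographically and a deletion must strictly outnumber the
best base. Maximal runs of positions with ≥`consensus_min_coverage` (= 4)
supports are corrected. Pass 1 splices corrected runs back into the
full-length template (uncorrected stretches — HERS — pass through);
pass 2 re-runs the whole machinery on pass-1 output and emits only the
corrected runs, so a template with an uncorrectable interior interval
yields multiple fragments. Fragments shorter than 1 kb are dropped.

## Trimming and assembly

The longest 40X of corrected reads are pairwise-overlapped; each read's
intervals covered by overlaps with identity >0.90 are unioned. Fully
covered reads are *complete*; others are trimmed to their longest covered
interval (leftmost on ties). Only trimmed×(complete ∪ trimmed) pairs are
re-aligned; complete×complete overlaps are reused.

Assembly filters overlaps in two steps. A per-read coverage filter removes
reads whose overlap coverage is locally absent (c_min < 2), excessive
(c_max > 200) or uneven (c_diff > 150). An adaptive identity/overhang
filter then applies, per read, cutoffs of mean − max(2·sd, 0.02) identity
and mean + max(2·sd, 200 bp) overhang, floored/capped by the global 0.90
and 500 bp; an overlap must satisfy both of its reads' cutoffs. The spread
floor (0.02 / 200 bp) exists because corrected-read identities cluster
within a few tenths of a percent and a pure mean − 2sd rule was observed to
discard genuine dovetail neighbours and shatter the graph.

The string graph is Myers-style: contained reads removed, each proper
dovetail yielding an extension edge and its dual. Transitive edges
(two-edge paths matching the direct edge length within 500 bp) are removed,
then only best in/out edges per node survive, then tips (≤3 reads),
bubbles (branches ≤5 reads, weaker side removed) and spurious links
(overlap <25% of the node's best) are cleaned. Unbranched paths become
contigs; each path's reverse-complement mirror is suppressed; cycle
components — a circular genome — are broken at their smallest node, so the
emitted contig repeats the breakpoint read's span once.

## Bridging

Raw reads are mapped back to the contigs. A read whose two hits attach to
the ends of two different contigs (within 2 kb of a terminus) becomes a
link candidate: gap length = unaligned read distance between the hits minus
the contigs' unaligned tails (negative means the contig ends overlap);
score = Σ identity×length of its two hits. Per contig pair and orientation
class, candidates are single-linkage clustered on gap length (window
1000 bp), the cluster with the highest score sum wins (ties toward the
smaller median |gap|), and its highest-scoring member fills the junction.
An end with competing partners is a branch and is never merged. Chains of
linked contigs are spliced left-to-right, trimming unaligned tails and
contig-end overlaps.

## The simulator: what it emulates and what it does not

`make_genome()` + `sample_reads()` generate the stated world the tests run
in: log-normal read lengths (mean 12 kb, truncated to 3–60 kb), uniform
position and strand, per-read target error drawn from a Beta rescaled to
[0.07, 0.50] with mode ≈0.14 and mean 0.15, error composition 40/30/30
substitution/deletion/insertion, and HERS injected with a length-dependent
probability (logistic by default, calibrated to the reported 3–23% of
>10 kb reads; a constant-probability variant is used where a criterion
states an exact fraction). Three calibration choices are frozen and
documented:

* **Event-rate inflation.** Independently planted edits partially cancel
  under optimal realignment, so events are planted at
  $e(r) = r(1 + 0.9r)$ to make the *realized* aligned error match the
  target $r$ (checked to ±0.02 in tests).
* **HERS length ≥ 2 windows (1000–1500 bp).** A rewritten interval shorter
  than two blocks can straddle a block boundary so that no single 500 bp
  block is fully garbage, and the blockwise aligner's 0.5 stop never
  fires; at ≥1000 bp one full block is always inside the interval
  regardless of phase. HERS events are insertion-heavy (25/15/60), as
  spurious basecalls dominate real high-error segments.
* **Circular sampling.** Reads may wrap the origin (default); with strict
  substrings a linear genome's ends taper to zero coverage and no method
  could reconstruct the outer ~2 kb, making a ≥99% reconstruction target
  unattainable in principle. The bacterial-scale genomes this models are
  circular.

The simulator stores each read's realized edit plan; replaying the plan on
the clean template reproduces the read byte-for-byte, which is tested.
What it does **not** emulate: quality scores, signal-level or homopolymer
error structure, chimeras, or coverage biases. A green end-to-end test
therefore establishes that the pipeline's logic is sound under the stated
error structure, not that it handles every artifact of real flow cells.

## Numerical and determinism notes

All coordinates are 0-based half-open; candidate coordinates are reported
on the oriented candidate with a strand flag and converted to
forward-strand coordinates in PAF output. Every tie-break is
deterministic: DDF seeds by smallest position, candidate ranking by score
then span then id, consensus bases lexicographically, trimming leftmost,
graph edges by id, bridge clusters by median |gap|. The pipeline is a pure
function of (input reads, configuration, seed); reruns are byte-identical.
The banded traceback is exact because its band is derived from the
already-computed distance of the same block; the bit-parallel distance is
exact by construction (verified against `adist()` in the test suite).

## Known limitations

* The contig of a circular component duplicates the breakpoint read's span
  (no cycle-trimming is attempted).
* Bridging joins only contig *ends*; repeat resolution through contig
  interiors is out of scope.
* The adaptive overlap filter is a documented stand-in: the published
  supplementary formulas for the global/local identity and overhang
  thresholds are not reproduced in the main text.
* Single-threaded; the `--threads` surface of the CLI is accepted but
  currently ignored.
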