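---
title: "mgpipe: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mgpipe: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records how each stage of `mgpipe` is defined, which knobs
matter, and why the genuinely open design choices were settled the way they
were. It is the companion to the README's user-facing tour.

## Read quality control

Two per-read trimming algorithms are offered. The *solexaqa* method keeps
the longest contiguous segment in which every Phred score passes the
quality cutoff; ties between equally long segments go to the 5′-most one,
so results are deterministic. The *fastx* method only strips the 3′ tail
while the terminal base fails the cutoff — interior low-quality bases
survive. "Passing" is inclusive by default (a base at exactly Q20 passes a
Q20 cutoff); `qc_params(inclusive = FALSE)` switches to a strict reading,
since aligner and trimmer lineages disagree on this and the choice shifts
retention at exactly-threshold bases.

The 5′ composition-bias trim is a sample-level decision, not a per-read
one: base frequencies are profiled per read position over all raw reads,
and each base's mean and sample standard deviation are taken **across
positions**. The trim length is the maximal contiguous prefix of positions,
starting at position 1, where at least one base deviates from its mean by
more than `five_prime_sd` (default 2) standard deviations; interior biased
positions are never touched, because a mid-read excision would break the
coordinate structure of every downstream alignment. Two points here were
genuinely underdetermined and are package decisions:

* the averaging axis (per base across positions, rather than per position
  across bases) — chosen because "a biased position" is only meaningful
  relative to the long-run frequency of the same base elsewhere in the
  read;
* the order of operations: 5′ trimming runs on the **raw** reads, before
  quality trimming, because the positional profile refers to raw machine
  cycles; quality trimming first would misalign cycle numbers across
  reads.

The trim is capped at 15% of the profiled positions
(`qc_params(five_prime_cap=)`) so a degenerate sample (e.g. very few
reads, where every position looks "biased") cannot delete entire reads.
One consequence worth knowing: on a perfectly unbiased sample each
position's frequency still fluctuates around the mean, so with the 2-SD
rule roughly one clean sample in ten trims one or two leading bases. This
is harmless — it removes the same 1–2 cycles from every read — and is the
straightforward price of a threshold stated in standard deviations.

After trimming, reads shorter than `length_cutoff` (default 30 bp) are
dropped; when one mate of a pair fails, the survivor moves to the
singleton output. Running the step on its own output changes nothing: the
biased prefix is already gone (the recomputed trim length is 0), trimmed
reads are already all-passing, and the length filter is idempotent.

## The internal mapper

The mapper exists so the screening/filtering/abundance stages have a
deterministic, dependency-free alignment source; any external SAM can be
substituted via `read_sam()`. It is a classical seed-and-extend design:

* exact k-mer seeds (default k = 15) indexed for both strands of every
  reference; k-mers containing N are skipped, and seeds hitting more than
  `max_hits_per_seed` (default 50) loci are ignored as repetitive;
* query seeds taken every `seed_stride` (default 10) positions plus the
  final offset, voted onto (reference, strand, diagonal) buckets;
* the top candidate diagonals (default 8, after merging diagonals within
  the band half-width of a stronger candidate) are extended. A gapless
  check on the candidate diagonal short-circuits the common case (≤ 2
  mismatches); otherwise a banded glocal alignment runs — global in the
  query, free leading/trailing gaps in a reference window `band`
  (default 10 bp) wider than the read on each side — with match +1,
  mismatch −1, gap −2.

One primary alignment is reported per read: the highest score, with ties
broken by lowest reference index, then leftmost position, then forward
strand, so identical inputs always produce byte-identical SAM. Multi-mapping
reads are therefore *assigned*, not fractionally distributed — with
closely related strains in the database, reads can cross-attract between
them, and strain-level abundance estimates inherit that ambiguity.

Percent identity is computed as
`100 · (aligned_query_length − NM) / aligned_query_length` with the
aligned query length summed over M and I CIGAR operations. Aligners vary
in whether identity is taken per aligned column or per query base; the
per-query-base definition was fixed here (and documented on
`alignment_identity`) so the 90% filter threshold has one meaning
throughout the package.

## Screening and adapter removal

`screen()` partitions reads exactly: `remove` mode retains what does *not*
match the database (host decontamination), `extract` mode retains what
does (quantification). With `paired_end_filtering = TRUE` a pair moves as
a unit as soon as either mate passes the length/identity filter — the
semantics that make sense for decontamination, where one confidently host
mate condemns the fragment.

Adapter screening is a local Smith–Waterman scan (match +1, mismatch −1,
gap −2, both adapter orientations) with a flagging threshold of 16,
i.e. a ≈16 bp near-exact match or a slightly longer degraded one
(18 matches − 2 mismatches also reaches 16). On 100 bp reads a chance
score of 16 is vanishingly rare (the test suite checks ≤ 0.1% of 2,000
random reads), so the threshold separates genuine adapter contamination
from noise without an e-value machinery.

## Coverage and abundance

For each reference: `base_count` is the sum of aligned query lengths
(M+I — insertion bases are sequenced bases assigned to that reference;
`base_ops = "M"` restricts to aligned columns), `read_count` counts
primary filtered records, and `insert_count` counts sequenced fragments
once — a pair with at least one mapped mate contributes 1, as does a
mapped singleton. Genome-size normalization sums counts and lengths over a
genome's replicons (chromosomes plus plasmids as one unit) before
dividing, then renormalizes across genomes to fractions. Zero-count
genomes keep their rows so observed and expected vectors always align, and
both base-count and read-count tables are emitted, since the two disagree
when coverage is uneven.

## Assembly parameter estimation and scaftigs

The assembly k-mer is the smallest odd integer ≥ half the mean
high-quality read length. The "≥" reading was chosen over a strict ">"
(the two differ only when half the read length is itself an odd integer,
e.g. mean length 46 giving 23 vs 25); the inclusive form is implemented
and tested over every integer length from 2 to 500.

Insert size is estimated from proper pairs (both mates mapped, same
reference, opposite strands) as the **median** outer distance, with the
raw median absolute deviation as spread. Median/MAD rather than mean/SD
because chimeric or mis-mapped pairs produce extreme outer distances that
would wreck a moment estimator but leave quantiles untouched. Any FASTA
can serve as the estimation reference (marker genes, draft contigs, a
known genome); no marker database is bundled.

Scaftig extraction splits scaffolds at every maximal run of Ns, keeps
N-free pieces of at least 60 bp, and numbers them `scaffold_1`,
`scaffold_2`, … in order. Before the length filter, the pieces conserve
exactly the scaffold's non-N bases (a tested invariant).

## Assembly revision

Revision is defined purely on gap-tolerant alignments to the scaftigs —
any SAM source works — making the step independent of the assembler and
aligner used upstream. One pileup pass drives three analyses, in order:
substitutions, short indels, breakpoints. No iteration: re-mapping against
the revised assembly is the caller's decision.

Consensus corrections are conservative by construction: a column needs
depth ≥ `min_depth` (default 3) and a **strict** majority (> 0.5) for a
non-reference base, an inserted sequence, or a deletion; ties keep the
reference, and indels longer than `max_indel` (default 10 bp) are never
applied. These thresholds are package decisions — no published values
existed to adopt — and are all surfaced in `revision_params()`.

Chimera detection is insert-based. A joined-but-wrong junction has a
signature: no read *pair* spans it, because no true fragment crosses the
join. A break region is a maximal internal run of zero insert-span
coverage (the number of proper pairs whose outer span strictly contains a
position) flanked on both sides by at least `span_window` (default 100)
positions of positive span coverage; the flank requirement keeps scaffold
ends — which never have spanning pairs — from triggering. Zero-depth
positions inside the region are removed; otherwise the scaftig is cut at
the region's minimum-depth position (leftmost on ties). An earlier design
additionally required zero *read* depth across the junction, but that
condition can provably never hold for a plain concatenation chimera under
tiling coverage — reads from both source loci abut the junction from
either side, so read depth stays positive even though span coverage drops
to zero — and it was dropped in favour of the span-only criterion, which
is also what an insert-size-aware aligner effectively tests. Terminal
zero-depth runs are trimmed (`end_trim`), and post-split pieces below
`min_scaftig` (default 60 bp) are dropped and logged.

All event positions refer to the input scaftig, and
`revise_assembly()` produces its output by replaying its own event log
(`replay_events()`), so the log is sufficient by construction to
reproduce the revision byte for byte — a tested invariant, along with
base conservation up to logged removals and the fixed-point property on a
correct assembly.

## The simulator, and what passing tests do not show

The simulator is the package's ground-truth substrate. Genomes are i.i.d.
base sequences at a requested GC content (independent genomes are ~75%
divergent; `mutate_genome()` derives strains at controlled divergence
when near-identical genomes are wanted). Community composition semantics:
a genome's expected share of *fragments* is abundance × length, so the
genome-size-normalized pipeline output estimates the abundance vector
itself — observed and expected live on the same scale. Log-uniform
abundances span two decades by default, a typical spread for dominant
through sub-dominant community members. Reads carry a constant-Q35
quality with a linear ramp to Q20 over the final 20% of cycles (so
quality trimming has realistic work to do), substitution errors at a
configurable rate, and no indel errors by default (keeping identity
arithmetic exact; reads with indels arise instead from mapping against
corrupted or diverged references). `corrupt_assembly()` cuts
non-overlapping genome segments as scaftigs and injects substitutions,
1–5 bp indels and two-genome chimeric fusions at recorded positions, with
the truth log expressed as the revision events needed to repair them.

What the simulator deliberately does not emulate: platform-specific error
profiles (quality-dependent miscalls, optical duplicates, chastity
failures), GC-coverage bias, repeat structure and mobile elements shared
across genomes, and real strain pangenomes. Tests passing on this
substrate demonstrate the algorithms' correctness under their stated
models — majority-vote repair at 30× clean coverage, abundance recovery
for well-separated genomes — not performance on real instrument data,
where mapping ambiguity and error structure are harsher.

## Problem sizes and numerical conventions

The package-level benchmark (also run by `scripts/acceptance.R`) uses 10
genomes of 100 kb with log-uniform abundances and 100,000 error-free
100 bp pairs; correlation thresholds are Pearson ≥ 0.95 and
Spearman ≥ 0.90 for both base- and read-count tables. Revision is
exercised on 3 genomes of 40 kb with 20 substitutions, 10 indels and 2
chimeras at 30× coverage; insert-size recovery on 20 seeds of 1,000 pairs
from a Normal(300, 30) library, requiring the median within 3 standard
errors. These sizes keep the full suite under a minute while leaving each
statistical check properly powered.

Conventions used throughout: all coordinates are 1-based inclusive (the
SAM/GFF and R convention — a single convention end to end avoids
off-by-one drift); qualities are re-encoded to Phred+33 at input, with the
+33/+64 ambiguity band (ASCII 59–74) resolved to +33 with a warning;
secondary alignments are parsed but ignored by every counting operation,
so each read is counted once; and every random process takes an explicit
seed, making all outputs reproducible.

## Known limitations

* The mapper is a minimal screen-grade aligner: no quality-aware scoring,
  no soft-clipping (reads are aligned end to end), and sensitivity drops
  for reads whose every k-mer window is disrupted — it is not a BWA
  replacement for divergent mapping.
* Strain-resolved abundance (genomes > ~90% identical) is inherently
  ambiguous under single-assignment mapping; expect cross-attraction
  between near-identical references.
* Revision runs a single pass; residual errors that only become visible
  after re-mapping require the caller to iterate.
* The pipeline layer runs samples serially; it trades throughput for
  determinism and simplicity.
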