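---
title: "Reference-guided de novo assembly: methods and design notes"
author: "refguide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-guided de novo assembly: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

De novo assembly of short-read data struggles with repeats, heterozygosity
and sequencing errors; a chromosome-scale genome of a *related* species, even
one diverged by several percent and rearranged, carries information that can
guide the process. `refguide` implements a reference-guided de novo assembly
strategy built on that idea: reads are mapped to the related genome only to
*partition* them into small, local assembly problems, while every base of
the final assembly is still called from the reads themselves. The guide
reduces the complexity of each de novo step; it never contributes sequence.

The pipeline has seven steps:

1. **Quality trimming.** Leading and trailing bases below phred 3 are
   removed; the read is then cut at the first 4 bp sliding window whose mean
   quality drops below 15; reads shorter than 40 bp are discarded. These
   defaults follow the standard leading/trailing/sliding-window trimmer
   semantics and can be changed in `trim_params()`.
2. **Mapping and superblocks.** Reads are mapped to the guide reference with
   the built-in seed-and-extend mapper (below). Maximal intervals of
   continuous read coverage form *blocks*; adjacent blocks spanned by at
   least 10 proper pairs are bridged. Consecutive blocks are combined into
   *superblocks* of at least 12 kb, neighbouring superblocks overlap by at
   least 300 bp, and superblocks longer than 100 kb are split into 100 kb
   pieces with exactly 300 bp overlap. Each superblock collects the reads
   aligned inside it plus unmapped reads whose mate maps there.
3. **Local de novo assembly.** Every superblock — and the pool of reads
   unmapped against the reference — is assembled independently with the
   built-in de Bruijn assembler, repeated for each k in the configured list.
4. **Homology-guided merging.** The pooled contigs (redundant because
   superblocks overlap and several k were used) are anchored to the guide
   reference by co-linear chains of exact 15-mers and merged column by
   column into non-redundant *supercontigs*. Contigs with unalignable
   overhangs beyond 1000 bp, or without an anchor chain, are set aside;
   tiles overlapping by at least 10 bp on the reference merge into one
   consensus. Consensus bases always come from contigs, never from the
   reference, so target-specific divergence survives this step.
5. **Rescue of diverged regions.** Merging against a diverged reference
   loses the contigs it cannot anchor. The trimmed reads are therefore
   aligned back to the supercontigs (end-to-end mode) and everything that
   remains unmapped is assembled once more (single k, default 31 at desk
   scale) and appended. This step is the switch `enable_step5` and the
   pipeline can be run without it to quantify its effect.
6. **Error correction.** Paired-end reads are aligned to the supercontigs;
   alignments below mapping quality 10 are dropped. A strict majority of
   non-reference bases (at least two reads) substitutes a column, majority
   deletions remove it, majority insertions are spliced in (left-aligned),
   uncovered stretches are excised with the supercontig split at them, and
   pieces shorter than 200 bp are discarded.
7. **Ranked scaffolding.** Read pairs bridging two supercontigs at mapping
   quality 10 or better vote for oriented junctions; the gap estimate is the
   library insert mean minus the mates' distances to their inner ends.
   Libraries are processed smallest insert first; within a library, links
   are accepted in descending support unless an end is already used or a
   cycle would close. Junctions are written as `max(gap, 10)` N's, then gap
   closing replaces an N run when exactly one k-mer read path bridges the
   junction. Scaffolds under 1 kb are discarded.

## The built-in mapper

The mapper exists so the pipeline is testable end to end without external
binaries; `read_sam()` imports alignments from any external mapper as an
equivalent entry point. It indexes all non-N 15-mers of both strands,
collects seed votes per (reference, strand, diagonal), and extends the best
candidates by banded gapped alignment with match +2, mismatch −3, gap open
−5, gap extend −2. `"local"` mode permits soft-clipped ends; `"sensitive"`
mode aligns the read end to end (clipping forbidden), which is how reads are
re-aligned in steps 5–7. Alignments scoring below `20 + 8·ln(read length)`
are unmapped. Mapping quality is `min(60, 6·(best − second best))` and 0 on
ties — downstream logic only relies on unique confident hits reaching
mapq ≥ 10 and ambiguous ones not doing so. These constants are package
choices, not claims about any particular external mapper.

## The built-in assembler

A canonical-k-mer de Bruijn assembler: k-mers below multiplicity 2 are
dropped (singleton error k-mers vanish at the coverages the pipeline
targets), dead-end paths shorter than 2k are clipped, and simple two-arm
bubbles — the signature of heterozygous substitutions — are popped keeping
the higher-multiplicity arm (ties resolved to the lexicographically smaller
sequence). Maximal non-branching paths are reported in canonical
orientation, sorted, so assembly is deterministic and invariant under
reverse-complementing the input. K-mers are packed in 128 bits, so k may
reach 63: the desk-scale default list is `c(21, 31, 41)`; at full scale
(100 bp reads, high coverage) the natural list is 41–63 in steps of 10 —
k beyond 63 is not representable in this implementation. The
`external_assembler()` hook runs any command template writing contigs as
FASTA and tolerates failure, so a production assembler can stand in per
superblock.

## The simulator

`simulate_reads()` emulates an Illumina read simulator closely enough to
exercise every pipeline branch: uniform fragment starts, normal insert
lengths truncated to `[2, contig length]`, FR paired-end and RF mate-pair
orientation, and a flat per-base substitution error rate (default 0.2%)
with base qualities tied to it by `Q = −10·log10(rate)`. A heterozygous
diploid is simulated by `mutate_genome()`: each non-N base is substituted
with probability 1% (the default) by one of the other three bases, and half
the fragments of every library are drawn from each haplotype.
`paper_libraries()` fixes the eight-library design this package treats as
its reference study condition: paired-end inserts 150/200/400 bp
(sd 34/36/87) at 72/72/40-fold coverage and mate-pair inserts 3/5/7/11/15 kb
(sd 400) at 76/82/104/44/40-fold, 100 bp reads throughout; `scale = 0.1`
gives the corresponding low-coverage design. `diverged_reference()` builds
the related-species guide: substitution divergence (default 5%) plus
segment shuffling and inversion across chromosomes, so guide and target
share homology but not coordinates.

What the simulator does **not** model: indel sequencing errors, PCR
duplicates, GC-coverage bias, optical artefacts, and empirical
position-dependent quality profiles (a per-position rate vector is accepted
but the default is flat). Tests passing on this generator therefore
demonstrate algorithmic correctness of the pipeline logic — partitioning,
assembly, merging, rescue, correction, scaffolding — not robustness to
every artefact of real instruments.

## Evaluation framework

`evaluate_assembly()` computes a registry of 34 oriented statistics:
contig/scaffold counts and N50, NG50 against the known genome size,
absolute length differences (total and gene-sized, ≥1.2 kb), misassembly
counts from truth alignment, local misassemblies, percentages of
misassembled and unaligned scaffolds, error-corrected NG50 and its ratio,
N's and indels per 100 kb, duplication ratios, read-mapping rates (mapped,
mapq ≥ 10, proper pairs at mapq ≥ 10), COMPASS coverage/validity/
multiplicity/parsimony, gene recovery (full at ≥95% single-scaffold
coverage, partial at ≥1 bp) against simulator-emitted gene intervals, and a
read-pair consistency score (fraction of error-free bases times
broken-N50/N50, where error regions are internal zero-fragment-coverage
stretches or clusters of at least five inconsistent pairs).

Truth alignment decomposes each scaffold into maximal co-linear segments by
iteratively extracting the best chain of exact 15-mer matches; segments
shorter than 500 bp are ignored (suppressing spurious micro-hits), and
chains break at diagonal drifts above 600 bp so rearrangements longer than
the 1 kb relocation threshold always surface as separate segments. Adjacent
segment pairs are classified with precedence translocation (different
chromosomes) > inversion (opposite strands) > relocation (same strand,
truth gap or overlap beyond 1 kb) > local (smaller inconsistencies above
85 bp, a floor that ignores indel-scale wobble).

**Orientations.** Statistics where smaller is better (counts, length
differences, error densities, parsimony, unaligned fractions) are negated
before standardization. Duplication ratio and multiplicity are best at
exactly 1, so they are transformed to `−|x − 1|` before standardization
("near-one" orientation). These assignments follow the usual
assembly-contest convention; they are fixed in the registry rather than
guessed per run.

**Ranking.** `zscore_rank()` standardizes each oriented statistic across
methods with the *sample* standard deviation (columns with zero spread
contribute zeros) and sums per method; leave-one-out error bars report the
best and worst summed z attainable by omitting one statistic. Pairwise
method comparisons use a one-sided Wilcoxon rank-sum test over the z-score
vectors: exact by complete mid-rank enumeration when the pooled size is at
most 20, and the tie-corrected normal approximation with continuity
correction otherwise. The test deliberately treats the per-statistic
z-scores as independent samples (rank-sum, not signed-rank), matching how
such rankings are compared in the assembly-evaluation literature.

## Numerical choices and determinism

- All intervals are 0-based half-open; only SAM emission converts to the
  1-based wire format.
- IUPAC ambiguity codes collapse to N on input; the pipeline alphabet is
  ACGTN.
- Consensus tie-breaks are lexicographic (A < C < G < T), deletions lose
  ties to bases; repeat-induced multi-placements take the highest-scoring
  chain, then the leftmost reference coordinate. Nothing is randomized: a
  fixed seed makes the whole pipeline byte-identical across runs, with the
  master seed fanned out to stages through a fixed affine map.
- Superblock overlap is realized by sharing whole blocks; when the shared
  block alone provides less than 300 bp the shared region extends leftward
  block by block, and when whole-block sharing would re-include an entire
  superblock (a single block of 12 kb or more) the next superblock instead
  starts exactly 300 bp before the previous end — the same within-block
  overlap the 100 kb split rule uses.
- The gap estimate floor of 10 N's keeps a visible junction when mates
  imply overlapping supercontig ends.

## Problem sizes

The test suite exercises the full pipeline on a 200 kb diploid genome (1%
heterozygosity) with a 5%-diverged, rearranged two-chromosome guide, one
paired-end library (insert 300 ± 30, 25×) and one mate-pair library (insert
3000 ± 300, 8×) — sizes chosen so the whole suite, including two end-to-end
runs (with and without the rescue step), completes in a few minutes on one
CPU while leaving every threshold of the method active (multiple
superblocks, 100 kb splits, bridged blocks, rescued regions, closed gaps).
Unit fixtures are smaller (3–50 kb) and constructed per property.

## Known limitations

- The mini assembler resolves neither repeats beyond k nor complex bubble
  structures; it is a faithful executor of the pipeline contract, not a
  competitor to production assemblers — which is why the external hook
  exists.
- Merging anchors each contig to a single best chain; a contig genuinely
  spanning a rearrangement breakpoint of the guide is set aside rather than
  split, and is recovered by the rescue step instead.
- Indel handling is by pileup majority vote with left-aligned
  representation; no realignment around indels is performed.
- The evaluation's indel density comes from diagonal shifts within anchor
  chains, a proxy rather than a base-level alignment count.
- Iterative re-running of the pipeline with the draft as the new reference
  is out of scope.
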