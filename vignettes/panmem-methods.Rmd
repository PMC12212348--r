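---
title: "Methods: r-index pangenome alignment in panmem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: r-index pangenome alignment in panmem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Aligning short reads to a single linear reference mis-places or loses reads
whose true source carries variation the reference lacks (reference bias).
panmem instead indexes a *collection* of haplotypes — built from a reference
FASTA plus a phased VCF — in a run-length compressed BWT index (the
r-index), aligns each read against all haplotypes at once, and lifts the
winning alignments back to linear-reference coordinates so the SAM output
stays compatible with downstream tools such as variant callers.

## Index

The pangenome text concatenates every haplotype (and, by default, the
reference itself) with reserved separator bytes and a terminator byte that
sort below all sequence characters, so no match can cross a document
boundary.  The index stores:

* the run-length BWT: one `(character, length)` pair per maximal run, plus
  cumulative character counts (the F column as counts);
* the suffix-array value at the first and last row of every run;
* per character, for each pair of consecutive runs of that character, the
  row of the *first minimum* of the LCP array between them (the
  *threshold*);
* a predecessor table over run-boundary SA values implementing the phi
  function `phi(SA[j]) = SA[j-1]`, used to enumerate occurrences from a
  single toehold;
* the text itself for random access.  (Grammar-compressed random access is
  deliberately replaced by plain storage with the same access contract;
  desk-scale inputs make compression pointless.)

Construction sorts suffixes by prefix doubling (`O(n log^2 n)` with
`std::sort`); this was chosen over induced sorting because it is far easier
to verify, and it costs only ~15 s on the ~2 MB texts the package targets.
Prefix-free parsing (PFP) is retained as the documented construction
front-end: `build_rindex(x, via = "pfp")` parses the text with a Karp–Rabin
rolling hash (base 1e9+7, 61-bit Mersenne modulus, reduced modulo `p`;
window length `w = 10`, `p = 100` by default — chosen so phrases average
about `p` characters, since no canonical values exist), validates the
prefix-free invariants, reconstructs the text from dictionary and parse
alone, and feeds the same builder.  Building the BWT *within* compressed
space from the parse is out of scope; the two paths are tested to produce
identical index content.

## MEM seeding

Matching statistics are computed in two passes.  The backward pass walks the
read right-to-left holding a single BWT row and its SA value; when the next
character cannot extend the current match, the thresholds structure decides
whether to jump to the end of the preceding run of that character or to the
start of the following one (rows at the threshold jump down — the threshold
is defined as the first minimum-LCP position, so the tie is exact).  The
forward pass measures each match length by direct text comparison.  `N`
never matches anything, in either direction, which prevents spurious seeds
through `N` runs.

MEMs start wherever the statistic did not decrease (`len[i-1] <= len[i]`);
seeds shorter than 25 bp are discarded, seeds longer than 50 bp are split
into two adjacent halves (ceiling/floor) that are re-located independently
— re-location rather than offset inheritance, because a half-MEM can occur
in places the full MEM does not.  Occurrences are enumerated from the
toehold by repeated phi application and capped at 1000 per *genome* (a
sample's two haplotypes count once).  Two post-filters follow: a seed
holding at least 50% of the read's total (capped) occurrence count is
dropped (occurrence count, not MEM count, is the operand — the stated
motivation is removing frequently occurring, uninformative matches), and a
strand whose mean seed length trails the other by 50 bp or more is dropped.

## Chaining, extension, liftover

Anchors (seed occurrences) are chained per (haplotype, strand) with the
minimap2-style recurrence
`f(j) = max(l_j, f(i) + min(dx, dy, l_j) - gap(|dx - dy|))`,
`gap(d) = c1 d + c2 log2 d`, with `c1 = 0.12`, `c2 = 0.5` (short-read-like
constants; configurable, since no canonical values are printed anywhere),
both gaps bounded by 500 bp.  Chains scoring below 40 are dropped and the
top five go to full alignment, after a uniqueness heuristic discards any
chain whose (score, lifted position of the leftmost anchor) pair repeats an
earlier chain's.

Full alignment verifies the anchors, trims overlapping ones, fills the gaps
between consecutive anchors with global affine-gap DP (match 2, mismatch 4,
gap open 4, extend 2; a length-g gap costs `4 + 2g`), and extends the
flanks to the read ends, soft-clipping wherever the best extension score
would be non-positive.  Tracebacks use explicit per-cell direction flags; a
CIGAR re-scorer (`score_cigar`) recomputes every emitted alignment's score
from scratch as a consistency check.  `M` is emitted by default (`=`/`X`
optional).

Liftover rewrites haplotype-coordinate operations through variant-derived
segment maps: only indels break segments (SNPs preserve coordinates); read
bases over haplotype insertions become `I`, deleted reference stretches
inject `D`, leading/trailing artifacts fold into soft clips, and the score
is carried over unchanged.  Alignments that lift to the same (contig,
position, strand) keep only the higher score.  An alignment entirely inside
a haplotype insertion has no reference anchor: the op-level API returns it
flagged on haplotype coordinates, the pipeline omits it from the SAM
(structural variants larger than the read are out of scope).

## Pairing and mapping quality

Insert sizes (outer distances on the reference) are accumulated with
Welford's one-pass algorithm over the first 1000 pairs whose mates each
have a unique best alignment; with fewer than two such pairs the aligner
falls back to single-end scoring with a warning.  Mate selection maximises
the score sum over combinations on the same reference contig, on opposite
strands, with outer distance inside `mu ± 4*sigma` (inclusive — a hard
constraint).  Pairing operates on *lifted* candidates rather than raw
haplotype hits: after same-position deduplication an identical alignment
may survive under a different haplotype label, so a same-haplotype test
would be label-dependent while the reference-coordinate test is not.  If no
combination qualifies, the higher-scoring mate anchors an orphan-recovery
attempt: the other mate is fit-aligned (read global, window free) inside
the `mu ± 4*sigma` window on the anchor's haplotype and accepted when its
score reaches `0.5 * match * length` — the acceptance floor is our
concretisation of "a suitable alignment".

Single-end mapping quality is BWA-like:

    Q  = min(60, 6.02 (s1 - s2) i / (4 m1) - 4.343 ln(n + 1)),
    i  = 1 - (m1 l - s1) / ((m1 + m2) l),

with `n` the number of distinct secondary scores within 80% of the best
score (the "fixed range" is unspecified upstream; 0.8 is configurable), the
result truncated to an integer and clamped to [0, 60].  4.343 is 10/ln 10,
so the `n` term is `10 log10(n+1)`.  For proper pairs each mate's value is
adjusted by

    Qi = min(max(Q, min(Q', Q + 40)), 6.02 (s1p - s2p) / m1),

where `Q'` applies the single-end formula to paired score sums (read length
`l1 + l2`): a low mate is elevated by at most 40 by a confident pair, and a
tied paired score caps everything at 0.

## The synthetic world

`simulate_pangenome()` draws an i.i.d. random reference and plants ~2% of
it as duplicated 500 bp segments.  The duplications are deliberate: an
i.i.d. 100 kb sequence contains no repeats, so every read would be uniquely
placeable and the low end of the MAPQ spectrum could never be exercised,
unlike any real genome.  Each of 20 haplotypes then receives Bernoulli SNPs
at 1e-3/bp and geometric-length indels (capped at 10 bp) at 1e-4/bp;
per-haplotype overlapping events are dropped and all events are merged into
a phased two-haplotypes-per-sample VCF.  Reads are 2x100 bp FR pairs with
normal outer distance 350 ± 50 (typical TruSeq-like values; unspecified
upstream) and substitution-only errors at 0.2% — no simulated indel errors,
which keeps ground-truth positions exact.  The generator assembles its
haplotypes and lift maps with its own event walk, independent of
`apply_variants()`, so the round trip through the pangenome builder is a
real check rather than a tautology.

What a green end-to-end test establishes: on this world the aligner reaches
≥99% recall and ≥95% precision at 10 bp tolerance, produces MAPQ values
covering 0–60, and orphan recovery strictly increases the aligned-read
count on a fixture with disabled-seed mates.  What it does not establish:
behaviour on real error profiles (indel errors, quality-correlated errors),
large structural variation, centromeric-grade repetition, or chromosome-
scale inputs.

Evaluation counts a read as a true positive when its (soft-clip adjusted)
position lands within 10 bp of the truth, false positive when mapped
elsewhere, false negative when unmapped; precision is `TP/(TP+FP)` and
recall `TP/(TP+FP+FN)` — the denominator includes mis-mapped reads, which
matches both the worked scoring example this module is tested against and
standard aligner-benchmark practice.

## Numerical and policy choices

* Coordinates are 0-based half-open internally; VCF input and SAM output
  are 1-based; R-facing positional helpers (`lift_position` etc.) are
  1-based.
* Byte order of the alphabet (terminator < separator < `#` < `A` < `C` <
  `G` < `N` < `T`) fixes the BWT content and is part of the index format.
* Overlapping VCF records on one haplotype: first kept, later ones skipped
  with a warning.  Multiallelic records are decomposed by GT index;
  symbolic alleles are rejected; unphased genotypes are an error.
* Ties: chain selection orders by (score desc, document, strand, position);
  dedup keeps the first among equal scores; extension tie-breaks prefer
  consuming more read, then more window.  All choices are deterministic, so
  identical inputs produce byte-identical SAM.
* MAPQ truncates (not rounds) and clamps to [0, 60]; negative raw values
  become 0.
* The occurrence enumerator carries a 500k safety bound per seed, far above
  anything the per-genome cap can retain.

## Known limitations

* Index construction is `O(n log^2 n)` time and `O(n)` memory in the
  uncompressed text — fine at desk scale, not at chromosome scale.
* FASTA-only indexes report coordinates on the indexed sequences (no lift
  maps), exactly as documented for the two build inputs.
* Recovery and pairing assume FR orientation libraries.
* Reads shorter than ~40 bp cannot pass the default chain-score threshold
  (40) unless seeds chain; that matches the intended 100–250 bp regime.
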