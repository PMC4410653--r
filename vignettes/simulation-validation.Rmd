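---
title: "Simulating diploid genomes with encoded ground truth, and validating secondary analysis against them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating diploid genomes with encoded ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Aligners and variant callers are usually benchmarked against real data for
which no ground truth exists. simval takes the opposite route: it *builds*
the truth. A phased diploid genome is synthesized by inserting known
variants — SNVs, small indels, and structural variants (deletions,
insertions, inversions, tandem duplications) — into a reference; paired-end
reads are simulated from that perturbed genome; and because every read's
true origin is known by construction, the package can judge, read by read
and call by call, whether a secondary-analysis pipeline recovered the
truth. Two validators close the loop: one scores SAM/BAM alignments against
per-read truth encoded in the read names, the other scores a call-set VCF
against the truth VCF and reports sensitivity (TPR), precision (PPV) and F1
stratified by variant type and size bin.

```{r, eval = FALSE}
library(simval)
fx     <- smoke_fixture(seed = 1)                     # reference + database + donor pool
db     <- normalize_variants(fx$db, fx$reference$sequences)
truth  <- sample_truth(db, sampling_spec(n_snv = 50, n_indel = 20, n_sv = 5,
                                         seed = 1),
                       fx$reference$sequences, fx$pool)
dip    <- build_diploid(fx$reference$sequences, truth)
reads  <- simulate_reads(dip$haplotypes, dip$map, read_sim_params(coverage = 50))
```

## The genome map: the data structure everything rests on

Applying a variant set to a reference changes the coordinate system: a
deletion shortens the haplotype, an insertion lengthens it, an inversion
reverses a span, and a tandem duplication makes two haplotype intervals
share one reference source. The package records the complete correspondence
as an ordered set of *blocks*, one tibble row each:

| feature    | host width | reference width | meaning                          |
|------------|-----------:|----------------:|----------------------------------|
| `SEQ`      | n          | n               | colinear sequence (SNVs substituted in place) |
| `DEL_GAP`  | 0          | n               | deleted span; a zero-width join point on the haplotype |
| `INS_NOVEL`| n          | 0               | novel inserted sequence; anchors at the breakpoint |
| `INV`      | n          | n               | reverse-complemented span, strand `-` |
| `DUP_COPY` | n          | n               | an extra tandem copy, mapping back to the single source interval |

Within a host contig the blocks of positive width tile `[0, length)`
exactly, so `lift_point()` is a binary search plus offset arithmetic and
`lift_interval()` splits any haplotype interval into reference segments.
The map is deliberately a *function* host → reference: a duplicated base
lifts to its one source location. The alternative — enumerating all copies
as equally true — would make "correct alignment" ambiguous at the map
level; instead, ambiguity is handled per read (below). All interface
coordinates are 1-based inclusive (VCF convention); every internal
computation uses 0-based half-open intervals. The map serializes to a
versioned TSV (`write_genome_map()`), one block per line.

Two invariants are enforced by `validate_genome_map()` and exercised in
the tests: tiling/ordering well-formedness, and the length balance
`len(host) = len(ref) + Σ ins − Σ del + Σ (copies − 1)·dup` per haplotype.
A reconstruction property ties it all together: fetching every lifted
segment back from the reference (reverse-complementing `INV` segments,
substituting recorded insertion sequences, and re-applying the truth set's
SNV/MNP substitutions, which live inside `SEQ` blocks) reproduces each
haplotype byte for byte.

## Canonical variant representation

The same indel can be written in many VCF encodings, especially in tandem
repeats. Comparison is only meaningful after normalization, so every record
passes through a canonicalizer on the way in: shared trailing bases are
trimmed, the record is extended and shifted left while an allele is empty,
and shared leading bases are trimmed down to the single anchor base. The
canonical form is therefore the *left-aligned, minimal* representation —
the convention used by mainstream normalizers. The operation is idempotent
and sequence-preserving, and the test suite brute-forces equivalence
classes (every encoding of an edit that yields the same edited sequence)
to confirm that all members collapse to one record. Insertion sequences
are re-derived from the canonical alleles so the record stays internally
consistent after shifting. Symbolic records (`<DEL>`, `<INS>`, `<INV>`,
`<DUP:TANDEM>`) are anchored by position and length and pass through
unchanged.

## Truth-set sampling

`sample_variants()` draws from a database VCF after a seeded shuffle,
accepting records in shuffled order until each category quota (SNV, indel
< 50 bp, SV) is met, and rejecting any record whose reference footprint
comes within `min_gap` (default 10 bp) of an accepted one. Rejection
sampling in a seeded order is simple, deterministic, and
order-independent of the database file. Genotypes are heterozygous with
probability `het_fraction` (default 0.6, roughly the het/hom balance of a
human genome) and land on either haplotype with probability 1/2.
Sampling is without replacement and uniform; database allele frequencies
are not modeled. Insertions without a concrete sequence receive one from a
donor pool — a uniformly chosen window of a uniformly chosen long-enough
donor — or i.i.d. bases if the pool cannot serve the length.

## Read simulation and the truth in the read name

The built-in engine is deliberately plain: fragment start uniform over each
haplotype (weighted by length), fragment length Normal(`frag_mean`,
`frag_sd`) clamped to `[read_len, 2·frag_mean]` (clamping rather than
re-drawing keeps the draw count fixed, which the sharding design needs),
mate 1 forward from the left end, mate 2 reverse-complemented from the
right end, substitution-only errors at a flat rate with constant base
qualities `round(−10·log10(max(rate, 1e−4)))`. Indel sequencing errors and
learned quality profiles are explicitly out of scope — the engine adapter
(`simulate_with_engine()`) is the extension point: any function that
returns reads with host coordinates gets truth annotation and name
encoding applied identically.

Generation is organized in fixed 512-pair chunks, each seeded from
`(seed, chunk index)`. A shard is a contiguous range of chunks, so the
FASTQ concatenation of any shard partition is byte-identical to the
single-shard run — parallelization can never change the output.

For each mate the map yields an ordered list of lifted segments, and from
them the set of *alternative true alignments*: if all segments are
colinear plain sequence, one full-length alternative; otherwise one
alternative per segment — that segment anchored at its own reference
start, the rest soft-clipped. This generalizes the inversion-edge case
symmetrically to deletions, duplication junctions and insertion edges.
Bases inside a novel insertion have no reference anchor; a read fully
inside one gets a single alternative at the breakpoint, labelled
`INS_NOVEL`. The per-pair truth (originating haplotype, and each mate's
region labels and alternatives) is packed into the read name as
`vs:<read_id>:<base64url payload>`. Both mates carry the *same* name —
paired-end aligners require identical query names — and mate identity is
recovered from the payload during validation, never from FLAG bits, so
mate-swapping by an aligner cannot corrupt scoring. Names are capped at
the 254-character SAM limit; rare overflows move the payload to a sidecar
table keyed by read id.

## Alignment validation

A primary record is CORRECT when its reported contig matches and its
leftmost aligned position (POS, which already excludes soft-clips) is
within `wiggle` bp of any alternative's anchor, for either mate. The
default `wiggle = 20` tolerates aligner end-trimming without absorbing
genuine misplacements; correctness is monotone in it by construction.
Strand agreement is deliberately not required: near clipped anchors,
aligners may report either orientation. Undecodable names become
`UNKNOWN_READ` and leave the accuracy denominator; secondary and
supplementary records are counted but never judged. Every record is
tallied under each region label it touches, so accuracy can be read off
per variant class (`SEQ`, `DEL_GAP`, `INS_NOVEL`, `INV`, `DUP_COPY`) as
well as overall.

## Variant-call validation

Small variants (all SNV/MNP, indels under 50 bp) must match exactly on
`(chrom, pos, ref, alt)` after normalization; genotype agreement (as an
unordered allele pair) is optional and off by default, matching the
site-level reporting convention. SVs match tolerantly: same type,
breakpoint start distance ≤ 100 bp, and size ratio
`min(size)/max(size) ≥ 0.8`; insertion content is not sequence-compared
because callers rarely emit full inserts. Matching is one-to-one and
greedy in order of increasing breakpoint distance (ties: larger size
ratio, then truth position) — transparent, deterministic, and checked in
the tests against an exhaustive optimal matcher on small fixtures whose
optimum is unique. Degenerate cells follow explicit conventions: TPR is
undefined (`null` in JSON) with no truth, PPV undefined with no calls,
and F1 is 0 whenever either rate is 0, undefined only when a rate is
undefined without a zero. Cells, per-type and per-bin marginals and the
grand total are reported over configurable size bins (default: 1, 2–5,
6–20, 21–50, 51–100, 101–200, 201–500, 501–1000, 1001–2000, 2001–5000,
>5000 bp; truth-derived records bin by truth size, false positives by
call size).

## The tumor/normal workflow

`build_tumor_normal()` samples one germline truth set with the shared
seed, builds the normal genome from it, and builds the tumor genome from
the same germline plus a somatic set applied on top; somatic records whose
footprints collide with the germline (or each other) are dropped and
reported. Somatic genotypes come from a separate RNG stream so the
germline draws are untouched — which is what makes the two genomes'
germline content byte-identical, the invariant the somatic workflow rests
on. `mix_reads()` models normal contamination as a global tumor fraction
α: each emitted pair is tumor-derived with probability α, drawn without
replacement within each pool, mates kept together. Per-variant subclonal
frequencies are out of scope — one α per run. `validate_somatic()` scores
calls against the somatic truth and additionally flags false positives
that match the germline truth as *germline leaks* (they stay false
positives for precision; the flag separates "caller leaked a real
germline variant" from "caller invented a variant").

## What the synthetic fixtures do and do not show

`make_reference()` draws i.i.d. bases at a target GC and embeds short
tandem repeat tracts at recorded positions; `make_variant_db()` populates
it with non-colliding records, deliberately emitting a quarter of the
small indels in right-shifted encodings inside those tracts so that any
normalization regression becomes immediately visible.
The fixtures emulate the *coordinate bookkeeping* challenges of real
genomes — repeats that make indel encodings ambiguous, SVs that break
colinearity — and every fixture is reproducible byte-for-byte from its
seed. They do not emulate human repeat landscapes, GC structure,
mutation-rate heterogeneity, or chromosome-scale contigs. Passing tests
therefore demonstrate correctness of the simulation/validation machinery,
not realism of the sequence model; for realism, feed real references and
databases through the same interfaces.

The standard problem sizes used throughout the tests and the acceptance
script are the package's smoke study: one 100 kb contig, a database of
~300 records, a truth set of 50 SNVs / 20 indels / 5 SVs, 50× paired-end
100 bp coverage (~50,000 pairs), and 10,000-pair mixtures for the somatic
concentration checks — large enough for the law-of-large-numbers checks
(coverage within 5%, mixing within 3 binomial σ) to bind, small enough to
run in minutes on one CPU.

## Numerical and degenerate-input choices

* Fragment lengths are clamped, not re-drawn (fixed RNG consumption per
  pair; the tail distortion is irrelevant at the defaults).
* Identity records (REF = ALT after trimming) are rejected, as are
  `0|0` genotypes and records on unknown contigs (skip-and-log by
  default, fatal in strict mode).
* Overlapping truth variants are a hard error in the diploid builder;
  the sampler's `min_gap` guarantees they cannot arise in the pipeline.
* An indel at position 1 that cannot extend left anchors on the right
  instead.
* Empty call sets, empty truth sets, empty shards, and header-only VCFs
  all have defined, tested behavior.

## Known limitations

Translocations, breakend (BND) notation, interspersed duplications and
multi-sample VCFs are out of scope. The somatic model has a single global
purity. The built-in error model is substitution-only. Alignment
validation judges placement, not CIGAR-level base accuracy. The variant
matcher is site-level; haplotype-aware consistency checking (comparing
edited sequences rather than records) is a deliberate non-goal.
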