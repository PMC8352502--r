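---
title: "Affine-plane subset designs for all-pairs comparisons"
author: "pairplan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Affine-plane subset designs for all-pairs comparisons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairplan)
```

## The problem

Many genomic analyses compare every pair of observations: detection of
identity-by-descent (IBD) segments between individuals, epistasis scans over
SNP pairs, relatedness estimation, protein similarity graphs. With $n$
individuals there are $\binom{n}{2}$ pairs, so both run time and — for tools
that hold the whole cohort in memory — RAM grow as $O(n^2)$. Splitting the
genome into windows does not help the sample-size axis, and it creates a
stitching problem for segments that span window boundaries.

`pairplan` parallelizes along the *sample* axis instead. It splits the $n$
individuals into about $n + \sqrt{n}$ overlapping subsets of at most
$\sqrt{n}$-ish individuals each, arranged so that **every unordered pair of
individuals occurs together in exactly one subset**. Any pairwise-local
analysis (one whose result for a pair depends only on that pair's data) can
then be run independently per subset and the per-subset outputs simply
concatenated: no pair is missed, none is duplicated, and the total number of
pairwise computations is exactly the naive $\binom{n}{2}$.

## The construction

Let $p$ be the smallest prime with $p^2 \ge n$ (`smallest_admissible_prime()`).
The numbers $1 \dots p^2$ are placed column-wise into a $p \times p$ matrix
$P$; values above $n$ are *null* cells indexing no individual
(`base_matrix()`). The design's $p^2 + p$ subsets are, in order:

1. the $p$ **columns** of $P$;
2. the $p$ **rows** of $P$;
3. for each shift level $k = 1 \dots p-1$, the $p$ **rows** of a shifted
   matrix $P_k$ whose column $i$ is column $i$ of $P$ rotated cyclically by
   $$r(i, k) = \big((i - 1)\, k\big) \bmod p$$
   rows (`shift_amount()`, `shifted_matrix()`). Column 1 is never shifted;
   the rotation moves column contents conveyor-belt style, so e.g. for
   $k = 1$ the last entry of column 2 of $P_1$ equals the first entry of
   column 2 of $P$. This identity is pinned in the test suite because prose
   descriptions of shift direction are ambiguous; the formula
   $P_k[j, i] = P[((j - 1 + r(i,k)) \bmod p) + 1,\, i]$ is the canonical
   definition used throughout.

Each individual lies in exactly $p + 1$ subsets (its column, its row, one
row of each $P_k$), and every unordered pair co-occurs in exactly one subset
— the subsets are the lines of an affine plane of order $p$, with
individuals as points. Primality of $p$ is essential: modular shifts by a
composite order collide, and the package's negative-control tests show the
coverage oracle catching exactly that.

No formal proof of the exact-once property is attempted here; instead the
property is verified computationally (see the oracle below), exhaustively
for $n = 4 \dots 2000$ and for randomly sampled $n$ up to $10^5$ in the
routine test run.

```{r}
d <- enumerate_subsets(25)
d
pair_coverage(d)
```

When $p^2 > n$ the null cells shrink some subsets; subsets left with fewer
than two members define no pairwise work and are skipped at emission time
(with a notice), while still being counted in the $p^2+p$ bookkeeping so the
design arithmetic stays literal.

**Self-comparisons.** When an application also needs each individual
compared against itself, doing so in every subset would repeat the work
$p+1$ times. Each individual occurs in exactly one *column* of $P$, so
self-comparisons are attached to the first $p$ subsets only; the total then
equals the naive $\binom{n}{2} + n$.

**Counting identities.** `comparison_count()` sums $\binom{m}{2}$ over
subsets of size $m$; exact-once coverage makes this $\binom{n}{2}$ for every
$n$, and $(p^4 - p^2)/2$ in the saturated case $n = p^2$. For the headline
cohort size $n = 435{,}187$ the design gives $p = 661$ and
$661^2 + 661 = 437{,}582$ subsets — about $9.6$ million per-subset runs
over 22 autosomes, each touching at most 661 individuals instead of all
435k.

## The coverage oracle

`pair_coverage()` is the package's independent verifier: it consumes only
the emitted member lists (never the matrices) and exhaustively counts, for
every unordered pair, the number of subsets containing both members. The
result is a histogram over the co-occurrence count $t$ — for a valid design,
a single spike at $t = 1$ — plus a capped list of offending pairs for
diagnosis. The kernel (C++) walks, for each individual $i$, the members
$j > i$ of the subsets containing $i$, marking partners in an epoch array;
each pair is touched exactly as often as it co-occurs, memory stays
$O(n + \sum_s |s|)$, and the $\binom{n}{2}$ pairs are never materialized, so
$n = 10^5$ verifies in seconds on one core. A repeated partner (a coverage
violation) triggers an exact per-individual recount, so histograms of broken
designs are exact too. The test suite additionally cross-checks the kernel
against a pure-R enumeration oracle at small $n$, keeping the two routes
independent.

Indexing is 1-based throughout (individuals $1 \dots n$), which keeps the
worked matrix identities literal; an external ID list maps line $\ell$ to
individual $\ell$. Subset ids are 0-based ordinals in the fixed construction
order (columns of $P$, rows of $P$, rows of $P_1 \dots P_{p-1}$) — the
construction itself is deterministic, so ids are stable across runs.

## Scatter-gather plumbing

`write_keep_files()` serializes each emitted subset as a one-ID-per-line
keep-file (the single-column dialect PLINK's `--keep` and GERMLINE-style
extraction accept), `write_manifest()` batches subsets into jobs of
`batch_size` (default 1000) in subset-id order and can write the manifest as
JSON, and `merge_results()` gathers per-subset segment TSVs: concatenate,
canonicalize pair order (lexicographic on string IDs, haplotype 0 before 1
within an individual), sort, and flag identical duplicate rows — which
exact-once coverage makes impossible — as a warning. Because every pair is
confined to one subset, the gather step is pure concatenation; there is no
cross-window stitching of the kind genomic windowing requires.

Segment records carry `(id_a, id_b, hap_a, hap_b, chrom, start_bp, end_bp,
start_marker, end_marker, length_cm)`. Marker spans are half-open
(`[start_marker, end_marker)`); bp bounds are inclusive positions of the
first and last matching marker; `length_cm` is written with 17 significant
digits so merged files compare bit-exactly against in-memory results.
GERMLINE `.match` files can be imported through a column-mapping adapter
(`read_germline_match()`); they carry no marker indices, so those fields are
`NA` on that path.

## Synthetic panels and the toy caller

The demonstration needs data for which full-sample and subset-parallel
calling can be compared exactly, with no external downloads.
`simulate_panel()` draws per-marker allele frequencies uniformly from
`maf_range` (default 0.1–0.5) and fills a $2n \times m$ phased 0/1 matrix
with independent Bernoulli draws — a deliberately linkage-free background in
which long chance matches essentially never occur. Markers sit every 5 kb by
default under a uniform 1 cM/Mb map (a piecewise-linear two-column map is
accepted), so a 3000-marker panel spans 15 cM. `plant_segments()` copies a
contiguous stretch of one haplotype onto another so the pair matches exactly
over a span of requested genetic length (3.5 cM and up in the bundled
demonstrations, matching the common IBD reporting threshold), records the
span as ground truth, and resamples placements that would overwrite an
earlier plant on the same haplotype. `inject_errors()` flips alleles
independently at a rate below 5%, leaving the truth records untouched.

What this generator does *not* emulate: linkage disequilibrium, coalescent
segment-length distributions, recombination hotspots, population structure,
phasing errors. Passing tests therefore certify the *combinatorics and
plumbing* — that subset-parallel calling loses and duplicates nothing — not
the accuracy of any particular IBD caller on real cohorts.

`call_ibd()` is an intentionally simple, exactly deterministic pairwise
caller in the GERMLINE mold: markers are cut into windows of
`window_markers` (default 75); haplotypes identical across a full window are
grouped by hashing; each within-group pair's runs of consecutive identical
markers are extended marker-by-marker; maximal runs containing at least one
aligned full window and at least `min_length_cm` (default 3.5) of genetic
length are reported. The trailing partial window can extend but never seed.
The defaults mirror common IBD practice (75-marker words, 3.5 cM
threshold). There is deliberately *no* error tolerance in matching: errors
fragment segments identically in full-sample and subset runs, so the
equivalence property is unaffected, and determinism stays bit-exact. This is
not a production caller and is not meant to compete with one.

## The equivalence demonstration

The central claim is that for any pairwise-local deterministic analysis,
running per subset and concatenating equals running on the full sample.
`equivalence_check()` performs both paths end to end — the per-subset path
genuinely writes one TSV per subset and merges the files — and compares
record sets exactly:

```{r}
panel <- demo_panel(25, m = 3000, n_planted = 10, seed = 1)
eq <- equivalence_check(panel, enumerate_subsets(25))
eq
```

Deleting any one subset removes precisely the calls between its members,
which the check reports as a non-empty missing-record diff; the routine
tests pin this negative control, alongside the composite-order one.

Wall-clock and memory savings of subset-parallelism on real clusters depend
entirely on hardware, scheduler overhead and I/O patterns; they are outside
what this package can or does measure.

## Sizes, tolerances and other numerical choices

* Exact-cover verification in the routine test run: exhaustive
  $n = 4 \dots 2000$ plus 20 seeded pseudo-random $n \le 10^5$ — a few
  minutes on one core; the oracle itself handles millions in principle,
  given time.
* Equivalence panels: $n \in \{16, 25, 49, 50, 100\}$ (covering $n = p^2$
  saturated and $p^2 > n$ padded cases), $m = 3000$ markers, 10 planted
  segments of 4–6 cM, fixed seeds; comparisons are `identical`-level, no
  tolerances.
* All simulation is funneled through explicit seeds and restores the
  caller's RNG state; identical seeds give bit-identical panels, designs are
  deterministic by construction.
* Primality is decided by deterministic trial division (the design prime is
  at most a few thousand for any cohort size in realistic reach, so nothing
  faster is warranted).
* `n < 4` is rejected outright rather than special-cased: with fewer than
  four individuals the matrix construction degenerates and the naive
  approach is trivially sufficient.
* Floating-point: the only non-integer quantity is genetic length;
  equality across the TSV round trip is guaranteed by printing 17
  significant digits.

## Known limitations

* No generalization to prime-power orders (Galois-field affine planes);
  composite orders are supported only as negative controls.
* The exact-once property is verified computationally, not proven.
* The toy caller's error-free exact matching means planted-segment recall
  under injected error is deliberately *not* a supported claim; only
  full-vs-merged equivalence is.
* Scheduler integration (Slurm and kin) is user territory; the manifest
  tells each job which keep-files to process and nothing more.
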