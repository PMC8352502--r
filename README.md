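# pairplan

Subset designs for massively parallelizing all-pairs comparison problems,
with identity-by-descent (IBD) segment calling as the worked use case.

## The problem and who this is for

Comparing every pair of $n$ individuals — IBD segment detection,
relatedness estimation, pairwise similarity graphs — costs
$\binom{n}{2} = (n^2 - n)/2$ comparisons, which is prohibitive for
biobank-scale cohorts if attempted in one process. `pairplan` is for anyone
who wants to scatter such a problem across a cluster *by sample* rather
than by genomic window: it splits the cohort into $p^2 + p$ subsets of at
most $p$ individuals, where $p$ is the smallest prime with $p^2 \ge n$, such
that **every unordered pair of individuals co-occurs in exactly one
subset**. The subsets are the lines of an affine plane of order $p$: number
individuals $1 \dots p^2$ column-wise into a $p \times p$ matrix $P$ (cells
beyond $n$ are null); take the $p$ columns of $P$, the $p$ rows of $P$, and
the rows of the $p - 1$ matrices $P_k$ obtained by cyclically rotating
column $i$ of $P$ by

$$r(i, k) = ((i - 1)\,k) \bmod p \qquad k = 1 \dots p - 1$$

rows. Each individual lands in $p + 1$ subsets, each pair in exactly one, so
per-subset results can be merged by pure concatenation and the total work is
exactly the naive $\binom{n}{2}$ — just split into $\approx n + \sqrt{n}$
independent jobs of $\approx \sqrt{n}$ samples each.

The package provides: the design constructor and its arithmetic
(`enumerate_subsets()`, `plan_design()`), a brute-force C++ coverage oracle
that verifies the exact-once property from the member lists alone
(`pair_coverage()`, `coverage_sweep()`), keep-file / job-manifest emission
and result merging (`write_keep_files()`, `write_manifest()`,
`merge_results()`), a seeded phased-haplotype simulator with planted IBD
segments (`simulate_panel()`, `plant_segments()`), and a deterministic
exact-match toy IBD caller (`call_ibd()`) used to demonstrate that
subset-parallel calling merged over the design is bit-identical to calling
on the full sample (`equivalence_check()`).

## Worked example

Plan the design for a 435,187-individual cohort:

```r
library(pairplan)
plan_design(435187)
#> Partition design plan
#>   individuals (n):           435,187
#>   design prime (p):          661
#>   subsets (p^2 + p):         437,582
#>   max individuals/subset:    661
#>   subsets per individual:    662
#>   pairwise comparisons:      94,693,644,891
#>   ... including self:        94,694,080,078
#>   runs over 22 chromosomes:  9,626,804
```

Every pair of individuals will be compared exactly once across 437,582
subsets of at most 661 individuals; covering 22 autosomes means about 9.6
million small runs instead of 22 enormous ones.

Build a small design, verify coverage, and emit keep-files:

```r
d <- enumerate_subsets(25)
pair_coverage(d)
#> Pair-coverage report (n = 25)
#>   t histogram: t=1: 300
#>   exact cover: every pair co-occurs in exactly one subset
```

All 300 pairs co-occur exactly once ($t = 1$); any other histogram would
name the offending pairs.

End-to-end equivalence demonstration on synthetic data — simulate 25
individuals with 10 planted segments (4–6 cM), call IBD on the full panel
and independently per subset, merge, compare:

```r
panel <- demo_panel(25, m = 3000, n_planted = 10, seed = 1)
eq <- equivalence_check(panel, d)
eq
#> Subset-parallel equivalence check
#>   full-sample records:   8
#>   merged subset records: 8
#>   PASS: record sets are identical
```

(The 10 plants include 2 within-individual self-IBD pairs, which the
default configuration skips, hence 8 records; enable them with
`caller_config(allow_self = TRUE)`.) Deleting any subset breaks the cover
and the check reports exactly the calls lost with it:

```r
eq2 <- equivalence_check(panel, drop_subset(d, 5))
eq2$missing_in_merged[, c("id_a", "id_b", "length_cm")]
#>   id_a id_b length_cm
#> 1  S01  S06      4.33
```

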