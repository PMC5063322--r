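---
title: "Word hypercube landscapes: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Word hypercube landscapes: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wordscape)
```

This vignette is the package's account of the models it implements, the
parameters that matter, and the places where the design was genuinely open
and a choice had to be made.

## The genotype space

A landscape is anchored by a *source* and a *target* sequence of equal
length `L` over single-character symbols. In the default **biallelic**
mode, site `i` admits only the source and target symbols; sites where the
two agree are frozen (singleton alphabets). The genotype space is then a
`d`-dimensional hypercube, `d` being the number of differing sites, with
`2^d` vertices and every vertex having exactly `d` one-mutant neighbors.
For WORD → GENE, `d = 4` and the space has 16 genotypes. A **full** mode
treats every site as ranging over a supplied alphabet (26 letters by
default). The full space is never materialized — `26^4 = 456,976` is
already large, and alphabets or lengths need not stop there — but its size
and neighbor queries are exact.

A *direct path* changes each differing site exactly once, always to the
target symbol, so the direct paths are in bijection with the `d!` orderings
of the differing sites. Enumeration is refused beyond `d = 9` for paths
(`9! = 362,880`) and `d = 20` for vertices; these are deliberate guardrails
against accidental combinatorial explosion, not tunable limits.
Determinism conventions: symbols are uppercased on ingestion, genotypes are
identified by their string form, vertex sets are reported in C-locale
lexicographic order, and paths in lexicographic order of their site
permutation.

## Fitness: word-usage frequency as a proxy

The canonical fitness proxy is a word's usage frequency in a year's book
corpus: occurrences divided by the year's total word count, aggregated
case-insensitively across case variants (a case-sensitive switch exists for
generality). A year is an *environment*; a series of years is an ordered
`environment_series`. Fitness is treated as **relative** throughout — only
ratios and orderings enter any downstream computation — so no normalization
is applied at storage time, and every accessibility or peak verdict is
invariant under strictly increasing transformations of the whole table (a
property the test suite checks explicitly).

Two policies exist for words absent from a year's records: fitness 0 (the
default — a word never printed has zero usage fitness) or a pseudocount
`epsilon / total`, which keeps log-scale analyses (epistasis, log-axis
plots) well defined. Zero fitness reaching the log-scale epistasis
functions is an error, never a silent imputation; the pseudocount decision
belongs upstream where the data are built. Smoothing across years, as
offered by the online frequency viewer, is intentionally out of scope: the
package stores raw per-year frequencies.

## Accessibility, peaks, walks

An *accessible trajectory* gains fitness at every step. Strict inequality
is the default criterion — a tie blocks a path — because with
continuous-valued frequencies ties carry no information and almost never
occur in real tables; a non-strict mode exists for exploration. Blocked
paths report their earliest violating step, indexed so that step `i` is
the move from the `i`-th to the `(i+1)`-th genotype of the path (1-based,
the natural R convention).

Accessibility is counted over **direct paths only**, matching the `d!`
framing of the classical analysis. Peaks use the strict definition (no
strictly fitter neighbor); genotypes on equal-fitness plateaus are
reported separately rather than merged. Greedy adaptive walks move to the
strictly fittest neighbor until none exists, with lexicographic (default)
or seeded-random tie-breaking; walks may roam the whole hypercube, which
is how a vertex off every direct path — WERE, in the classic example — is
reached. `ruggedness_summary()` composes the two analyses: an additive
landscape scores `(1 peak, fraction accessible 1.0)`; anything else is
ruggedness.

## Wright–Fisher simulation

The simulator is haploid, asexual, with non-overlapping generations and
constant population size `N`. Each generation applies, in order:

1. **Selection** — expected offspring share of genotype `g` proportional
   to `count(g) × fitness(g)`;
2. **Mutation** — each individual mutates at each site independently with
   probability `mu`, switching to the alternative biallelic symbol
   (uniform choice among alternatives at multi-allele sites), at most one
   mutation per site per generation;
3. **Resampling** — a multinomial draw of `N` individuals from the
   post-mutation expected frequencies.

The selection → mutation → resampling order is the standard
Wright–Fisher-with-selection discretization; nothing in the source
narrative fixes the order, and at the mutation rates of interest
(`mu ≤ 10⁻³`) the alternatives are indistinguishable. The implementation
is genotype-count based: a `2^d × 2^d` mutation kernel with entries
`(mu/a_s)^k (1−mu)^(d−k)` over the differing sites is applied to the
selection-weighted frequency vector, which is exactly equivalent in
distribution to mutating individuals one by one and keeps a 16-genotype,
250-generation run in the low milliseconds. All randomness comes from the
seeded generator, so identical (config, table) pairs give bit-identical
trajectories. A deterministic infinite-`N` expectation iterator
(`expectation = TRUE`) exposes the exact selection–mutation recursion for
closed-form testing: with two genotypes of fitness ratio `w` and `mu = 0`,
the frequency ratio multiplies by `w` each generation. When `mu = 0` a
monomorphic population is absorbing, and the simulator freezes the
trajectory at that point rather than resampling a constant.

Default thresholds: a genotype is *fixed* on reaching frequency 0.99, and
an intermediate has *tunneled* if the final genotype fixes while the
intermediate never exceeds 0.05. The qualitative narrative ("never reaches
fixation", "low frequency") gives no numbers; these operationalizations
are configurable arguments recorded in each simulation's output metadata.
`fixation_probability_estimate()` credits, per replicate, the first
genotype to reach the fixation threshold, and reports binomial standard
errors `sqrt(p(1−p)/r)`; replicate `i` uses seed `seed + i`.

## Epistasis and environment interaction

Pairwise epistasis uses the four-point test on the **log scale by
default**, because usage-frequency fitness spans orders of magnitude and
multiplicative (log-additive) independence is the natural null; a linear
scale is available. `|epsilon| ≤ 10⁻¹²` counts as exactly zero — a
floating-point guard for computed fixtures, not a scientific tolerance. A
substitution's effect "flips sign" only when strictly beneficial on one
background and strictly deleterious on the other; boundary-zero effects do
not flip, so the `none`/`magnitude`/`sign`/`reciprocal_sign` classes are
mutually exclusive.

Landscape-by-environment interaction has no canonical formula, so the
package operationalizes it in rank terms, consistent with the
ordering-invariance of everything else: per-environment accessibility
counts, Spearman rank correlations of genotype fitness between environment
pairs, and the list of strict fitness-order flips (genotype pairs ordered
one way in one environment and the opposite way in another). Spearman
rather than Pearson because only orderings drive accessibility.

## The synthetic-landscape generators

`make_landscape_fixture()` encodes the qualitative *orderings* of the
classic examples, never any real corpus values (the `fixture` attribute on
each series says so). The archetypes, with defaults:

* **additive** — `fitness = base · (1 + inc)^m`, `m` = sites matching the
  target; `base = 10⁻⁶` (a plausible word-frequency scale), `inc = 0.5`.
  Smooth: unique peak at the target, all `d!` paths accessible.
* **dominant_interior_peak** — additive, then the named peak is multiplied
  by `10³` ("orders of magnitude" above the rest, while keeping log plots
  readable), and the source is raised to `sqrt(1 + inc)` times its best
  neighbor. The source boost is part of this archetype because the
  trapping scenario it reproduces has the source out-ranking its
  intermediates (WORD above WORE) — without it the first step would not be
  a valley. The square root puts the source strictly between adjacent
  additive levels, avoiding exact fitness ties.
* **source_trapped** — additive plus the source boost alone.
* **env_flip** — two environments: the first plain additive (so the
  flip pair's second member, e.g. BENE, out-ranks the source, and
  everything is accessible), the second with the source raised above the
  whole landscape (reversing the pair and sealing every path out of the
  source — by 2000, GENE outranks BIRD itself).

Every archetype asserts its advertised ordering at generation time and
errors on parameter combinations that break it (e.g. oversized jitter), so
analyses downstream can rely on the structure without re-checking.
Optional log-normal jitter (`jitter_sd`) adds realism for property tests;
the default is 0, fully deterministic. `make_ngram_files()` round-trips a
series through the 1-gram export format with `count = round(fitness ×
total)`, erroring if rounding at the chosen `total` (default `10⁹`) would
collapse any strict ordering.

What the fixtures deliberately do **not** emulate: real corpora's heavy
right-tailed frequency distributions, year-to-year autocorrelation,
OCR-era noise in early decades, and the sheer sparsity of four-letter
non-words. Passing tests on fixtures therefore demonstrate the
correctness of the machinery on landscapes with the stated orderings, not
any empirical claim about English usage.

## Problem sizes and numerical checks

The test suite and the acceptance script run entirely on generated data:
oracle comparisons use 50 random landscapes with `d ≤ 6` against an
independent Lehmer-code path enumerator; neutral-drift calibration uses
`N = 100`, `mu = 0`, 500 replicates, initial frequencies 0.1 and 0.5,
checked within three binomial standard errors; the tunneling study uses
`N = 10⁴`, `mu = 10⁻³`, 250 generations, 100 replicates. These sizes give
comfortable statistical resolution while keeping a full run in seconds.

## Known limitations

Substitution-only moves (no insertions or deletions); biallelic dynamics
in the simulator's sweet spot (full-alphabet spaces support size and
neighbor queries, not population simulation at scale); no
fixation-probability-weighted path ensembles; no higher-order (three-way
and up) epistasis decomposition; no diploidy, recombination, or spatial
structure; no live corpus queries — n-gram data enter only as local
export-format files.
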