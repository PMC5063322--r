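# wordscape

Combinatorial fitness landscapes on word hypercubes, with accessibility
analysis, epistasis, landscape-by-environment interaction, and
Wright–Fisher simulation.

## The idea

John Maynard Smith's protein-space analogy pictures molecular evolution as
a word game: transform **WORD** into **GENE** one letter at a time, with
every intermediate a meaningful word. `wordscape` turns that device into a
quantitative adaptive-landscape toolkit. Between any two equal-length
sequences (words, amino-acid strings — any single-character alphabet) the
package builds the biallelic hypercube of all `2^d` genotypes obtainable by
choosing the source or target symbol at each of the `d` differing sites
(16 genotypes for WORD → GENE; the surrounding full 26-letter space holds
`26^4 = 456,976` four-letter strings). Each genotype gets a per-environment
fitness value — by default a word-usage frequency

```
fitness(w, year) = (occurrences of w in the year's corpus) /
                   (total words in the year's corpus)
```

computed case-insensitively from Google Books 1-gram export files, with a
year playing the role of an environment; arbitrary
`genotype,environment,fitness` CSV tables work just as well.

On a landscape the package answers the standard questions of the field:

* **Accessibility** — of the `d!` direct mutational paths from source to
  target, how many increase in fitness at every step?
* **Peaks and walks** — which genotypes are local optima (no strictly
  fitter one-mutant neighbor), and where do greedy adaptive walks end?
* **Epistasis** — for every site pair and background, the four-point
  log-scale interaction `epsilon = log f11 − log f10 − log f01 + log f00`
  with the magnitude / sign / reciprocal-sign classification.
* **G×E** — how topography changes across environments: per-environment
  accessibility, Spearman rank correlations of fitness, and every pairwise
  fitness-order flip.
* **Dynamics** — a seeded haploid Wright–Fisher simulator (selection →
  per-site mutation → multinomial resampling) for trapping on local peaks
  and stochastic tunneling through low-fitness intermediates.

Synthetic-landscape generators (`make_landscape_fixture()`,
`make_ngram_files()`) provide archetypal landscapes — smooth additive,
dominant interior peak, trapped source, environment flip — so every
analysis runs with no external data.

## Worked example

The WORD → GENE landscape with a dominant interior peak at WERE (the
common English word, orders of magnitude more frequent than anything else
in the landscape) and WORD out-ranking its one-mutant neighbors:

```r
library(wordscape)

spec <- landscape_spec("WORD", "GENE")
spec
#> Landscape spec: WORD -> GENE (biallelic, L = 4, d = 4)
#> Space size: 16

fx  <- make_landscape_fixture("WORD", "GENE", "dominant_interior_peak",
                              peak = "WERE")
tab <- fx$tables[[1]]

count_accessible(spec, tab)
#> Accessibility report (environment 1900): 0 / 24 direct paths accessible (0%)

find_peaks(spec, tab)
#> Peaks (environment 1900): GENE, WERE, WORD
```

No direct path to GENE is accessible — every trajectory out of WORD loses
fitness immediately — yet a population evolving at a high mutation rate
still escapes, tunneling through the WORE intermediate to the WERE peak:

```r
cfg <- sim_config(N = 1e4, mu = 1e-3, generations = 250,
                  init = "WORD", seed = 42)
res <- wright_fisher(cfg, spec, tab)
res
#> Wright-Fisher result: N = 10000, mu = 0.001, 250 generations, environment 1900
#> Final composition: WERE=0.996, WORE=0.002, GERE=0.001, WENE=0.001, WERD=0.001
#> Fixation events: WORD@g0, WERE@g13

detect_tunneling(res, "WORE", "WERE")
#> [1] TRUE
```

WERE fixes within ~13 generations while the stepping-stone WORE never
exceeds a few tenths of a percent — the signature of stochastic tunneling.

A command-line front end wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","wordscape.R",package="wordscape"))')" \
    access --landscape WORD GENE --fitness table.csv --env 1900 --out-dir out/
```

with subcommands `fitness`, `access`, `simulate`, `epistasis`, `gxe`,
`fixtures` and `report`; every run writes a JSON manifest (parameters,
seed, input digests) for reproducibility.

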