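Package: wordscape
Title: Combinatorial Fitness Landscapes on Word Hypercubes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds biallelic hypercube genotype spaces between two
    equal-length sequences, attaches per-environment fitness values
    (word-usage frequency proxies from Google Books ngram-export files, or
    arbitrary fitness tables), and analyzes the resulting adaptive
    landscapes: accessible mutational trajectories, local peaks, greedy
    adaptive walks, pairwise epistasis (sign and magnitude), and
    landscape-by-environment interaction. Includes a Wright-Fisher
    simulator with per-site mutation for studying trapping on local peaks
    and stochastic tunneling, plus synthetic-landscape generators so every
    analysis is reproducible without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: jsonlite, stats, utils, tools, grDevices, graphics
Suggests: testthat (>= 3.0.0), optparse, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
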