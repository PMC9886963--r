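Package: rangesim
Title: Spatially Explicit Simulation of Range Contraction and Its Genetic Consequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-time, continuous-space, individual-based simulation of a
    generalist species whose geographic range contracts by shrinkage,
    amputation, or fragmentation, together with the downstream population
    analyses: demography (abundance, age structure, reproductive output),
    pedigree relatedness, nucleotide diversity and divergence, Nei/Hudson-style
    F_ST between sampled groups, and the spatial distribution of genetic
    ancestry. Individuals are diploid hermaphrodites with overlapping
    generations, Gaussian-kernel competition and mate choice, natal dispersal
    with absorbing range boundaries, and neutral infinite-sites genomes with
    recombination. The per-timestep engine is implemented in C++ via Rcpp.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
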