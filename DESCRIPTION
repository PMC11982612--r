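Package: meiodiv
Title: Meiotic Crossover Landscapes and Interference from Testcross Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects meiotic crossovers in testcross (backcross) progenies
    genotyped with SNP markers, builds Kosambi genetic maps, and compares
    recombination landscapes and crossover interference between populations
    with a binned Kullback-Leibler divergence framework: divergence to the
    flat landscape with randomization p-values, pairwise landscape divergence
    with bootstrap confidence intervals, divergence to a shuffle-constructed
    no-interference null, and bootstrap ordering tests with Bonferroni-
    corrected compact letter displays. Includes a gamma-renewal meiosis
    simulator (Marey-map landscape warping, chromatid thinning, tunable
    interference) so every stage can be exercised against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
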