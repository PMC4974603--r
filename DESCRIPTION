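Package: admixbench
Title: Blinded Ancestry-Label Benchmarks from Forward-Time Hybridization
    Simulations
Version: 0.1.0
Authors@R:
    person("Benchmark", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for building and scoring blinded ancestry-label
    benchmarks. Provides a forward-in-time pedigree simulator that
    hybridizes diploid genotypes with block recombination at uniformly
    spaced hotspots, descent-rule labelling of pedigree members
    (matrilineal and grandparent-threshold rules), blinding and scoring
    of third-party label predictions, PLINK text genotype input/output,
    windowed r-squared LD pruning, synthetic founder generation under a
    Balding-Nichols model, supervised admixture estimation against fixed
    ancestral allele-frequency profiles, the minimal-Euclidean admixture
    distance statistic, and threshold distance graphs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
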