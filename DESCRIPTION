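Package: queenline
Title: Colony Genetic Structure Inference for Multi-Queen Ants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for inferring the genetic structure of multi-queen ant
    colonies from codominant microsatellite genotypes under haplodiploidy
    and monandry. Simulates truth-tracked colonies with queen turnover,
    unrelated adopted queens and rare triploid brood; partitions offspring
    into the minimal number of maternal sibships and reconstructs mother
    and father genotypes; matches reconstructed mothers to collected
    queens; classifies queens (former mothers, active egg-layers,
    non-layers) and nests (single contributor, several present
    contributors, several contributors mostly absent); computes pairwise
    Queller-Goodnight relatedness by queen-pair category; and evaluates
    breeder-detection power for a given worker sample size by multinomial
    inclusion-exclusion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
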