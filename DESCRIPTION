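Package: microlesion
Title: Exactly Solvable Age-Structured Model of Driver Mutation
    Accumulation in Tumours
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models a solid tumour as a conglomerate of non-interacting
    microlesions that grow deterministically, accumulate driver mutations,
    and seed new lesions by cell migration. Provides exact Laplace-domain
    solutions of the age-structured lesion equations (surface, slow-down
    and volumetric growth laws), Euler-Lotka growth rates, large-time
    asymptotics for tumour volume and mean driver count, a discretized
    numerical integrator of the age-structured equations, an event-driven
    stochastic simulator of the lesion process, a three-dimensional
    Eden-type lattice simulator for cross-validation, and a parameter-region
    scanner linking migration probability and lesion expansion speed to
    clinically plausible tumour sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
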