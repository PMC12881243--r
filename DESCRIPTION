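Package: hebbnet
Title: Brain-Constrained Multi-Area Spiking Networks with Hebbian
    Cell-Assembly Formation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a twelve-area brain-constrained network of spiking
    excitatory and graded inhibitory neurons on 25x25 toroidal grids, with
    distance-dependent Gaussian connectivity, area-wide global inhibition,
    and an Artola-Broecher-Singer (ABS) Hebbian plasticity rule on all
    excitatory-to-excitatory synapses.  Provides two numerical backends
    (synchronous forward-Euler updating and exact integration on a
    half-step delay grid), word-learning and cell-assembly evaluation
    protocols grounding action and object words in motor and visual areas,
    and the associated statistics (cell-assembly tables, two-way
    repeated-measures ANOVA, Bonferroni-corrected post-hoc comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
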