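Package: turnfold
Title: Turning Machines: Asynchronous Chain Folding on the Triangular Grid
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and verification toolkit for Turning Machines, a
    molecular-robotics model in which a chain of monomers on the triangular
    grid folds itself by asynchronous turning rules with volume exclusion.
    Provides the rule engine with blocking, continuous-time Markov chain
    trajectory sampling and exact expected completion times, exhaustive
    reachability analysis that decides foldability and extracts permanently
    blocked witness configurations, and compilers that turn target shapes
    (lines, zig-zag paths, squares, y-monotone shapes, factor-2 scaled
    shapes with a yw-separator, spirals) into turning-number programs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
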