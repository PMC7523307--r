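Package: dynbridge
Title: Bridge Effects in Dynamic Networks of Momentary Mental States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how individual mental states bridge the
    depression and anxiety symptom clusters in intensive longitudinal
    (ecological momentary assessment) data. Provides a synthetic panel
    generator with a multilevel VAR(1) ground truth, preprocessing of
    unequally spaced prompts onto an equally spaced time lattice,
    per-person KPSS stationarity screening, a hierarchical Bayesian
    first-order vector autoregression fitted by Gibbs sampling with
    missing-data augmentation and group-dummy regression at the
    between-person level, and the summed lag-2 indirect-effect ("bridge
    effect") statistic with group comparisons and node rankings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
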