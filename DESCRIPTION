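Package: saxsmod
Title: Small-Angle X-Ray Scattering Analysis and Symmetric Hybrid Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of one-dimensional small-angle X-ray scattering (SAXS)
    curves and reconstruction of low-resolution structural models for
    homodimeric multi-domain proteins. Implements primary curve analysis
    (Guinier fitting, indirect Fourier transform to the pair-distance
    distribution P(r), Porod invariant/volume/exponent, dimensionless Kratky
    plots, molecular-mass and oligomeric-state estimation), Debye-formula
    forward scattering from coarse-grained bead or atomic models, ab initio
    dummy-residue shape reconstruction by simulated annealing with ensemble
    averaging (normalized spatial discrepancy), a C2-symmetric rigid-body
    assembly search ranked by reduced chi-square with a morphological
    complementarity tie-break, and completion of assemblies with
    self-avoiding dummy-residue linkers and tails. A synthetic-data module
    generates ground-truth toy structures and SEC-SAXS-like noisy curves for
    end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    pracma,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
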