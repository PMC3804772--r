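Package: lieassay
Title: Linear Interaction Energy Affinity Models and Fluorescence-Quench
    Dissociation Constants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for empirical binding free-energy analysis of
    protein-ligand affinity data. Fits the linear interaction energy (LIE)
    model with surface generalized Born (SGB) energy components by ordinary
    least squares, predicts binding free energies for new compounds,
    interconverts free energy and dissociation constants via dG = RT ln KD,
    and estimates dissociation constants from fluorescence-quench titrations
    using inner-filter correction, double-reciprocal saturation estimation
    and fractional-occupancy regression. Includes simulators for LIE
    training tables and quench titrations, packaged reference compound
    tables for tubulin-binding noscapinoid analogues, and a reproducibility
    report that recomputes the derivable quantities in those tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
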