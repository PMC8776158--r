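Package: excitbench
Title: Composite Excitation-Energy Protocols and Benchmark Statistics for
    Peptide Excited States
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for excited-state benchmark studies of
    capped peptide chromophores. Assembles adiabatic zero-point-corrected
    (0-0) excitation energies from vertical, adiabatic and ZPVE energy terms
    via composite wavefunction/DFT protocols; fits and applies
    mode-dependent linear scaling functions to amide-A harmonic frequencies
    and evaluates S1-S0 frequency shifts; compares conformer geometries via
    internal coordinates and Kabsch superposition; decomposes transition
    amplitudes into natural transition orbitals and classifies excited-state
    character; and computes MAE/ME benchmark error statistics with report
    tables. Ships the printed in-paper benchmark tables for an
    N-acetyl-phenylalaninyl-amide peptide series as a bundled dataset, plus
    a seeded synthetic-data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
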