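Package: nmsgen
Title: Normal-Mode-Sampling Conformer Generation and Curation for
    Machine-Learning Potential Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates off-equilibrium molecular conformers by normal mode
    sampling: vibrational analysis of mass-weighted Hessians, thermally
    scaled random displacements along normal modes, per-size sampling
    schedules, energy-window curation of the resulting conformer sets, a
    per-molecule HDF5 dataset format (coordinates/energies/species with
    separate high-energy arrays), and conformational-coverage statistics
    (pair-distance, angle, energy-per-electron and atomization-energy
    distributions). Ships pluggable single-point-energy backends, including
    analytic harmonic and Morse toy potentials, so the whole pipeline runs
    and is testable at desk scale without any quantum-chemistry package.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    rhdf5,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
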