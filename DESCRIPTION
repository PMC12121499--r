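Package: frlpsii
Title: Exciton Models and Charge-Separation Kinetics for Far-Red Photosystem II
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyses Frenkel exciton Hamiltonians for the
    photosystem II reaction-center pigment cluster, with point-dipole
    excitonic couplings estimated from structure, Gaussian-broadened and
    disorder-averaged absorption spectra with reference-peak alignment, a
    strain/electrostatic/coupling decomposition of pigment spectral tuning
    from vertical excitation energy sets, redox-shift bookkeeping of
    charge-separated state energies, and a Marcus-theory master-equation
    model of the charge-separation cascade with detailed-balance back
    rates.  Synthetic generators emulate the upstream quantum-chemistry and
    molecular-dynamics inputs (pigment clusters, static disorder, vertical
    excitation energy quadruples, kinetic networks) so the full pipeline is
    testable offline; curated parameter sets for the white-light and
    far-red-light photosystem II models ship as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
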