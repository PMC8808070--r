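Package: EPRedox
Title: Semiquinone Redox Titrations, CW-EPR Powder Simulation and
    Kinetics for Menaquinone-Linked Metalloenzymes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the quantitative characterization of
    quinone-reactive metalloenzymes by EPR-monitored potentiometry and
    multifrequency continuous-wave EPR. Implements the two successive
    one-electron Nernst model for semiquinone titration curves with its
    derived thermodynamics (two-electron midpoint potential, semiquinone
    stability constant, maximal semiquinone fraction, Q-site occupancy,
    quinone/quinol binding ratio from midpoint-potential shifts),
    first-harmonic powder-pattern simulation of S = 1/2 species with
    rhombic g-tensors, first-order hyperfine structure and H-strain or
    g-strain Gaussian linewidth models at arbitrary microwave frequency,
    spectrum post-processing (baseline correction, peak-to-peak metrics,
    double integration, internal-standard spin quantitation, Mn(II)
    marker field calibration), Michaelis-Menten fitting with turnover
    number bookkeeping, and seeded synthetic-data generators for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'constants.R'
    'AllClasses.R'
    'AllGenerics.R'
    'redox.R'
    'powder.R'
    'spectral.R'
    'kinetics.R'
    'synthetic.R'
    'fixtures.R'
    'io.R'
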