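Package: lambdaCPH
Title: Desk-Scale Lambda-Dynamics Constant-pH Molecular Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A self-contained toy engine for lambda-dynamics based constant-pH
    molecular dynamics. Titratable sites are represented by alchemical
    lambda-coordinates with fictitious mass; intermediate protonation states
    are modelled by linear interpolation of partial charges, so a single
    electrostatic evaluation per step yields both atomic forces and
    lambda-gradients. Includes the multisite representation of chemically
    coupled sites (one coordinate per physical protonation state, constrained
    to the simplex), collective buffer particles that keep the cell neutral
    through a charge constraint, smooth pH and double-well biasing potentials,
    thermodynamic-integration calibration of polynomial correction potentials,
    leapfrog/v-rescale dynamics of the lambda degrees of freedom, titration
    campaigns with Henderson-Hasselbalch pKa fitting, and brute-force
    quadrature oracles for every statistical claim. Direct-sum and
    reaction-field electrostatics replace mesh Ewald at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, yaml
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'constants.R'
    'AllClasses.R'
    'AllGenerics.R'
    'charges.R'
    'potentials.R'
    'electrostatics.R'
    'dynamics.R'
    'ensemble.R'
    'calibration.R'
    'titration.R'
    'fixtures.R'
    'io.R'
    'lambdaCPH-package.R'
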