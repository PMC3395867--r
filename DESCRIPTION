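Package: sieveplate
Title: Hydraulic Resistance of Phloem Sieve Tubes and Sieve Plates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Low-Reynolds-number hydraulic resistor models for phloem sieve
    tubes terminated by perforated sieve plates. Implements the per-pore
    resistance (Hagen-Poiseuille plus Sampson orifice terms), series/parallel
    composition for whole plates, a pore-size-distribution integral for plates
    whose pore radii are normally distributed, and two legacy estimators for
    comparison. Includes a seedable generator of idealized sieve-plate
    realizations (normally distributed pore radii, non-overlapping placement),
    a species-level analysis of lumen versus plate resistance with a
    log-space proportionality fit, and an axisymmetric Stokes (creeping-flow)
    solver used to validate the closed forms for a single coaxial pore.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
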