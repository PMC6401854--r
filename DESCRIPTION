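Package: paac
Title: Acid-Base, Circular-Dichroism and Conformational Analysis of
    Amphoteric Polyamidoamino Acid Polymers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterising amphoteric polyamidoamino acid (PAAC)
    polyelectrolytes whose repeat unit carries one carboxyl and one tertiary
    amine group. Provides potentiometric titration-curve analysis (degree of
    dissociation, apparent pKa from the Henderson-Hasselbalch relation, and
    the Katchalsky-Spitnik cooperativity parameter from its modified form),
    pH speciation of the four repeat-unit ionisation microstates with
    isoelectric-point location, normalisation of circular-dichroism spectra
    to repeat-unit molar ellipticity with differential-ellipticity sigmoid
    fitting of the pH-driven structuring transition, and conformational
    descriptors of oligomer structures (end-to-end distance, radius of
    gyration, Shrake-Rupley solvent-accessible surface area, dipole moment,
    backbone torsion statistics). A synthetic-data generator produces
    titration curves by electroneutrality inversion, pH series of CD spectra
    coupled to amine deprotonation, and extended or coiled ten-repeat-unit
    chain coordinates, so the full pipeline is testable without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
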