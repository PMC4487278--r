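Package: kermalab
Title: Air-Kerma Realization for Low-Energy Electronic Brachytherapy X-Ray Sources
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for realizing air kerma from free-air ionization chamber
    measurements of miniature 50 kV electronic brachytherapy x-ray sources.
    Implements backward stripping of HPGe pulse-height distributions into
    incident photon spectra, the classical free-air-chamber correction factors
    (ion recombination, humidity, air attenuation, electron loss, photon
    scatter, fluorescence and bremsstrahlung reabsorption, initial ion,
    diaphragm scatter), the air-kerma measurement equation with normalization
    to reference conditions, conversion to air-kerma strength, and GUM-style
    quadrature uncertainty budgets. A synthetic-source module generates
    Axxent-like 50 kV spectra, forward-models them into pulse-height
    distributions and simulates chamber current measurements so that the full
    chain can be exercised and tested without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
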