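Package: arteryfield
Title: Electric Field and Joule Heating Simulation of Endovascular
    Stimulation of Large Arteries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Finite-volume simulation of endovascular electrical
    stimulation of a large artery embedded in muscle tissue. Solves the
    electro-quasistatic conduction equation on a rectilinear grid for
    several electrode configurations, computes wall-field metrics (mean
    field, homogeneity, localization value), sweeps inter-electrode
    distance to locate optimal spacings, and runs transient Pennes
    bioheat simulations of pulse-train Joule heating under varying
    blood perfusion.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: Matrix, methods, stats, utils, yaml, xml2
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
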