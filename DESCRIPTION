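Package: paphantom
Title: Dynamical Modeling and Characterization of Photoacoustic Signals from
    Tissue-Mimicking Hydrogel Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyze photoacoustic (PA) signals from tissue-mimicking
    polyvinyl-alcohol (PVA) hydrogel phantoms as impulse responses of a
    second-order linear time-invariant system. Implements output-only N4SID
    subspace identification of discrete-time state-space models from a single
    PA trace, extraction of the damping ratio and natural frequency from the
    identified system matrix, time-domain descriptors (peak-to-peak amplitude,
    arrival time, speed of sound), integrating-sphere reflectance and
    transmittance algebra with a Henyey-Greenstein Monte-Carlo slab model and
    Nelder-Mead inversion for absorption and scattering coefficients, pore-size
    histogramming with lognormal fits, and density, elastic-modulus and
    PVA-weight helpers. Includes a synthetic panel generator emulating a
    nine-hydrogel study and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
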