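Package: ccoupled
Title: Electric Field Dosimetry for Capacitively Coupled Cell-Stimulation Setups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the electric field induced in the culture medium of
    capacitively coupled (CCoupled) in vitro electrical stimulation setups.
    Models a layered cylindrical rig as a series ladder of parallel
    resistor-capacitor elements and solves it in the phasor domain, converts
    arbitrary voltage waveforms (trapezoidal pulses, asymmetric sawtooths,
    piecewise-linear captures, DC) to an equivalent matched-frequency sinusoid
    via the slew-rate rule, and integrates the full time-domain response with
    a stiff, L-stable RC-ladder solver. Ships parameterised fixtures for eight
    published stimulation setups together with the field values their authors
    reported, so the published estimates can be audited and regenerated.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
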