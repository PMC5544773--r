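Package: atrindex
Title: Complex Refractive Index Spectra of Aqueous Solutions from ATR-FTIR
    Absorbance
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Extracts complex refractive index spectra n + ik of aqueous
    solutions from uncollimated, unpolarised attenuated total reflection
    (ATR) FTIR absorbance measurements.  An empirical effective penetration
    depth is calibrated against a water standard with known optical
    constants, the imaginary index k follows from a Beer-Lambert inversion,
    and the real index n is recovered with a Kramers-Kronig transform using
    low-frequency extrapolation from the water standard and offset anchoring
    in a low-loss region.  A differential pathway yields the index increment
    of dilute analytes measured against a water reference.  A
    Lorentz-oscillator forward ATR simulator provides causal ground truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    pracma,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
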