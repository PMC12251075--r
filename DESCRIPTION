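Package: flowspec
Title: Inline Microfluidic Spectroscopy for Multi-Solute Infusion Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Digital twin of a multi-pump drug-infusion line monitored by
    inline flow-cell spectroscopy. Simulates dye absorption spectra and a
    Beer-Lambert flow-cell detector, fits and inverts single-exponential or
    linear calibration curves, recovers two dye concentrations from
    dual-wavelength (424 nm / 631 nm) normalized transmission by an exact
    2x2 absorbance-space solve, models pump schedules with dead-volume
    transport (tanks-in-series or plug flow) and a gravimetric balance, and
    derives total and per-stream flow rates, the third-stream (saline)
    fraction by conservation of mass, and steady-state accuracy and
    repeatability (SEM) statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
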