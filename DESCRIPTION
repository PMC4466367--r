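Package: dnabreaksim
Title: Direct DNA Strand-Break Simulation for A-, B- and Z-DNA Chromatin Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-scale geometric models of the A-, B- and Z-DNA double helix
    packed as nucleosomes into chromatin-fiber fragments inside an annular
    region of interest, together with an analytic energy-deposition event
    locator, single/double/total strand-break scoring, dosimetry, and
    site-hit-probability statistics. Synthetic event generators (uniform in
    the region of interest, and a parameterized track surrogate emulating
    ion irradiation with secondary-electron clustering) stand in for a full
    Monte Carlo transport engine, so that the purely geometric determinants
    of the direct strand-break yield can be studied in isolation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
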