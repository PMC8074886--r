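Package: cdquant
Title: Enantiomer Quantification from Circular Dichroism and Achiral LC
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies single chiral analytes and L/D enantiomer mixtures
    from electronic circular dichroism (CD) spectra combined with achiral
    liquid chromatography (LC). Implements the CD signal law relating
    ellipticity to molar circular dichroism, concentration and path length;
    linear calibration with inverse prediction and signal-to-noise based
    detection and quantification limits; and deconvolution of absolute L-
    and D-enantiomer concentrations by combining the CD-derived absolute
    concentration difference with the LC-derived concentration sum. A
    seeded forward simulator of CD spectra (Gaussian Cotton bands, mirror
    symmetry between enantiomers) and co-eluting achiral chromatograms
    makes every stage testable without instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
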