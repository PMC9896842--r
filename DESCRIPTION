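Package: retppg
Title: Retinal Vessel Pulse Amplitude Mapping from Fundus Video Photoplethysmography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for cardiac-gated retinal vessel
    photoplethysmography. Fits harmonic regression models (two Fourier
    harmonics, linear-spline trend, AR(1) errors) to green-channel
    densitometry of fundus video at 5x5-pixel loci, maps log pulse
    amplitudes in disc-centred polar coordinates over the 0.25-1 mm
    annulus, summarises per-vessel mean/maximum log amplitude and
    amplitude-versus-distance attenuation slopes under
    ophthalmodynamometric force, and compares study groups with linear
    mixed-effects models. Includes a synthetic fundus-video generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    png,
    tiff,
    lme4,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
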