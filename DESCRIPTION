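Package: actinometry
Title: Fluorescence Actinometry for Absolute Light Intensity Measurement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts fluorescence kinetics recorded under constant
    illumination into absolute light intensity (photon flux density) and
    two-dimensional irradiance maps. Provides a registry of fluorescent
    actinometers with tabulated photoconversion cross sections,
    monoexponential kinetic fitting for single traces and per-pixel image
    stacks (wide-field and raster-scan timing), conversion of characteristic
    times into einstein-based irradiance with validity checks and
    uncertainty propagation, wavelength-to-wavelength intensity transfer
    with an inert reference fluorophore, action-spectrum corrections for
    polychromatic sources, and forward simulators (including
    reaction-diffusion blurring, inner-filter reporting and photosynthetic
    fluorescence rise) that generate all test inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    optparse,
    pracma,
    stats,
    tiff,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
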