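Package: sior
Title: Structured Illumination Ophthalmoscopy Simulation and Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for structured illumination ophthalmoscopy (SIO): a forward
    imaging model for fringe-illuminated retinal frames with sub-pixel eye
    motion and a defocused scattering background, a synthetic acquisition
    simulator (cone-mosaic phantoms, drift/microsaccade trajectories, blink
    surrogates, camera noise), the pre-processing, frame-selection and
    shift-estimation stages of the reconstruction pipeline, a two-layer
    maximum a posteriori reconstruction under positivity constraint that
    jointly achieves optical sectioning and super-resolution, and
    post-reconstruction metrics (radial power spectra, effective cutoff
    frequency, cone detection and cone-density maps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    jsonlite,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
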