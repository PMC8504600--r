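Package: profilerestore
Title: Volume-Averaging-Free Photon Beam Profile Reconstruction from
    Ion-Chamber-Array Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Reconstructs continuous, volume-averaging-free photon beam
    profiles from discrete ionization-chamber-array measurements.  Discrete
    readings are upsampled with modified Akima (Makima) interpolation and
    passed through a sliding-window three-layer neural network trained with
    Levenberg-Marquardt backpropagation against high-resolution reference
    profiles.  Includes a physics-based synthetic generator for 6 MV beam
    profiles sampled by a 5 mm pitch chamber array, penumbra-width and 1-D
    gamma evaluation metrics, and an experiment pipeline that trains
    plane-specific and combined networks and tabulates their performance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
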