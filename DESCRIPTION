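Package: duodop
Title: Automatic Carotid Peak-Velocity Measurement with Dual-Beam Vector Doppler
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automatic measurement of the peak blood velocity in the
    common carotid artery from a dual angled-array transversal ultrasound
    acquisition. Implements automatic lumen localization in B-mode frame
    sequences by a gradient circular Hough transform with multi-frame
    consensus, automatic Doppler region-of-interest placement, multigate
    spectral processing of complex IQ ensembles (wall filtering, short-time
    FFT, modified centre-of-mass frequency centroid), dual-beam angle-corrected
    velocity triangulation, and the evaluation statistics used for phantom and
    volunteer campaigns. A synthetic-data generator emulates speckled B-mode
    phantom sequences with a hypoechoic circular lumen and dual-beam pulsed
    Doppler IQ signals with known velocity ground truth, standing in for the
    probe and scanner hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    rhdf5,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
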