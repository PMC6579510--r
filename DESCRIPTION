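Package: orbitrack
Title: Simulation and Analysis of 3D Orbital Single-Particle Tracking of
    Axonal Organelle Transport
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for feedback-based 3D orbital single
    particle tracking of organelles such as axonal mitochondria. Provides a
    physical simulator (Gaussian-beam point spread function, 16-sector orbit
    photon counts from two axially offset detection planes, Poisson noise,
    extended emitters, motion-state ground truth, synthetic wide-field
    movies), the closed-loop localization engine (first-order Fourier sector
    estimator, calibration look-up tables, spiral search, dark orbits,
    long-range stage recentering), trajectory motion-state analysis (angle
    autocorrelation segmentation with a randomized threshold, two-Gaussian
    maximum-likelihood velocity classification, state, pause and transition
    statistics, kymographs), and wide-field colocalization of moving
    organelles with stationary ones (moving-object removal, stationary-object
    detection, second-order polynomial camera-to-tracking mapping, occupancy
    and crossing-time profiles).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    tiff,
    EBImage,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
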