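Package: sptmotion
Title: Motion Classification and Simulation for Single-Particle Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies short windows (tracklets) of single-particle membrane
    receptor trajectories into immobile, confined, Brownian, and directed
    motion using a maximal-excursion statistic whose Brownian null quantiles
    are calibrated by Monte Carlo simulation. Includes track-table input and
    quality filtering, track-level motion-change summaries, stochastic
    trajectory simulators (Brownian, drift-diffusion, Ornstein-Uhlenbeck),
    a synthetic fluorescence time-lapse renderer with mixed Poisson-Gaussian
    noise, a minimal spot detector and nearest-neighbor linker for end-to-end
    benchmarks, and AIC-selected Gaussian-mixture analysis of spot intensities
    for fluorophore stoichiometry.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
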