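Package: locusdrift
Title: Drift-Velocity and Anomalous-Diffusion Analysis of Chromosomal Locus Tracking Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantitative analysis of single-particle tracks of fluorescently
    labelled chromosomal loci across the bacterial cell cycle: ensemble
    mean-squared displacement and power-law scaling exponents, step-size
    statistics against a Gaussian diffusive null, spatially binned drift
    velocity profiles with equilibrium-position and relaxation-time
    estimation, and order-of-magnitude force inference through the
    overdamped Langevin picture and the Einstein relation. Includes a
    seeded synthetic trajectory generator (Ornstein-Uhlenbeck,
    fractional Gaussian noise, and a full split-cycle model with an
    equilibrium that jumps from mid-cell to the quarter-cell positions)
    so every stage of the pipeline is testable without microscopy data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
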