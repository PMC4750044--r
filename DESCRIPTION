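Package: embryokin
Title: Nuclear-Cycle Kinetics and Anoxia-Perturbation Analysis for On-Chip
    Drosophila Embryo Time-Lapse Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying early Drosophila embryogenesis from
    Histone-GFP time-lapse fluorescence stacks acquired in microfluidic embryo
    arrays. Segments nuclei per frame by relative-difference filtering and
    connected-component clustering, extracts the mean-nuclear-area trajectory,
    derives nuclear-cycle durations (NC10-NC13, stage 5) from telophase minima,
    aligns cohorts at nuclear division 12, and quantifies anoxia-induced
    metaphase arrest, recovery-to-anaphase times, developmental milestones and
    control-versus-treated comparisons. Includes a ground-truth synthetic
    generator for area trajectories and image stacks, and a transient 2D
    convection-diffusion model of oxygen removal in the gas channel + PDMS
    cross-section of the device.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    Matrix,
    jsonlite,
    methods,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
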