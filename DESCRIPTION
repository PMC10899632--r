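Package: teckit
Title: Transcription Elongation Kinetics Through Archaeal Histone-Based Chromatin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-driven quantification of RNA polymerase elongation
    kinetics through archaeal histone-based chromatin landscapes. Provides a
    seeded continuous-time Markov simulator of ternary elongation complexes
    (TECs) restarting from a +58 stall and elongating to a +231 template end
    through periodic histone-dimer barriers, an exact transient-distribution
    oracle for the underlying birth chain, a synthetic 1-D gel densitometry
    layer (lane profiles, marker lanes), ImageQuant-style lane quantification
    (marker-based size calibration by linear regression, background
    subtraction, seven-bin transcript-length binning, waterfall
    normalization), and the kinetic statistics used to summarize such assays:
    bin-midpoint mean transcript length, average elongation rate in nt/s,
    rates relative to histone-free templates, two-point exponential pause
    half-life at the +58 stall with reference-normalized tables, full-length
    fractions, and replicate standard errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
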