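Package: spinesim
Title: Dendritic Spine Calcium Signalling Simulator with Subunit-Specific NMDAR Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates glutamatergic transmission at a single CA1 pyramidal
    dendritic spine: vesicular glutamate release with cleft and porous-medium
    extrasynaptic diffusion and transporter uptake, deterministic eight-state
    NR2A/NR2B NMDA-receptor and seven-state AMPA-receptor kinetics with Q10
    temperature scaling, a two-compartment spine/shaft electrical model with
    Jahr-Stevens magnesium block and voltage-dependent calcium channels, and a
    four-compartment calcium model (PSD, cytosol, neck, shaft) with pumps,
    immobile buffers and inter-compartment diffusion.  Includes stimulation
    protocols (single pulse, LFS, HFS, pairing, theta-burst), amyloid-beta
    oligomer perturbation experiments, a downstream CaMKII state-transition
    cascade, Latin-hypercube/PRCC global sensitivity analysis and ensemble
    MCMC calibration of the calcium-handling parameters against
    backpropagating-action-potential evoked transients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    lhs,
    yaml,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
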