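Package: nanokymo
Title: Simulation and Deep-Learning Analysis of Nanofluidic Scattering
    Microscopy Kymographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for nanofluidic scattering microscopy (NSM) of single
    biomolecules diffusing in nanochannels. Simulates ground-truthed
    kymographs (Brownian trajectories, Gaussian optical-contrast responses,
    a parametric background-noise model), preprocesses raw intensity stacks
    into normalized background-suppressed kymographs, estimates molecular
    weight and hydrodynamic radius with a compact hierarchical vision
    transformer that outputs probability-weighted property maps, applies
    probability-sum thresholding and Gaussian outlier pruning to populations
    of estimates, and benchmarks estimator precision against Cramer-Rao
    lower bounds. Includes Stokes-Einstein (optionally hindered) diffusivity
    conversions and dsDNA ladder calculators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
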