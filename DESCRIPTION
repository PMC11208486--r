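Package: cosolv
Title: Enzyme Stability and Activity in Water-Miscible Co-Solvents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies enzyme stability in water-miscible organic
    co-solvents from thermal-ramp fluorimetry (nanoDSF F350/330 ratios or
    FMN-release melt curves) and microplate kinetics. Extracts melting
    temperatures by inflection-point detection, slices thermal ramps
    isothermally across co-solvent concentration and fits an extended
    two-state unfolding model to obtain the co-solvent concentration of
    half-unfolding (cU50) at a given temperature, fits a Gaussian-augmented
    activity-solvent model to specific-activity profiles, and provides the
    downstream analyses: melting-temperature shifts, stability rankings,
    operating-window identification from cU50-versus-temperature curves,
    and correlation of activity- and unfolding-derived parameters. Includes
    seeded synthetic-data generators with the models' statistical structure
    for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
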